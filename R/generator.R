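#' Generator configuration
#'
#' The generator emulates the heterogeneity of text-mined relationships: one
#' ground-truth fact surfaces as several paraphrases that vary the key-entity
#' synonym, the role label (including past-tense forms), passive voice (the
#' `$$` labels of the inverse-direction role), and orientation through the
#' inverse role. Probabilities are per-paraphrase sampling weights.
#'
#' @param n_facts number of distinct ground-truth facts.
#' @param paraphrases_per_fact distinct surface renderings per fact.
#' @param p_passive probability of choosing a `$$` (passive) label when the
#'   chosen direction role has one.
#' @param p_inverse_orientation probability of expressing the fact through
#'   the inverse role (arguments swapped); for symmetric roles, of swapping
#'   the arguments.
#' @param p_synonym_substitution probability that a key entity surfaces as a
#'   non-preferred synonym.
#' @param p_plural probability of pluralizing a modifier label ("dose" ->
#'   "doses"), exercising the pluralization fallback.
#' @param seed RNG seed; fixes the output exactly.
#' @return list of class `phare_genconfig`.
#' @export
generator_config <- function(n_facts = 100, paraphrases_per_fact = 5,
                             p_passive = 0.3, p_inverse_orientation = 0.3,
                             p_synonym_substitution = 0.5, p_plural = 0.25,
                             seed = 42) {
  probs <- c(p_passive, p_inverse_orientation, p_synonym_substitution, p_plural)
  if (any(probs < 0 | probs > 1)) {
    phare_error("probabilities must lie in [0, 1]", class = "phare_config_error")
  }
  stopifnot(n_facts >= 0, paraphrases_per_fact >= 1)
  structure(
    list(n_facts = n_facts, paraphrases_per_fact = paraphrases_per_fact,
         p_passive = p_passive, p_inverse_orientation = p_inverse_orientation,
         p_synonym_substitution = p_synonym_substitution, p_plural = p_plural,
         seed = seed),
    class = "phare_genconfig"
  )
}

# Entity specifications available for fact sampling: every key entity, plus
# every depth-1 wrap by an entity type whose modifier restriction the key's
# category satisfies.
generator_entity_pool <- function(onto) {
  pool <- list()
  for (k in onto$lexicon) {
    pool[[length(pool) + 1L]] <- list(key = k$id, type = NULL,
                                      category = k$category)
  }
  scoped <- Filter(function(t) !is.null(t$modifier_category), onto$entity_types)
  for (k in onto$lexicon) {
    for (t in scoped) {
      if (t$modifier_category == k$category) {
        pool[[length(pool) + 1L]] <- list(key = k$id, type = t$id,
                                          category = k$category)
      }
    }
  }
  pool
}

spec_entity_id <- function(spec, onto) {
  base <- encode_local_name(tolower(onto$lexicon[[spec$key]]$preferred_name))
  if (is.null(spec$type)) return(base)
  paste(base, encode_local_name(tolower(onto$entity_types[[spec$type]]$labels[[1]])),
        sep = "=")
}

# Roles usable as fact orbits: one representative per inverse pair (the one
# owning non-$$ labels), plus symmetric and plain roles.
generator_role_pool <- function(onto) {
  ids <- character()
  for (r in onto$roles) {
    if (!is.null(r$inverse)) {
      if (any(grepl("$$", r$labels, fixed = TRUE)) &&
          !all(grepl("$$", r$labels, fixed = TRUE))) {
        # mixed-label role: still usable; prefer the lexicographically first
      }
      if (all(grepl("$$", r$labels, fixed = TRUE))) next
      if (r$id > r$inverse && !all(grepl("$$", onto$roles[[r$inverse]]$labels,
                                         fixed = TRUE))) next
    }
    ids <- c(ids, r$id)
  }
  sort(ids)
}

sample_one <- function(x) if (length(x) == 1) x else sample(x, 1)

# Render one paraphrase of a fact; returns list(raw_type, subj, obj tokens).
render_paraphrase <- function(fact, onto, config) {
  r <- onto$roles[[fact$role]]
  subj <- fact$subject; obj <- fact$object
  direction <- r
  if (!is.null(r$inverse) && stats::runif(1) < config$p_inverse_orientation) {
    direction <- onto$roles[[r$inverse]]
    tmp <- subj; subj <- obj; obj <- tmp
  } else if (isTRUE(r$symmetric) && stats::runif(1) < config$p_inverse_orientation) {
    tmp <- subj; subj <- obj; obj <- tmp
  }
  passive <- grepl("$$", direction$labels, fixed = TRUE)
  labels <- direction$labels
  if (any(passive) && any(!passive)) {
    labels <- if (stats::runif(1) < config$p_passive) labels[passive] else labels[!passive]
  }
  # the first label of the (voice-restricted) set is the default surface;
  # alternatives appear only under synonym substitution, so that a config
  # with all probabilities zero renders identical paraphrases
  pick_label <- function(labs) {
    if (length(labs) > 1 && stats::runif(1) < config$p_synonym_substitution) {
      sample_one(labs[-1])
    } else {
      labs[[1]]
    }
  }
  surface_of <- function(spec) {
    k <- onto$lexicon[[spec$key]]
    syn <- k$preferred_name
    others <- setdiff(k$synonyms, k$preferred_name)
    if (length(others) && stats::runif(1) < config$p_synonym_substitution) {
      syn <- sample_one(others)
    }
    toks <- strsplit(syn, "[[:space:]]+")[[1]]
    if (!is.null(spec$type)) {
      lab <- pick_label(onto$entity_types[[spec$type]]$labels)
      if (stats::runif(1) < config$p_plural && !grepl("s$", lab)) {
        lab <- paste0(lab, "s")
      }
      toks <- c(toks, strsplit(lab, "[[:space:]]+")[[1]])
    }
    toks
  }
  list(raw_type = pick_label(labels),
       subject_tokens = surface_of(subj),
       object_tokens = surface_of(obj))
}

#' Generate a synthetic raw-relationship corpus with retained ground truth
#'
#' Samples `n_facts` distinct facts (distinct inverse/symmetry orbits) over
#' the ontology's key entities, their depth-1 composite wraps, and its
#' roles, then renders each fact as `paraphrases_per_fact` *distinct* surface
#' paraphrases. Every emitted surface form uses only labels the ontology
#' owns, so the corpus is fully normalizable and integration must recover
#' exactly the ground-truth fact set.
#'
#' @param config a [generator_config()].
#' @param onto a `phare_ontology`; defaults to [generator_ontology()].
#' @return list with:
#'   * `raws`: list of `phare_raw`;
#'   * `truth`: data frame mapping each raw record (`raw_id`) to its
#'     `fact_id` and orbit key;
#'   * `facts`: data frame of the ground-truth facts (`fact_id`, `role`,
#'     `subject_id`, `object_id`, `orbit`).
#' @export
generate_corpus <- function(config = generator_config(), onto = generator_ontology()) {
  stopifnot(inherits(config, "phare_genconfig"), inherits(onto, "phare_ontology"))
  with_seed(config$seed, {
    entities <- generator_entity_pool(onto)
    roles <- generator_role_pool(onto)
    if (!length(entities) || !length(roles)) {
      phare_error("ontology offers no entities or roles to sample",
                  class = "phare_config_error")
    }
    facts <- list()
    orbits <- character()
    guard <- 0L
    while (length(facts) < config$n_facts) {
      guard <- guard + 1L
      if (guard > 200L * max(1L, config$n_facts)) {
        phare_error("fact space too small for the requested number of facts",
                    class = "phare_config_error")
      }
      role_id <- sample_one(roles)
      pair <- sample.int(length(entities), 2)
      subj <- entities[[pair[[1]]]]
      obj <- entities[[pair[[2]]]]
      sid <- spec_entity_id(subj, onto)
      oid <- spec_entity_id(obj, onto)
      if (sid == oid) next
      ok <- orbit_key(onto, role_id, sid, oid)
      if (ok %in% orbits) next
      orbits <- c(orbits, ok)
      facts[[length(facts) + 1L]] <- list(
        fact_id = length(facts) + 1L, role = role_id,
        subject = subj, object = obj,
        subject_id = sid, object_id = oid, orbit = ok
      )
    }
    raws <- list()
    truth_fact <- integer()
    truth_orbit <- character()
    for (fact in facts) {
      # distinct paraphrases are best-effort: when the variant space is
      # smaller than requested (e.g. all probabilities zero), the first
      # rendering is repeated, so a degenerate config yields identical
      # surface forms rather than an error
      picked <- list()
      seen <- character()
      tries <- 0L
      while (length(picked) < config$paraphrases_per_fact && tries < 500L) {
        tries <- tries + 1L
        pp <- render_paraphrase(fact, onto, config)
        key <- paste(pp$raw_type,
                     paste(pp$subject_tokens, collapse = " "),
                     paste(pp$object_tokens, collapse = " "), sep = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        picked[[length(picked) + 1L]] <- pp
      }
      while (length(picked) < config$paraphrases_per_fact) {
        picked[[length(picked) + 1L]] <- picked[[1L]]
      }
      for (pp in picked) {
        idx <- length(raws) + 1L
        raws[[idx]] <- raw_relationship(
          pp$raw_type, pp$subject_tokens, pp$object_tokens,
          pmid = as.character(100000L + idx),
          sentence = sprintf("%s %s %s (synthetic sentence %d for fact %d).",
                             paste(pp$subject_tokens, collapse = " "),
                             gsub("$$", " ", pp$raw_type, fixed = TRUE),
                             paste(pp$object_tokens, collapse = " "),
                             idx, fact$fact_id)
        )
        truth_fact <- c(truth_fact, fact$fact_id)
        truth_orbit <- c(truth_orbit, fact$orbit)
      }
    }
    list(
      raws = raws,
      truth = data.frame(raw_id = seq_along(raws), fact_id = truth_fact,
                         orbit = truth_orbit, stringsAsFactors = FALSE),
      facts = data.frame(
        fact_id = vapply(facts, `[[`, integer(1), "fact_id"),
        role = vapply(facts, `[[`, character(1), "role"),
        subject_id = vapply(facts, `[[`, character(1), "subject_id"),
        object_id = vapply(facts, `[[`, character(1), "object_id"),
        orbit = vapply(facts, `[[`, character(1), "orbit"),
        stringsAsFactors = FALSE
      )
    )
  })
}
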