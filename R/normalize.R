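#' Raw text-mined relationships
#'
#' A raw relationship is the untyped output of upstream extraction:
#' `raw_type(subject, object)` plus provenance. Composite entities arrive in
#' extractor order: the key-entity token(s) first, then modifiers read left
#' to right with the head entity last (the phrase "differences in coumadin
#' requirements" becomes tokens `coumadin requirements differences`).
#'
#' @param raw_type relationship-type string, possibly carrying the `$$`
#'   passive-voice separator.
#' @param subject_tokens,object_tokens character vectors of whitespace-free
#'   tokens.
#' @param pmid PubMed identifier (positive integer as string).
#' @param sentence the source sentence.
#' @return a list of class `phare_raw`.
#' @export
raw_relationship <- function(raw_type, subject_tokens, object_tokens, pmid,
                             sentence) {
  stopifnot(is_scalar_string(raw_type), is_scalar_string(sentence),
            nzchar(sentence))
  pmid <- as.character(pmid)
  if (!grepl("^[0-9]+$", pmid) || as.numeric(pmid) <= 0) {
    phare_error(sprintf("pmid must be a positive integer, got '%s'", pmid),
                class = "phare_format_error")
  }
  check_tokens <- function(tok, side) {
    tok <- as.character(tok)
    if (!length(tok) || any(!nzchar(tok)) || any(grepl("[[:space:]]", tok))) {
      phare_error(sprintf("%s tokens must be non-empty and whitespace-free", side),
                  class = "phare_format_error")
    }
    tok
  }
  structure(
    list(raw_type = raw_type,
         subject_tokens = check_tokens(subject_tokens, "subject"),
         object_tokens = check_tokens(object_tokens, "object"),
         pmid = pmid, sentence = sentence),
    class = "phare_raw"
  )
}

raw_surface_key <- function(raw) {
  paste(raw$raw_type,
        paste(tolower(raw$subject_tokens), collapse = " "),
        paste(tolower(raw$object_tokens), collapse = " "),
        sep = " | ")
}

failure <- function(stage, token) {
  structure(list(stage = stage, token = token), class = "phare_failure")
}

#' @export
is_failure <- function(x) inherits(x, "phare_failure")

#' Normalize a composite entity against the ontology
#'
#' Implements the left-to-right wrap: the longest prefix of tokens matching a
#' key-entity synonym becomes the anchor (its preferred name replacing any
#' synonym such as `coumadin` -> `warfarin`); failing that, a first token
#' matching an entity-type label (e.g. the word "gene") anchors the chain in
#' that class. Each subsequent token is looked up with [find_entity_type()]
#' using the anchor's key category to disambiguate scoped labels, and wraps
#' the current entity via the `modified` link.
#'
#' As a side effect, the first observation of an outer type wrapping an inner
#' *typed* entity appends a composition axiom to the ontology (see
#' [add_composition_axiom()]).
#'
#' @param tokens character vector of tokens (or a `phare_raw`'s token field).
#' @param onto a `phare_ontology`.
#' @return a normalized entity (class `phare_entity`) or a `phare_failure`
#'   with fields `stage` (`"key"` or `"modifier"`) and `token`.
#' @export
normalize_entity <- function(tokens, onto) {
  tokens <- as.character(tokens)
  n <- length(tokens)
  if (!n) return(failure("key", ""))
  ne <- NULL
  category <- NULL
  k <- 0L
  for (len in rev(seq_len(n))) {
    span <- paste(tokens[seq_len(len)], collapse = " ")
    ke <- tryCatch(resolve_key_entity(onto, span),
                   phare_ambiguity = function(e) e)
    if (inherits(ke, "condition")) return(failure("key", span))
    if (!is.null(ke)) {
      ne <- structure(list(kind = "key", key = ke$id), class = "phare_entity")
      category <- ke$category
      k <- len
      break
    }
  }
  if (is.null(ne)) {
    et <- tryCatch(find_entity_type(onto, tokens[[1]]),
                   phare_ambiguity = function(e) e)
    if (inherits(et, "condition") || is.null(et)) {
      return(failure("key", tokens[[1]]))
    }
    ne <- structure(list(kind = "class", type = et$id), class = "phare_entity")
    category <- if (et$id %in% key_categories()) et$id else NULL
    k <- 1L
  }
  if (k < n) {
    for (i in seq(k + 1L, n)) {
      et <- tryCatch(find_entity_type(onto, tokens[[i]], category),
                     phare_ambiguity = function(e) e)
      if (inherits(et, "condition") || is.null(et)) {
        return(failure("modifier", tokens[[i]]))
      }
      if (ne$kind == "typed") add_composition_axiom(onto, et$id, ne$type)
      ne <- structure(list(kind = "typed", type = et$id, modified = ne),
                      class = "phare_entity")
    }
  }
  ne
}

#' Canonical identifier of a normalized entity
#'
#' Deterministic `=`-encoded id built from the anchor's preferred name and
#' the preferred labels of the wrapping types, innermost first:
#' `Variation(DrugDose(warfarin))` becomes `warfarin=dose=variation`.
#'
#' @param ne a `phare_entity`.
#' @param onto the ontology the entity was normalized against.
#' @return a character id.
#' @export
entity_id <- function(ne, onto) {
  stopifnot(inherits(ne, "phare_entity"))
  if (ne$kind == "key") {
    k <- onto$lexicon[[ne$key]]
    return(encode_local_name(tolower(k$preferred_name)))
  }
  label <- tolower(onto$entity_types[[ne$type]]$labels[[1]])
  if (ne$kind == "class") {
    return(encode_local_name(label))
  }
  paste(entity_id(ne$modified, onto), encode_local_name(label), sep = "=")
}

#' Surface tokens of a normalized entity
#'
#' Renders a normalized entity back to extractor-order tokens using preferred
#' names/labels only; normalizing these tokens again yields the same entity
#' (normalization is idempotent on its own output surface).
#'
#' @inheritParams entity_id
#' @return character token vector.
#' @export
entity_surface <- function(ne, onto) {
  stopifnot(inherits(ne, "phare_entity"))
  if (ne$kind == "key") {
    return(strsplit(onto$lexicon[[ne$key]]$preferred_name, "[[:space:]]+")[[1]])
  }
  label <- strsplit(onto$entity_types[[ne$type]]$labels[[1]], "[[:space:]]+")[[1]]
  if (ne$kind == "class") return(label)
  c(entity_surface(ne$modified, onto), label)
}

# The most specific entity type of a normalized entity (for KB typing).
entity_type_of <- function(ne, onto) {
  switch(ne$kind,
         key = onto$lexicon[[ne$key]]$category,
         class = ne$type,
         typed = ne$type)
}

#' Normalize a raw relationship type
#'
#' Delegates to [find_role()]. Passive labels (containing `$$`) belong to the
#' passive-direction role (e.g. `is$$inhibited` to `isInhibitedBy`), so no
#' argument swap happens here; inverse handling is the assembly step's job.
#'
#' @param raw_type the raw type string.
#' @param onto a `phare_ontology`.
#' @return list with `role` (a `phare_role`) and `orientation = "as-stated"`,
#'   or a `phare_failure` with stage `"type"`.
#' @export
normalize_type <- function(raw_type, onto) {
  r <- tryCatch(find_role(onto, raw_type), phare_ambiguity = function(e) e)
  if (inherits(r, "condition") || is.null(r)) return(failure("type", raw_type))
  list(role = r, orientation = "as-stated")
}

new_normalized_relationship <- function(role_id, subj, obj, subj_id, obj_id,
                                        provenance, derived_by_inverse) {
  structure(
    list(role = role_id, subject = subj, object = obj,
         subject_id = subj_id, object_id = obj_id,
         provenance = provenance, derived_by_inverse = derived_by_inverse),
    class = "phare_relationship"
  )
}

#' Assemble a normalized relationship, expanding inverses and symmetry
#'
#' Returns the stated relationship plus, when the role has an inverse, the
#' inverse relationship with subject and object swapped (flagged
#' `derived_by_inverse`); for a symmetric role, the swapped twin under the
#' same role. Never both.
#'
#' @param onto a `phare_ontology`.
#' @param role a `phare_role` (or its id).
#' @param subj,obj normalized entities (`phare_entity`).
#' @param provenance data frame with columns `pmid` and `sentence`.
#' @return list of `phare_relationship`.
#' @export
assemble <- function(onto, role, subj, obj, provenance) {
  if (is.character(role)) role <- onto$roles[[role]]
  stopifnot(inherits(role, "phare_role"))
  sid <- entity_id(subj, onto)
  oid <- entity_id(obj, onto)
  out <- list(new_normalized_relationship(role$id, subj, obj, sid, oid,
                                          provenance, FALSE))
  if (!is.null(role$inverse)) {
    out <- c(out, list(new_normalized_relationship(
      role$inverse, obj, subj, oid, sid, provenance, TRUE)))
  } else if (isTRUE(role$symmetric) && sid != oid) {
    out <- c(out, list(new_normalized_relationship(
      role$id, obj, subj, oid, sid, provenance, TRUE)))
  }
  out
}

# Canonical key of one directed normalized triple.
triple_key <- function(role_id, sid, oid) paste(role_id, sid, oid, sep = " | ")

#' Canonical key of the inverse/symmetry orbit of a triple
#'
#' Two directed triples that express the same fact through an inverse pair
#' (`isInhibitedBy(a,b)` / `inhibits(b,a)`) or a symmetric swap share one
#' orbit key; counting orbits counts *expressions* rather than triples.
#'
#' @param onto a `phare_ontology`.
#' @param role_id role id.
#' @param sid,oid canonical entity ids.
#' @return a character key.
#' @export
orbit_key <- function(onto, role_id, sid, oid) {
  r <- onto$roles[[role_id]]
  if (!is.null(r) && isTRUE(r$symmetric)) {
    ends <- sort(c(sid, oid))
    return(triple_key(role_id, ends[[1]], ends[[2]]))
  }
  if (!is.null(r) && !is.null(r$inverse)) {
    return(min(triple_key(role_id, sid, oid),
               triple_key(r$inverse, oid, sid)))
  }
  triple_key(role_id, sid, oid)
}

#' Normalize and integrate a batch of raw relationships
#'
#' Runs the four normalization steps on every raw relationship: subject
#' entity, object entity, relationship type, then assembly with
#' inverse/symmetric expansion. Relationships identical after normalization
#' (same role, subject, object) are merged into one relationship with
#' concatenated provenance; an assertion and its inverse-derived twin from
#' another sentence merge the same way. Failures are collected as data, not
#' raised.
#'
#' @param raws list of `phare_raw`.
#' @param onto a `phare_ontology` (mutated: composition axioms may be added).
#' @return an object of class `phare_outcome` with fields:
#'   * `normalized`: list of merged `phare_relationship`s (each with an
#'     `n_sources` count of contributing raw records);
#'   * `raw_status`: one row per input (`ok`, failure `stage`/`token`, the
#'     raw surface key, and the orbit key when normalized);
#'   * `n_input`.
#' @export
integrate_relationships <- function(raws, onto) {
  stopifnot(inherits(onto, "phare_ontology"))
  acc <- new.env(parent = emptyenv())
  order_keys <- character()
  n <- length(raws)
  status <- data.frame(
    idx = seq_len(n),
    ok = logical(n),
    stage = rep(NA_character_, n),
    token = rep(NA_character_, n),
    surface = rep(NA_character_, n),
    orbit = rep(NA_character_, n),
    pmid = rep(NA_character_, n),
    sentence = rep(NA_character_, n),
    raw_type = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    raw <- raws[[i]]
    stopifnot(inherits(raw, "phare_raw"))
    status$surface[i] <- raw_surface_key(raw)
    status$pmid[i] <- raw$pmid
    status$sentence[i] <- raw$sentence
    status$raw_type[i] <- raw$raw_type
    subj <- normalize_entity(raw$subject_tokens, onto)
    if (is_failure(subj)) {
      status$stage[i] <- subj$stage; status$token[i] <- subj$token
      next
    }
    obj <- normalize_entity(raw$object_tokens, onto)
    if (is_failure(obj)) {
      status$stage[i] <- obj$stage; status$token[i] <- obj$token
      next
    }
    ty <- normalize_type(raw$raw_type, onto)
    if (is_failure(ty)) {
      status$stage[i] <- ty$stage; status$token[i] <- ty$token
      next
    }
    prov <- data.frame(pmid = raw$pmid, sentence = raw$sentence,
                       stringsAsFactors = FALSE)
    rels <- assemble(onto, ty$role, subj, obj, prov)
    for (rel in rels) {
      key <- triple_key(rel$role, rel$subject_id, rel$object_id)
      if (is.null(acc[[key]])) {
        rel$n_sources <- 1L
        acc[[key]] <- rel
        order_keys <- c(order_keys, key)
      } else {
        old <- acc[[key]]
        merged <- rbind(old$provenance, rel$provenance)
        old$provenance <- merged[!duplicated(paste(merged$pmid, merged$sentence)), ,
                                 drop = FALSE]
        old$derived_by_inverse <- old$derived_by_inverse && rel$derived_by_inverse
        old$n_sources <- old$n_sources + 1L
        acc[[key]] <- old
      }
    }
    status$ok[i] <- TRUE
    status$orbit[i] <- orbit_key(onto, rels[[1]]$role,
                                 rels[[1]]$subject_id, rels[[1]]$object_id)
  }
  normalized <- lapply(sort(order_keys), function(k) acc[[k]])
  structure(
    list(normalized = normalized, raw_status = status, n_input = n),
    class = "phare_outcome"
  )
}

#' @export
print.phare_outcome <- function(x, ...) {
  cat(sprintf(
    "<phare_outcome: %d raw in, %d normalized triples (%d expressions), %d failed>\n",
    x$n_input, length(x$normalized), length(distinct_expressions(x)),
    sum(!x$raw_status$ok)
  ))
  invisible(x)
}

#' Distinct normalized expressions of an outcome
#'
#' An inverse pair of triples counts as one expression (the Figure-style "4
#' raw relationships normalize to 2 expressions" count).
#'
#' @param outcome a `phare_outcome`.
#' @return character vector of orbit keys.
#' @export
distinct_expressions <- function(outcome) {
  stopifnot(inherits(outcome, "phare_outcome"))
  unique(stats::na.omit(outcome$raw_status$orbit))
}

#' Render normalized relationships back to raw surface form
#'
#' Preferred labels only; used to check idempotence of the pipeline. Derived
#' twins are skipped (they are re-created by assembly).
#'
#' @param outcome a `phare_outcome`.
#' @param onto the ontology.
#' @return list of `phare_raw`.
#' @export
surface_raws <- function(outcome, onto) {
  rels <- Filter(function(r) !r$derived_by_inverse, outcome$normalized)
  lapply(rels, function(r) {
    raw_relationship(
      raw_type = onto$roles[[r$role]]$labels[[1]],
      subject_tokens = entity_surface(r$subject, onto),
      object_tokens = entity_surface(r$object, onto),
      pmid = r$provenance$pmid[[1]],
      sentence = r$provenance$sentence[[1]]
    )
  })
}

#' Curation report over un-normalized relationships
#'
#' Frequency-ranked unmatched raw types and unmatched modifier/key tokens,
#' each with an example sentence, for curator review during ontology
#' refinement. Ties are broken lexicographically.
#'
#' @param outcome a `phare_outcome`.
#' @param top_n keep at most this many rows (default all).
#' @return data frame with columns `kind` (`"role"` or `"term"`), `term`,
#'   `count`, `example`.
#' @export
refinement_report <- function(outcome, top_n = Inf) {
  stopifnot(inherits(outcome, "phare_outcome"))
  st <- outcome$raw_status
  bad <- st[!st$ok & !is.na(st$stage), , drop = FALSE]
  if (!nrow(bad)) {
    return(data.frame(kind = character(), term = character(),
                      count = integer(), example = character(),
                      stringsAsFactors = FALSE))
  }
  bad$kind <- ifelse(bad$stage == "type", "role", "term")
  key <- paste(bad$kind, tolower(bad$token), sep = "|")
  agg <- lapply(split(bad, key), function(g) {
    data.frame(kind = g$kind[[1]], term = tolower(g$token[[1]]),
               count = nrow(g), example = g$sentence[[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$count, out$term), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
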