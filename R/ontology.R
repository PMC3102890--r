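#' The relationship ontology
#'
#' An ontology bundles three vocabularies used to normalize text-mined
#' pharmacogenomic relationships:
#'
#' * *entity types*: a subsumption hierarchy of classes such as `Expression`
#'   or `DrugDose`, each carrying an ordered label set (the first label is the
#'   preferred one) and optionally a *modifier restriction*: the key category
#'   `X` in the pattern "exists modified.X" that scopes ambiguous labels
#'   ("gene level" is an expression, "drug level" is a dose);
#' * *roles*: relation types such as `inhibits`, each with an ordered label
#'   set (surface verbs, past tense, and passive-voice forms marked with the
#'   opaque `$$` separator), an optional parent role, an optional inverse
#'   role, and a symmetry flag;
#' * a *key-entity lexicon*: genes, drugs and phenotypes with synonyms,
#'   preferred names and external identifiers (Entrez Gene, DrugBank, MeSH).
#'
#' The object has reference semantics (an environment): normalization appends
#' composition axioms to it as a side effect.
#'
#' @return an object of class `phare_ontology`.
#' @seealso [add_entity_type()], [add_role()], [add_key_entity()],
#'   [validate_ontology()], [load_ontology()]
#' @export
phare_ontology <- function() {
  onto <- new.env(parent = emptyenv())
  onto$entity_types <- list()
  onto$roles <- list()
  onto$lexicon <- list()
  onto$axioms <- list()
  onto$stale <- TRUE
  class(onto) <- "phare_ontology"
  onto
}

#' @export
print.phare_ontology <- function(x, ...) {
  cat(sprintf(
    "<phare_ontology: %d entity types, %d roles, %d key entities, %d composition axioms>\n",
    length(x$entity_types), length(x$roles), length(x$lexicon), length(x$axioms)
  ))
  invisible(x)
}

#' Define an entity type
#'
#' @param id identifier (IRI-safe, no spaces).
#' @param labels character vector of labels; the first is the preferred label.
#' @param parents character vector of parent entity-type ids (subsumption).
#' @param modifier_category optional key category (`"Gene"`, `"Drug"` or
#'   `"Phenotype"`) scoping this type's labels: the type only matches a
#'   modifier word when the composite entity is anchored in that category.
#' @return a list of class `phare_entity_type`.
#' @export
entity_type <- function(id, labels, parents = character(), modifier_category = NULL) {
  stopifnot(is_scalar_string(id), is.character(labels), length(labels) >= 1)
  if (!is.null(modifier_category)) {
    modifier_category <- match.arg(modifier_category, key_categories())
  }
  structure(
    list(id = id, labels = labels, parents = as.character(parents),
         modifier_category = modifier_category),
    class = "phare_entity_type"
  )
}

#' Define a role
#'
#' @param id identifier; by convention the preferred label in camelCase.
#' @param labels character vector of labels (first = preferred). Labels may
#'   contain the `$$` voice separator (e.g. `"is$$inhibited"`); `$$` is
#'   treated as opaque text inserted by the upstream extractor.
#' @param parent optional parent role id.
#' @param inverse optional inverse role id (must be reciprocal).
#' @param symmetric logical; a role may not be both symmetric and have a
#'   distinct inverse.
#' @return a list of class `phare_role`.
#' @export
role <- function(id, labels, parent = NULL, inverse = NULL, symmetric = FALSE) {
  stopifnot(is_scalar_string(id), is.character(labels), length(labels) >= 1,
            is.logical(symmetric), length(symmetric) == 1)
  structure(
    list(id = id, labels = labels, parent = parent, inverse = inverse,
         symmetric = symmetric),
    class = "phare_role"
  )
}

#' Define a key entity (lexicon entry)
#'
#' @param id identifier; defaults to the `=`-encoded lowercase preferred name.
#' @param preferred_name the preferred surface name.
#' @param synonyms character vector of synonyms; the preferred name is added
#'   if absent.
#' @param category one of `"Gene"`, `"Drug"`, `"Phenotype"`.
#' @param external_ids named character vector of external identifiers;
#'   recognised names are `entrez`, `drugbank`, `mesh`.
#' @return a list of class `phare_key_entity`.
#' @export
key_entity <- function(preferred_name, category, synonyms = character(),
                       external_ids = character(), id = NULL) {
  category <- match.arg(category, key_categories())
  stopifnot(is_scalar_string(preferred_name))
  if (!(tolower(preferred_name) %in% tolower(synonyms))) {
    synonyms <- c(preferred_name, synonyms)
  }
  id <- id %||% encode_local_name(tolower(preferred_name))
  structure(
    list(id = id, preferred_name = preferred_name,
         synonyms = as.character(synonyms), category = category,
         external_ids = external_ids),
    class = "phare_key_entity"
  )
}

#' @export
key_categories <- function() c("Gene", "Drug", "Phenotype")

#' Add components to an ontology
#'
#' These mutate the ontology in place (it has reference semantics) and
#' return it invisibly.
#'
#' @param onto a `phare_ontology`.
#' @param x an [entity_type()], [role()] or [key_entity()].
#' @name ontology-add
NULL

#' @rdname ontology-add
#' @export
add_entity_type <- function(onto, x) {
  stopifnot(inherits(onto, "phare_ontology"), inherits(x, "phare_entity_type"))
  onto$entity_types[[x$id]] <- x
  onto$stale <- TRUE
  invisible(onto)
}

#' @rdname ontology-add
#' @export
add_role <- function(onto, x) {
  stopifnot(inherits(onto, "phare_ontology"), inherits(x, "phare_role"))
  onto$roles[[x$id]] <- x
  onto$stale <- TRUE
  invisible(onto)
}

#' @rdname ontology-add
#' @export
add_key_entity <- function(onto, x) {
  stopifnot(inherits(onto, "phare_ontology"), inherits(x, "phare_key_entity"))
  onto$lexicon[[x$id]] <- x
  onto$stale <- TRUE
  invisible(onto)
}

#' Record a composition axiom
#'
#' When normalization first observes an outer entity type wrapping an inner
#' entity type (e.g. a `Variation` of a `DrugDose`), the composed class --
#' the outer type restricted to things modified by the inner type -- is
#' asserted to be a subclass of the outer type. The axiom is appended once
#' per (outer, inner) pair.
#'
#' @param onto a `phare_ontology`.
#' @param outer,inner entity-type ids.
#' @return `TRUE` invisibly if the axiom was new, `FALSE` if already present.
#' @export
add_composition_axiom <- function(onto, outer, inner) {
  stopifnot(inherits(onto, "phare_ontology"))
  key <- paste(outer, inner, sep = "|")
  have <- vapply(onto$axioms, function(a) paste(a$outer, a$inner, sep = "|"),
                 character(1))
  if (key %in% have) return(invisible(FALSE))
  onto$axioms[[length(onto$axioms) + 1L]] <- list(outer = outer, inner = inner)
  invisible(TRUE)
}

# Rebuild the label/synonym lookup indexes if stale.
reindex <- function(onto) {
  if (!isTRUE(onto$stale)) return(invisible(onto))
  role_idx <- list()
  for (r in onto$roles) {
    for (lab in tolower(r$labels)) {
      role_idx[[lab]] <- unique(c(role_idx[[lab]], r$id))
    }
  }
  type_idx <- list()
  for (t in onto$entity_types) {
    for (lab in tolower(t$labels)) {
      type_idx[[lab]] <- unique(c(type_idx[[lab]], t$id))
    }
  }
  syn_idx <- list()
  for (k in onto$lexicon) {
    for (s in tolower(k$synonyms)) {
      syn_idx[[s]] <- unique(c(syn_idx[[s]], k$id))
    }
  }
  onto$idx <- list(role = role_idx, type = type_idx, syn = syn_idx)
  onto$stale <- FALSE
  invisible(onto)
}

#' Resolve a token span against the key-entity lexicon
#'
#' Case-insensitive synonym lookup, so that e.g. `"coumadin"` resolves to the
#' key entity whose preferred name is `warfarin`.
#'
#' @param onto a `phare_ontology`.
#' @param span the surface string (possibly multiword).
#' @return the matching `phare_key_entity`, or `NULL` when no synonym matches.
#'   A synonym shared by two key entities raises a condition of class
#'   `phare_ambiguity`, carrying the candidate ids.
#' @export
resolve_key_entity <- function(onto, span) {
  reindex(onto)
  ids <- onto$idx$syn[[tolower(trimws(span))]]
  if (is.null(ids)) return(NULL)
  if (length(ids) > 1) {
    phare_error(
      sprintf("synonym '%s' is ambiguous between key entities: %s",
              span, paste(ids, collapse = ", ")),
      class = "phare_ambiguity", candidates = ids
    )
  }
  onto$lexicon[[ids]]
}

#' Find the entity type owning a modifier word
#'
#' Matching is case-insensitive with a pluralization fallback (a trailing
#' `"s"` or `"es"` is stripped and the lookup retried). When several entity
#' types share the label, the anchor's key category selects the type whose
#' modifier restriction it satisfies; failing that, a single unscoped type is
#' accepted.
#'
#' @param onto a `phare_ontology`.
#' @param word the modifier word.
#' @param modifier_category optional key category of the composite entity's
#'   anchor, used to disambiguate shared labels.
#' @return the matching `phare_entity_type`, or `NULL`. Unresolvable shared
#'   labels raise a `phare_ambiguity` condition (routed to the curation
#'   report by callers).
#' @export
find_entity_type <- function(onto, word, modifier_category = NULL) {
  reindex(onto)
  for (v in label_variants(word)) {
    ids <- onto$idx$type[[v]]
    if (is.null(ids)) next
    if (length(ids) == 1) return(onto$entity_types[[ids]])
    cats <- vapply(ids, function(i) {
      onto$entity_types[[i]]$modifier_category %||% NA_character_
    }, character(1))
    if (!is.null(modifier_category)) {
      hit <- ids[!is.na(cats) & cats == modifier_category]
      if (length(hit) == 1) return(onto$entity_types[[hit]])
    }
    hit <- ids[is.na(cats)]
    if (length(hit) == 1) return(onto$entity_types[[hit]])
    phare_error(
      sprintf("label '%s' is ambiguous between entity types %s (category %s)",
              word, paste(ids, collapse = ", "),
              modifier_category %||% "<none>"),
      class = "phare_ambiguity", candidates = ids
    )
  }
  NULL
}

#' Find the role owning a raw relationship-type string
#'
#' Case-insensitive exact match (the `$$` voice separator included) with the
#' same pluralization fallback as [find_entity_type()], so `"represses"`
#' finds the role labelled `"repress"`.
#'
#' @param onto a `phare_ontology`.
#' @param raw_type the raw relationship-type string.
#' @return the matching `phare_role` or `NULL`.
#' @export
find_role <- function(onto, raw_type) {
  reindex(onto)
  for (v in label_variants(raw_type)) {
    ids <- onto$idx$role[[v]]
    if (is.null(ids)) next
    if (length(ids) > 1) {
      phare_error(
        sprintf("role label '%s' belongs to several roles: %s",
                raw_type, paste(ids, collapse = ", ")),
        class = "phare_ambiguity", candidates = ids
      )
    }
    return(onto$roles[[ids]])
  }
  NULL
}

#' Test subsumption between entity types
#'
#' Reflexive-transitive reachability over the `parents` links, e.g.
#' `Expression` is subsumed by `Phenotype`.
#'
#' @param onto a `phare_ontology`.
#' @param ancestor,descendant entity-type ids.
#' @return logical.
#' @export
subsumes <- function(onto, ancestor, descendant) {
  stopifnot(inherits(onto, "phare_ontology"))
  if (is.null(onto$entity_types[[ancestor]]) ||
      is.null(onto$entity_types[[descendant]])) {
    phare_error(sprintf("unknown entity type(s): %s / %s", ancestor, descendant),
                class = "phare_lookup_error")
  }
  frontier <- descendant
  seen <- character()
  while (length(frontier)) {
    cur <- frontier[[1]]
    frontier <- frontier[-1]
    if (cur == ancestor) return(TRUE)
    if (cur %in% seen) next
    seen <- c(seen, cur)
    et <- onto$entity_types[[cur]]
    if (!is.null(et)) frontier <- c(frontier, et$parents)
  }
  FALSE
}

# All ancestors of an entity type (reflexive closure), as a character vector.
type_ancestors <- function(onto, id) {
  frontier <- id
  seen <- character()
  while (length(frontier)) {
    cur <- frontier[[1]]
    frontier <- frontier[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    et <- onto$entity_types[[cur]]
    if (!is.null(et)) frontier <- c(frontier, et$parents)
  }
  seen
}

#' Validate ontology structure
#'
#' Checks the structural rules the normalization algorithm relies on:
#'
#' * each role label belongs to exactly one role;
#' * each entity-type label belongs to exactly one type within a modifier
#'   scope;
#' * the subsumption graph is acyclic and parent/inverse references resolve;
#' * inverses are involutive (`inverse(inverse(r)) == r`);
#' * no role is both symmetric and paired with a distinct inverse;
#' * lexicon entries carry a valid category and contain their preferred name
#'   among their synonyms.
#'
#' @param onto a `phare_ontology`.
#' @return a data frame with columns `rule` and `detail`; zero rows mean the
#'   ontology is valid.
#' @export
validate_ontology <- function(onto) {
  stopifnot(inherits(onto, "phare_ontology"))
  rule <- character()
  detail <- character()
  note <- function(r, d) {
    rule <<- c(rule, r)
    detail <<- c(detail, d)
  }

  # role label injectivity
  owners <- list()
  for (r in onto$roles) {
    for (lab in tolower(r$labels)) owners[[lab]] <- c(owners[[lab]], r$id)
  }
  for (lab in names(owners)) {
    if (length(unique(owners[[lab]])) > 1) {
      note("role-label-unique",
           sprintf("label '%s' belongs to roles %s", lab,
                   paste(unique(owners[[lab]]), collapse = ", ")))
    }
  }

  # entity label injectivity within modifier scope
  towners <- list()
  for (t in onto$entity_types) {
    scope <- t$modifier_category %||% "<unscoped>"
    for (lab in tolower(t$labels)) {
      k <- paste(scope, lab, sep = "|")
      towners[[k]] <- c(towners[[k]], t$id)
    }
  }
  for (k in names(towners)) {
    if (length(unique(towners[[k]])) > 1) {
      note("type-label-unique-in-scope",
           sprintf("scoped label '%s' belongs to types %s", k,
                   paste(unique(towners[[k]]), collapse = ", ")))
    }
  }

  # parent references + acyclicity (entity types)
  ids <- names(onto$entity_types)
  for (t in onto$entity_types) {
    for (p in t$parents) {
      if (!(p %in% ids)) {
        note("type-parent-exists",
             sprintf("type %s has unknown parent %s", t$id, p))
      }
    }
  }
  color <- stats::setNames(rep(0L, length(ids)), ids) # 0 white, 1 grey, 2 black
  visit <- function(v, path) {
    if (!(v %in% ids)) return()
    if (color[[v]] == 1L) {
      note("type-acyclic",
           sprintf("subsumption cycle through %s",
                   paste(c(path, v), collapse = " -> ")))
      return()
    }
    if (color[[v]] == 2L) return()
    color[[v]] <<- 1L
    for (p in onto$entity_types[[v]]$parents) visit(p, c(path, v))
    color[[v]] <<- 2L
  }
  for (v in ids) visit(v, character())

  # role references, involution, symmetry conflicts
  rids <- names(onto$roles)
  for (r in onto$roles) {
    if (!is.null(r$parent) && !(r$parent %in% rids)) {
      note("role-parent-exists",
           sprintf("role %s has unknown parent %s", r$id, r$parent))
    }
    if (!is.null(r$inverse)) {
      if (!(r$inverse %in% rids)) {
        note("role-inverse-exists",
             sprintf("role %s has unknown inverse %s", r$id, r$inverse))
      } else {
        back <- onto$roles[[r$inverse]]$inverse
        if (is.null(back) || back != r$id) {
          note("role-inverse-involutive",
               sprintf("inverse(%s) = %s but inverse(%s) = %s",
                       r$id, r$inverse, r$inverse, back %||% "<none>"))
        }
      }
      if (isTRUE(r$symmetric) && r$inverse != r$id) {
        note("role-symmetric-vs-inverse",
             sprintf("role %s is symmetric yet has distinct inverse %s",
                     r$id, r$inverse))
      }
    }
  }

  # lexicon sanity
  for (k in onto$lexicon) {
    if (!(k$category %in% key_categories())) {
      note("lexicon-category",
           sprintf("key entity %s has category %s", k$id, k$category))
    }
    if (!(tolower(k$preferred_name) %in% tolower(k$synonyms))) {
      note("lexicon-preferred-in-synonyms",
           sprintf("key entity %s lacks its preferred name among synonyms", k$id))
    }
  }

  data.frame(rule = rule, detail = detail, stringsAsFactors = FALSE)
}

#' Label-count summary used by the evaluation metrics
#'
#' @param onto a `phare_ontology`.
#' @return list with `n_entity_types`, `n_roles`, `labels_per_entity_type`,
#'   `labels_per_role` (arithmetic means of label-set sizes).
#' @export
label_stats <- function(onto) {
  stopifnot(inherits(onto, "phare_ontology"))
  if (!length(onto$entity_types) && !length(onto$roles)) {
    phare_error("label statistics are undefined on an empty ontology",
                class = "phare_empty_error")
  }
  nt <- vapply(onto$entity_types, function(t) length(t$labels), integer(1))
  nr <- vapply(onto$roles, function(r) length(r$labels), integer(1))
  list(
    n_entity_types = length(nt),
    n_roles = length(nr),
    labels_per_entity_type = if (length(nt)) mean(nt) else NA_real_,
    labels_per_role = if (length(nr)) mean(nr) else NA_real_
  )
}
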