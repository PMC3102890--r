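# Ontology serialization.
#
# Entity types are owl:Class subjects, roles are owl:ObjectProperty
# subjects (owl:SymmetricProperty in addition when symmetric). All labels
# are rdfs:label statements in order; the first is the preferred name.
# Modifier restrictions use the standard existential pattern
#   phare:DrugDose rdfs:subClassOf [ ... owl:someValuesFrom phare:Drug ] .
# and composition axioms observed during normalization the mirrored form
#   [ ... owl:someValuesFrom phare:DrugDose ] rdfs:subClassOf phare:Variation .

ontology_statements <- function(onto) {
  s <- character(); p <- character(); o <- character()
  emit <- function(su, pr, ob) {
    s <<- c(s, su); p <<- c(p, pr); o <<- c(o, ob)
  }
  for (id in sort(names(onto$entity_types))) {
    t <- onto$entity_types[[id]]
    iri <- paste0("phare:", t$id)
    emit(iri, "rdf:type", "owl:Class")
    for (lab in t$labels) emit(iri, "rdfs:label", ttl_literal(lab))
    for (par in t$parents) emit(iri, "rdfs:subClassOf", paste0("phare:", par))
    if (!is.null(t$modifier_category)) {
      emit(iri, "rdfs:subClassOf",
           restriction_term(paste0("phare:", t$modifier_category)))
    }
  }
  for (id in sort(names(onto$roles))) {
    r <- onto$roles[[id]]
    iri <- paste0("phare:", r$id)
    emit(iri, "rdf:type", "owl:ObjectProperty")
    if (isTRUE(r$symmetric)) emit(iri, "rdf:type", "owl:SymmetricProperty")
    for (lab in r$labels) emit(iri, "rdfs:label", ttl_literal(lab))
    if (!is.null(r$parent)) {
      emit(iri, "rdfs:subPropertyOf", paste0("phare:", r$parent))
    }
    if (!is.null(r$inverse)) {
      emit(iri, "owl:inverseOf", paste0("phare:", r$inverse))
    }
  }
  for (ax in onto$axioms) {
    emit(restriction_term(paste0("phare:", ax$inner)),
         "rdfs:subClassOf", paste0("phare:", ax$outer))
  }
  statement_df(s, p, o)
}

#' Save an ontology to Turtle or N-Triples
#'
#' @param onto a validated `phare_ontology` (the lexicon is saved separately;
#'   see [write_lexicon()]).
#' @param path output file.
#' @param format `"turtle"` (default) or `"ntriples"`.
#' @return the path, invisibly.
#' @export
save_ontology <- function(onto, path, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  rep <- validate_ontology(onto)
  if (nrow(rep)) {
    phare_error(paste0("refusing to save an invalid ontology:\n",
                       paste(rep$detail, collapse = "\n")),
                class = "phare_validation_error", report = rep)
  }
  write_statements(ontology_statements(onto), path, format)
}

#' Load an ontology from Turtle or N-Triples
#'
#' Inverse of [save_ontology()]: the round-trip is the identity on the axiom
#' set (statement multiset). The loaded ontology is validated; violations
#' raise a `phare_validation_error` listing them.
#'
#' @param path ontology file.
#' @param lexicon optional path to a lexicon TSV to attach (see
#'   [read_lexicon()]).
#' @param format ignored; the dialect is detected from the content.
#' @return a `phare_ontology`.
#' @export
load_ontology <- function(path, lexicon = NULL, format = NULL) {
  df <- read_statements(path)
  onto <- phare_ontology()
  if (nrow(df)) {
    local_of <- function(x) sub("^phare:", "", x)
    subj <- df$s
    named <- !startsWith(subj, "[")
    kinds <- df[df$p == "rdf:type" & named, , drop = FALSE]
    class_ids <- local_of(kinds$s[kinds$o == "owl:Class"])
    role_ids <- local_of(kinds$s[kinds$o == "owl:ObjectProperty"])
    sym_ids <- local_of(kinds$s[kinds$o == "owl:SymmetricProperty"])
    for (id in unique(class_ids)) {
      iri <- paste0("phare:", id)
      rows <- df[df$s == iri, , drop = FALSE]
      labels <- literal_value(rows$o[rows$p == "rdfs:label"])
      sup <- rows$o[rows$p == "rdfs:subClassOf"]
      restr <- sup[startsWith(sup, "[")]
      parents <- local_of(sup[!startsWith(sup, "[")])
      cat <- NULL
      if (length(restr)) cat <- local_of(restriction_inner(restr[[1]]))
      if (!length(labels)) {
        phare_error(sprintf("entity type %s has no rdfs:label", id),
                    class = "phare_format_error")
      }
      add_entity_type(onto, entity_type(id, labels, parents, cat))
    }
    for (id in unique(role_ids)) {
      iri <- paste0("phare:", id)
      rows <- df[df$s == iri, , drop = FALSE]
      labels <- literal_value(rows$o[rows$p == "rdfs:label"])
      parent <- local_of(rows$o[rows$p == "rdfs:subPropertyOf"])
      inverse <- local_of(rows$o[rows$p == "owl:inverseOf"])
      if (!length(labels)) {
        phare_error(sprintf("role %s has no rdfs:label", id),
                    class = "phare_format_error")
      }
      add_role(onto, role(
        id, labels,
        parent = if (length(parent)) parent[[1]] else NULL,
        inverse = if (length(inverse)) inverse[[1]] else NULL,
        symmetric = id %in% sym_ids
      ))
    }
    comp <- df[startsWith(df$s, "[") & df$p == "rdfs:subClassOf", , drop = FALSE]
    for (i in seq_len(nrow(comp))) {
      add_composition_axiom(onto,
                            outer = local_of(comp$o[[i]]),
                            inner = local_of(restriction_inner(comp$s[[i]])))
    }
  }
  if (!is.null(lexicon)) {
    for (k in read_lexicon(lexicon)) add_key_entity(onto, k)
  }
  rep <- validate_ontology(onto)
  if (nrow(rep)) {
    phare_error(paste0("ontology fails validation:\n",
                       paste(sprintf("- [%s] %s", rep$rule, rep$detail),
                             collapse = "\n")),
                class = "phare_validation_error", report = rep)
  }
  onto
}

#' Compare two ontologies on their axiom sets
#'
#' @param a,b `phare_ontology` objects.
#' @return logical: identical statement multisets and lexicons.
#' @export
ontology_equal <- function(a, b) {
  fmt <- function(onto) {
    df <- ontology_statements(onto)
    sort(sprintf("%s %s %s", df$s, df$p, df$o))
  }
  lex <- function(onto) {
    sort(vapply(onto$lexicon, function(k) {
      paste(k$id, k$preferred_name, paste(sort(tolower(k$synonyms)), collapse = "|"),
            k$category, sep = "\t")
    }, character(1)))
  }
  identical(fmt(a), fmt(b)) && identical(lex(a), lex(b))
}

#' Read / write the key-entity lexicon
#'
#' Tab-separated with columns `id`, `preferred_name`, `synonyms`
#' (pipe-delimited), `category`, `entrez`, `drugbank`, `mesh`.
#'
#' @param path TSV file.
#' @return `read_lexicon` returns a list of `phare_key_entity`.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("id", "preferred_name", "synonyms", "category")
  if (!all(need %in% names(df))) {
    phare_error(sprintf("lexicon is missing columns: %s",
                        paste(setdiff(need, names(df)), collapse = ", ")),
                class = "phare_format_error")
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ext <- character()
    for (src in c("entrez", "drugbank", "mesh")) {
      v <- df[[src]][i] %||% ""
      if (!is.null(v) && !is.na(v) && nzchar(v)) ext[[src]] <- v
    }
    out[[i]] <- key_entity(
      preferred_name = df$preferred_name[i],
      category = df$category[i],
      synonyms = strsplit(df$synonyms[i], "|", fixed = TRUE)[[1]],
      external_ids = ext,
      id = df$id[i]
    )
  }
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}

#' @rdname read_lexicon
#' @param lexicon list of `phare_key_entity` (or a `phare_ontology`, whose
#'   lexicon is used).
#' @export
write_lexicon <- function(lexicon, path) {
  if (inherits(lexicon, "phare_ontology")) lexicon <- lexicon$lexicon
  get_ext <- function(k, src) {
    v <- k$external_ids[src]
    if (length(v) && !is.na(v)) unname(v) else ""
  }
  df <- data.frame(
    id = vapply(lexicon, `[[`, character(1), "id"),
    preferred_name = vapply(lexicon, `[[`, character(1), "preferred_name"),
    synonyms = vapply(lexicon, function(k) paste(k$synonyms, collapse = "|"),
                      character(1)),
    category = vapply(lexicon, `[[`, character(1), "category"),
    entrez = vapply(lexicon, get_ext, character(1), "entrez"),
    drugbank = vapply(lexicon, get_ext, character(1), "drugbank"),
    mesh = vapply(lexicon, get_ext, character(1), "mesh"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
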