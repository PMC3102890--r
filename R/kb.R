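#' Knowledge-base container
#'
#' A `phare_kb` holds a set of triples (role instantiations between
#' individuals, plus `rdf:type` typing triples) and an individuals registry
#' (types, display label, external identifiers). Asserted role triples carry
#' sentence-level provenance as (pmid, sentence) pairs; inferred triples are
#' flagged and share the provenance of the triples they derive from.
#'
#' Internally `triples` is a data frame with columns `subject`, `predicate`,
#' `object`, `kind` (`"role"` or `"type"`), `inferred`, `derived` (asserted
#' via an inverse expansion at normalization time) and a `provenance` list
#' column of data frames.
#'
#' @name phare_kb
NULL

new_kb <- function(triples, individuals) {
  structure(list(triples = triples, individuals = individuals),
            class = "phare_kb")
}

empty_triples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), kind = character(),
             inferred = logical(), derived = logical(),
             provenance = I(list()), stringsAsFactors = FALSE)
}

#' @export
print.phare_kb <- function(x, ...) {
  cat(sprintf(
    "<phare_kb: %d role triples (%d inferred), %d typing triples, %d individuals>\n",
    sum(x$triples$kind == "role"),
    sum(x$triples$kind == "role" & x$triples$inferred),
    sum(x$triples$kind == "type"), length(x$individuals)
  ))
  invisible(x)
}

kb_has_triple <- function(kb, s, p, o) {
  any(kb$triples$subject == s & kb$triples$predicate == p & kb$triples$object == o)
}

add_triple <- function(kb, s, p, o, kind, inferred, derived = FALSE,
                       provenance = NULL) {
  row <- data.frame(subject = s, predicate = p, object = o, kind = kind,
                    inferred = inferred, derived = derived,
                    stringsAsFactors = FALSE)
  row$provenance <- list(provenance %||%
    data.frame(pmid = character(), sentence = character(),
               stringsAsFactors = FALSE))
  kb$triples <- rbind(kb$triples, row)
  kb
}

register_individual <- function(kb, id, label, types = character(),
                                external_ids = character()) {
  cur <- kb$individuals[[id]] %||%
    list(id = id, label = label, types = character(), external_ids = character())
  cur$types <- unique(c(cur$types, types))
  if (length(external_ids)) {
    cur$external_ids <- external_ids
  }
  kb$individuals[[id]] <- cur
  kb
}

#' Build a knowledge base from a normalization outcome
#'
#' Each normalized relationship becomes one asserted role triple (those
#' created by inverse expansion are flagged `derived` but remain asserted,
#' matching the convention that the materialized KB counts both directions).
#' Individuals are registered with their most specific entity type; key
#' entities get their external identifiers from the lexicon.
#'
#' @param outcome a `phare_outcome` from [integrate_relationships()].
#' @param onto the ontology the outcome was produced with.
#' @return a `phare_kb`.
#' @export
build_kb <- function(outcome, onto) {
  stopifnot(inherits(outcome, "phare_outcome"), inherits(onto, "phare_ontology"))
  kb <- new_kb(empty_triples(), list())
  seen_type <- character()
  reg_entity <- function(kb, ne, id) {
    ty <- entity_type_of(ne, onto)
    if (is.null(onto$entity_types[[ty]])) {
      phare_error(sprintf("individual %s references unknown entity type %s", id, ty),
                  class = "phare_consistency_error")
    }
    ext <- character()
    label <- decode_local_name(id)
    if (ne$kind == "key") {
      k <- onto$lexicon[[ne$key]]
      ext <- k$external_ids
      label <- k$preferred_name
    }
    kb <- register_individual(kb, id, label, ty, ext)
    tkey <- paste(id, ty)
    if (!(tkey %in% seen_type)) {
      seen_type <<- c(seen_type, tkey)
      kb <- add_triple(kb, id, "rdf:type", ty, kind = "type", inferred = FALSE)
    }
    # register the chain's inner individuals too, so `modified` targets exist
    if (ne$kind == "typed") {
      kb <- reg_entity(kb, ne$modified, entity_id(ne$modified, onto))
    }
    kb
  }
  for (rel in outcome$normalized) {
    if (is.null(onto$roles[[rel$role]])) {
      phare_error(sprintf("normalized relationship uses unknown role %s", rel$role),
                  class = "phare_consistency_error")
    }
    kb <- reg_entity(kb, rel$subject, rel$subject_id)
    kb <- reg_entity(kb, rel$object, rel$object_id)
    kb <- add_triple(kb, rel$subject_id, rel$role, rel$object_id,
                     kind = "role", inferred = FALSE,
                     derived = rel$derived_by_inverse,
                     provenance = rel$provenance)
  }
  kb
}

#' Materialize inferred triples
#'
#' Computes the closure the SPARQL endpoint of the original system relied
#' on, so that queries see asserted as well as inferred facts:
#'
#' 1. typing triples for all supertypes via subsumption (an `Expression`
#'    individual is also a `Phenotype`);
#' 2. the inverse role triple for any asserted triple whose inverse is
#'    absent;
#' 3. the symmetric swap for symmetric roles.
#'
#' Additions are flagged `inferred` and share the source triple's
#' provenance. The operation is a monotone, idempotent closure.
#'
#' @param kb a `phare_kb`.
#' @param onto the ontology.
#' @return the materialized `phare_kb`.
#' @export
materialize <- function(kb, onto) {
  stopifnot(inherits(kb, "phare_kb"), inherits(onto, "phare_ontology"))
  repeat {
    changed <- FALSE
    tr <- kb$triples
    # supertype typing
    for (i in which(tr$kind == "type")) {
      anc <- setdiff(type_ancestors(onto, tr$object[[i]]), tr$object[[i]])
      for (a in anc) {
        if (!kb_has_triple(kb, tr$subject[[i]], "rdf:type", a)) {
          kb <- add_triple(kb, tr$subject[[i]], "rdf:type", a,
                           kind = "type", inferred = TRUE)
          kb$individuals[[tr$subject[[i]]]]$types <-
            unique(c(kb$individuals[[tr$subject[[i]]]]$types, a))
          changed <- TRUE
        }
      }
    }
    # inverse and symmetric closure
    for (i in which(tr$kind == "role")) {
      r <- onto$roles[[tr$predicate[[i]]]]
      if (is.null(r)) next
      targets <- list()
      if (!is.null(r$inverse)) {
        targets[[length(targets) + 1L]] <-
          c(tr$object[[i]], r$inverse, tr$subject[[i]])
      } else if (isTRUE(r$symmetric) && tr$subject[[i]] != tr$object[[i]]) {
        targets[[length(targets) + 1L]] <-
          c(tr$object[[i]], r$id, tr$subject[[i]])
      }
      for (t in targets) {
        if (!kb_has_triple(kb, t[[1]], t[[2]], t[[3]])) {
          kb <- add_triple(kb, t[[1]], t[[2]], t[[3]], kind = "role",
                           inferred = TRUE,
                           provenance = tr$provenance[[i]])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  kb
}

#' Triple-pattern query
#'
#' Matches a `(subject, predicate, object)` pattern against all triples,
#' asserted and inferred; `NULL` positions are wildcards. This is the
#' testable core the paper's SPARQL endpoint exposes.
#'
#' @param kb a `phare_kb`.
#' @param subject,predicate,object bound values or `NULL`.
#' @return the matching rows of the triples data frame.
#' @export
kb_query <- function(kb, subject = NULL, predicate = NULL, object = NULL) {
  stopifnot(inherits(kb, "phare_kb"))
  keep <- rep(TRUE, nrow(kb$triples))
  if (!is.null(subject)) keep <- keep & kb$triples$subject == subject
  if (!is.null(predicate)) keep <- keep & kb$triples$predicate == predicate
  if (!is.null(object)) keep <- keep & kb$triples$object == object
  out <- kb$triples[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

format_provenance <- function(prov) {
  sprintf("[%s, %s]", prov$pmid, prov$sentence)
}

parse_provenance <- function(x) {
  m <- regmatches(x, regexec("^\\[([0-9]+), (.*)\\]$", x))[[1]]
  if (length(m) != 3) {
    phare_error(sprintf("malformed provenance string: %s", x),
                class = "phare_format_error")
  }
  data.frame(pmid = m[[2]], sentence = m[[3]], stringsAsFactors = FALSE)
}

#' Export / import a knowledge base as RDF
#'
#' Triples are written as plain statements; each triple additionally gets a
#' reified `rdf:Statement` carrying its provenance as `rdfs:comment` strings
#' formatted `"[PMID, sentence]"` and, for inferred triples, a
#' `phare:inferred "true"` marker. Individuals carry `rdfs:label` and
#' external-identifier statements. The round-trip is the identity on
#' (triples, provenance).
#'
#' @param kb a `phare_kb`.
#' @param path file path.
#' @param format `"turtle"` or `"ntriples"`.
#' @return `export_rdf` the path invisibly; `import_rdf` a `phare_kb`.
#' @export
export_rdf <- function(kb, path, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  s <- character(); p <- character(); o <- character()
  emit <- function(su, pr, ob) {
    s <<- c(s, su); p <<- c(p, pr); o <<- c(o, ob)
  }
  ext_preds <- c(entrez = "phare:entrezGeneId", drugbank = "phare:drugBankId",
                 mesh = "phare:meshId")
  for (id in sort(names(kb$individuals))) {
    ind <- kb$individuals[[id]]
    iri <- paste0("phare:", id)
    emit(iri, "rdfs:label", ttl_literal(ind$label))
    for (src in names(ind$external_ids)) {
      pred <- ext_preds[src]
      if (!is.na(pred)) emit(iri, pred, ttl_literal(ind$external_ids[[src]]))
    }
  }
  tr <- kb$triples
  ord <- order(tr$kind, tr$subject, tr$predicate, tr$object)
  tr <- tr[ord, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    subj <- paste0("phare:", tr$subject[[i]])
    obj <- paste0("phare:", tr$object[[i]])
    pred <- if (tr$kind[[i]] == "type") "rdf:type" else paste0("phare:", tr$predicate[[i]])
    emit(subj, pred, obj)
    st <- sprintf("phare:stmt%05d", i)
    emit(st, "rdf:type", "rdf:Statement")
    emit(st, "rdf:subject", subj)
    emit(st, "rdf:predicate", pred)
    emit(st, "rdf:object", obj)
    if (tr$inferred[[i]]) emit(st, "phare:inferred", ttl_literal("true"))
    if (tr$derived[[i]]) emit(st, "phare:derivedByInverse", ttl_literal("true"))
    prov <- tr$provenance[[i]]
    if (nrow(prov)) {
      for (cmt in format_provenance(prov)) emit(st, "rdfs:comment", ttl_literal(cmt))
    }
  }
  write_statements(statement_df(s, p, o), path, format)
}

#' @rdname export_rdf
#' @export
import_rdf <- function(path) {
  df <- read_statements(path)
  kb <- new_kb(empty_triples(), list())
  if (!nrow(df)) return(kb)
  local_of <- function(x) sub("^phare:", "", x)
  is_stmt <- grepl("^phare:stmt[0-9]+$", df$s)
  meta <- df[is_stmt, , drop = FALSE]
  body <- df[!is_stmt, , drop = FALSE]
  # reified metadata keyed by (s,p,o)
  meta_by_id <- split(meta, meta$s)
  meta_key <- list()
  for (g in meta_by_id) {
    subj <- g$o[g$p == "rdf:subject"]
    pred <- g$o[g$p == "rdf:predicate"]
    obj <- g$o[g$p == "rdf:object"]
    if (length(subj) != 1 || length(pred) != 1 || length(obj) != 1) next
    comments <- literal_value(g$o[g$p == "rdfs:comment"])
    prov <- if (length(comments)) {
      do.call(rbind, lapply(comments, parse_provenance))
    } else {
      data.frame(pmid = character(), sentence = character(),
                 stringsAsFactors = FALSE)
    }
    meta_key[[paste(subj, pred, obj)]] <- list(
      inferred = any(g$p == "phare:inferred"),
      derived = any(g$p == "phare:derivedByInverse"),
      provenance = prov
    )
  }
  ext_srcs <- c("phare:entrezGeneId" = "entrez", "phare:drugBankId" = "drugbank",
                "phare:meshId" = "mesh")
  for (i in seq_len(nrow(body))) {
    subj <- body$s[[i]]; pred <- body$p[[i]]; obj <- body$o[[i]]
    id <- local_of(subj)
    if (pred == "rdfs:label") {
      kb <- register_individual(kb, id, literal_value(obj))
      kb$individuals[[id]]$label <- literal_value(obj)
    } else if (pred %in% names(ext_srcs)) {
      kb <- register_individual(kb, id, decode_local_name(id))
      ext <- kb$individuals[[id]]$external_ids
      ext[[ext_srcs[[pred]]]] <- literal_value(obj)
      kb$individuals[[id]]$external_ids <- ext
    } else if (pred == "rdf:type") {
      ty <- local_of(obj)
      md <- meta_key[[paste(subj, pred, obj)]] %||% list(inferred = FALSE,
                                                         derived = FALSE,
                                                         provenance = NULL)
      kb <- register_individual(kb, id, decode_local_name(id), types = ty)
      kb <- add_triple(kb, id, "rdf:type", ty, kind = "type",
                       inferred = md$inferred, derived = md$derived,
                       provenance = md$provenance)
    } else {
      md <- meta_key[[paste(subj, pred, obj)]] %||% list(inferred = FALSE,
                                                         derived = FALSE,
                                                         provenance = NULL)
      kb <- register_individual(kb, id, decode_local_name(id))
      oid <- local_of(obj)
      kb <- register_individual(kb, oid, decode_local_name(oid))
      kb <- add_triple(kb, id, local_of(pred), oid, kind = "role",
                       inferred = md$inferred, derived = md$derived,
                       provenance = md$provenance)
    }
  }
  kb
}

#' Compare two knowledge bases on triples and provenance
#'
#' @param a,b `phare_kb` objects.
#' @return logical.
#' @export
kb_equal <- function(a, b) {
  fmt <- function(kb) {
    tr <- kb$triples
    keys <- vapply(seq_len(nrow(tr)), function(i) {
      prov <- tr$provenance[[i]]
      paste(tr$subject[[i]], tr$predicate[[i]], tr$object[[i]], tr$kind[[i]],
            tr$inferred[[i]], tr$derived[[i]],
            paste(sort(format_provenance(prov)), collapse = " ;; "),
            sep = " || ")
    }, character(1))
    sort(keys)
  }
  identical(fmt(a), fmt(b))
}

#' Extract a display subnetwork around a focus individual
#'
#' Role triples only (typing triples such as `x rdf:type Disease` are
#' dropped). A neighbour is kept when the number of distinct (pmid,
#' sentence) pairs supporting role triples between it and the focus is
#' strictly greater than `min_sentences` ("related in more than 5 different
#' sentences"); edges among the retained nodes are kept under the same
#' filter. Each edge is labelled with the `top_labels` most frequent role
#' preferred names on that pair (frequency = distinct supporting sentences;
#' ties lexicographic).
#'
#' @param kb a `phare_kb` (materialize first if inferred edges should count).
#' @param focus individual id.
#' @param min_sentences strict lower bound on distinct supporting sentences.
#' @param top_labels number of role labels per edge.
#' @param onto optional ontology used to map role ids to preferred labels.
#' @return an undirected `igraph` graph with vertex attribute `label` and
#'   edge attribute `label`.
#' @export
subnetwork <- function(kb, focus, min_sentences = 5, top_labels = 2,
                       onto = NULL) {
  stopifnot(inherits(kb, "phare_kb"))
  if (is.null(kb$individuals[[focus]])) {
    phare_error(sprintf("unknown focus individual: %s", focus),
                class = "phare_lookup_error")
  }
  tr <- kb$triples[kb$triples$kind == "role", , drop = FALSE]
  pair_of <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = " | ")
  stats_for_pair <- function(a, b) {
    rows <- which((tr$subject == a & tr$object == b) |
                    (tr$subject == b & tr$object == a))
    sent <- character()
    by_role <- list()
    for (i in rows) {
      prov <- tr$provenance[[i]]
      keys <- paste(prov$pmid, prov$sentence, sep = "\r")
      sent <- c(sent, keys)
      rid <- tr$predicate[[i]]
      by_role[[rid]] <- unique(c(by_role[[rid]], keys))
    }
    list(n = length(unique(sent)), by_role = by_role)
  }
  role_label <- function(rid) {
    if (!is.null(onto) && !is.null(onto$roles[[rid]])) {
      onto$roles[[rid]]$labels[[1]]
    } else {
      rid
    }
  }
  neighbours <- setdiff(unique(c(tr$object[tr$subject == focus],
                                 tr$subject[tr$object == focus])), focus)
  keep <- neighbours[vapply(neighbours, function(x) {
    stats_for_pair(focus, x)$n > min_sentences
  }, logical(1))]
  nodes <- unique(c(focus, keep))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes,
                            label = decode_local_name(nodes))
  if (length(nodes) > 1) {
    done <- character()
    for (a in nodes) for (b in nodes) {
      if (a >= b) next
      pk <- pair_of(a, b)
      if (pk %in% done) next
      done <- c(done, pk)
      st <- stats_for_pair(a, b)
      if (st$n == 0 || st$n <= min_sentences) next
      counts <- vapply(st$by_role, length, integer(1))
      labs <- vapply(names(counts), role_label, character(1))
      ord <- order(-counts, labs)
      top <- labs[ord][seq_len(min(top_labels, length(labs)))]
      g <- igraph::add_edges(g, c(a, b))
      g <- igraph::set_edge_attr(g, "label", index = igraph::ecount(g),
                                 value = paste(top, collapse = "; "))
    }
  }
  g
}

#' Write a graph to GML
#'
#' Standard GML (node/edge records with label attributes) as read by common
#' graph viewers such as Cytoscape.
#'
#' @param graph an `igraph` graph (e.g. from [subnetwork()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_gml <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  igraph::write_graph(graph, path, format = "gml")
  invisible(path)
}
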