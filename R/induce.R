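#' Frequency inventory of a raw-relationship corpus
#'
#' Exact multiset counts of raw relationship-type strings and of modifier
#' tokens in composite entities (every token after the leading key-entity
#' token, on both subject and object side). These inventories drive both the
#' semi-automatic ontology construction (top-N selection for manual review)
#' and the fully automatic induction.
#'
#' @param raws list of `phare_raw`.
#' @return list of class `phare_inventory` with named integer vectors
#'   `type_counts` and `modifier_counts`.
#' @export
count_inventory <- function(raws) {
  types <- vapply(raws, `[[`, character(1), "raw_type")
  mods <- unlist(lapply(raws, function(r) {
    c(if (length(r$subject_tokens) > 1) r$subject_tokens[-1],
      if (length(r$object_tokens) > 1) r$object_tokens[-1])
  }))
  count <- function(x) {
    if (!length(x)) return(stats::setNames(integer(0), character(0)))
    tab <- table(tolower(x))
    stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(type_counts = count(types), modifier_counts = count(mods)),
            class = "phare_inventory")
}

#' Top-n terms of an inventory
#'
#' Ranked by count descending with lexicographic tie-break.
#'
#' @param inventory a `phare_inventory`.
#' @param n how many terms to keep per list (`n >= 0`).
#' @return list with character vectors `types` and `modifiers`.
#' @export
top_terms <- function(inventory, n) {
  stopifnot(inherits(inventory, "phare_inventory"), n >= 0)
  pick <- function(counts) {
    if (!length(counts) || n == 0) return(character(0))
    ord <- order(-counts, names(counts))
    names(counts)[ord][seq_len(min(n, length(counts)))]
  }
  list(types = pick(inventory$type_counts),
       modifiers = pick(inventory$modifier_counts))
}

# Partition a vocabulary by synset co-membership.
# transitive = TRUE: connected components of the term--synset graph
# (overlapping synsets chain); FALSE: each synset is its own group and a
# term belongs to the first synset (file order) that contains it.
synset_groups <- function(vocab, synsets, transitive = TRUE) {
  vocab <- unique(tolower(vocab))
  if (!length(vocab)) return(list())
  if (transitive) {
    g <- igraph::make_empty_graph(n = length(vocab), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = vocab)
    for (ss in synsets) {
      members <- intersect(tolower(ss), vocab)
      if (length(members) > 1) {
        pairs <- utils::combn(members, 2)
        g <- igraph::add_edges(g, as.vector(pairs))
      }
    }
    comp <- igraph::components(g)
    groups <- split(vocab, comp$membership)
  } else {
    assigned <- stats::setNames(rep(NA_integer_, length(vocab)), vocab)
    gid <- 0L
    for (ss in synsets) {
      members <- intersect(tolower(ss), vocab)
      members <- members[is.na(assigned[members])]
      if (length(members)) {
        gid <- gid + 1L
        assigned[members] <- gid
      }
    }
    for (w in vocab[is.na(assigned)]) {
      gid <- gid + 1L
      assigned[[w]] <- gid
    }
    groups <- split(names(assigned), assigned)
  }
  unname(lapply(groups, function(g) sort(g)))
}

#' Induce a flat ontology from term inventories and a synonym resource
#'
#' The fully automatic (WordNet-style) construction: terms that co-occur in
#' synsets are merged into one role (for relationship-type terms) or one
#' entity type (for modifier terms). Each group's members become the
#' alternative labels; the preferred label is the lexicographically first
#' member and also serves as the identifier. The induced ontology is flat:
#' no hierarchy, no inverses, no modifier restrictions.
#'
#' @param inventory a `phare_inventory` (from [count_inventory()]).
#' @param synsets list of character-vector synsets (see [read_synsets()]).
#' @param mode `"all"` uses the full vocabulary; `"top"` restricts both
#'   vocabularies to their `n` most frequent terms first.
#' @param n top-n cut for `mode = "top"`.
#' @param transitive merge across overlapping synsets via connected
#'   components (default); `FALSE` keeps each synset a separate group.
#' @return a validated `phare_ontology`.
#' @export
induce_ontology <- function(inventory, synsets, mode = c("all", "top"),
                            n = 200, transitive = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(inventory, "phare_inventory"))
  vocab <- list(types = names(inventory$type_counts),
                modifiers = names(inventory$modifier_counts))
  if (mode == "top") vocab <- top_terms(inventory, n)
  onto <- phare_ontology()
  for (grp in synset_groups(vocab$modifiers, synsets, transitive)) {
    add_entity_type(onto, entity_type(encode_local_name(grp[[1]]), grp))
  }
  for (grp in synset_groups(vocab$types, synsets, transitive)) {
    add_role(onto, role(encode_local_name(grp[[1]]), grp))
  }
  rep <- validate_ontology(onto)
  if (nrow(rep)) {
    phare_error(paste0("induced ontology fails validation:\n",
                       paste(rep$detail, collapse = "\n")),
                class = "phare_validation_error", report = rep)
  }
  onto
}
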