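# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: union-find for synset grouping, pairwise comparison
# for duplicate counting, row-by-row scans for queries, and path search for
# subsumption.

# union-find over synset co-membership (transitive grouping oracle)
oracle_synset_groups <- function(vocab, synsets) {
  vocab <- unique(tolower(vocab))
  parent <- stats::setNames(vocab, vocab)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (ss in synsets) {
    members <- intersect(tolower(ss), vocab)
    if (length(members) > 1) {
      for (m in members[-1]) {
        ra <- find(members[[1]]); rb <- find(m)
        if (ra != rb) parent[[rb]] <- ra
      }
    }
  }
  roots <- vapply(vocab, find, character(1))
  unname(lapply(split(vocab, roots), sort))
}

# quadratic pairwise duplicate counter: class sizes by all-pairs equality
oracle_histogram <- function(keys) {
  n <- length(keys)
  if (n == 0) return(c("2-4" = 0L, "5-9" = 0L, "10+" = 0L))
  eq <- outer(keys, keys, "==")
  sizes <- rowSums(eq)
  first <- !duplicated(keys)
  mult <- sizes[first]
  c("2-4" = sum(mult >= 2 & mult < 5),
    "5-9" = sum(mult >= 5 & mult < 10),
    "10+" = sum(mult >= 10))
}

# row-by-row triple pattern scan
oracle_query <- function(triples, s = NULL, p = NULL, o = NULL) {
  hit <- logical(nrow(triples))
  for (i in seq_len(nrow(triples))) {
    ok <- TRUE
    if (!is.null(s) && triples$subject[[i]] != s) ok <- FALSE
    if (!is.null(p) && triples$predicate[[i]] != p) ok <- FALSE
    if (!is.null(o) && triples$object[[i]] != o) ok <- FALSE
    hit[[i]] <- ok
  }
  which(hit)
}

# reachability by exhaustive path enumeration over a parent map
oracle_reachable <- function(parents, from, to) {
  if (from == to) return(TRUE)
  frontier <- from
  seen <- character()
  while (length(frontier)) {
    cur <- frontier[[1]]; frontier <- frontier[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    for (p in parents[[cur]] %||% character()) {
      if (p == to) return(TRUE)
      frontier <- c(frontier, p)
    }
  }
  FALSE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random parent DAG over ids T1..Tn (edges only to lower indexes: acyclic)
random_dag_ontology <- function(n, p_edge = 0.3) {
  onto <- phare_ontology()
  ids <- paste0("T", seq_len(n))
  parents <- list()
  for (i in seq_len(n)) {
    pars <- if (i > 1) ids[which(stats::runif(i - 1) < p_edge)] else character()
    parents[[ids[[i]]]] <- pars
    add_entity_type(onto, entity_type(ids[[i]], paste0("label", i), parents = pars))
  }
  list(onto = onto, ids = ids, parents = parents)
}

fig_fixture <- function() figure_fixture()
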