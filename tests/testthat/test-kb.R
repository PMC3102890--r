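kb_fixture <- function(materialized = FALSE) {
  fx <- fig_fixture()
  out <- integrate_relationships(c(fx$raw, list(fx$uchl1_raw)), fx$ontology)
  kb <- build_kb(out, fx$ontology)
  if (materialized) kb <- materialize(kb, fx$ontology)
  list(kb = kb, onto = fx$ontology, out = out)
}

test_that("build_kb registers triples, typing and external identifiers", {
  f <- kb_fixture()
  kb <- f$kb
  # merged dose fact has two provenance sentences
  hit <- kb_query(kb, subject = "vkorc1", predicate = "influences",
                  object = "warfarin=dose")
  expect_equal(nrow(hit), 1)
  expect_equal(nrow(hit$provenance[[1]]), 2)
  # provenance formatted "[PMID, sentence]"
  assoc <- kb_query(kb, subject = "uchl1", predicate = "isAssociatedWith")
  expect_match(
    phare:::format_provenance(assoc$provenance[[1]]),
    "^\\[14522054, Neuronal ubiquitin C-terminal hydrolase \\(UCH-L1\\)",
  )
  # individuals carry lexicon identifiers and most specific types
  expect_equal(kb$individuals[["uchl1"]]$external_ids[["entrez"]], "7345")
  expect_equal(kb$individuals[["vkorc1=expression"]]$types, "Expression")
  expect_equal(nrow(kb_query(kb, subject = "parkinson=disease",
                             predicate = "rdf:type", object = "Phenotype")), 1)
  # empty outcome -> empty KB
  empty <- build_kb(integrate_relationships(list(), f$onto), f$onto)
  expect_equal(nrow(empty$triples), 0)
})

test_that("build_kb rejects dangling role references", {
  f <- kb_fixture()
  out <- f$out
  out$normalized[[1]]$role <- "noSuchRole"
  expect_error(build_kb(out, f$onto), class = "phare_consistency_error")
})

test_that("materialization infers supertype membership and is a fixpoint", {
  f <- kb_fixture()
  kbm <- materialize(f$kb, f$onto)
  # Expression(vkorc1=expression) + Expression subClassOf Phenotype
  #   => Phenotype(vkorc1=expression), flagged inferred
  inf <- kb_query(kbm, subject = "vkorc1=expression", predicate = "rdf:type",
                  object = "Phenotype")
  expect_equal(nrow(inf), 1)
  expect_true(inf$inferred)
  # asserted typing is untouched
  expect_false(kb_query(kbm, subject = "vkorc1=expression",
                        predicate = "rdf:type", object = "Expression")$inferred)
  # idempotence: a second run changes nothing
  expect_true(kb_equal(materialize(kbm, f$onto), kbm))
  # monotone: no asserted triple removed
  expect_true(nrow(kbm$triples) >= nrow(f$kb$triples))
})

test_that("materialization adds exactly one inverse per uncovered invertible triple", {
  onto <- fig_fixture()$ontology
  kb <- phare:::new_kb(phare:::empty_triples(), list())
  n <- 7
  set.seed(41)
  for (i in seq_len(n)) {
    s <- sprintf("a%02d", i); o <- sprintf("b%02d", i)
    kb <- phare:::register_individual(kb, s, s)
    kb <- phare:::register_individual(kb, o, o)
    kb <- phare:::add_triple(kb, s, sample(c("inhibits", "treats"), 1), o,
                             kind = "role", inferred = FALSE,
                             provenance = data.frame(pmid = "1", sentence = "x"))
  }
  kbm <- materialize(kb, onto)
  added <- kbm$triples[kbm$triples$inferred, , drop = FALSE]
  expect_equal(nrow(added), n)
  expect_true(all(added$predicate %in% c("isInhibitedBy", "isTreatedBy")))
  # inferred inverses share the source provenance
  expect_equal(added$provenance[[1]]$pmid, "1")
})

test_that("triple-pattern query matches the brute-force scan", {
  co <- generate_corpus(generator_config(n_facts = 25, seed = 13))
  onto <- generator_ontology()
  kb <- materialize(build_kb(integrate_relationships(co$raws, onto), onto), onto)
  tr <- kb$triples
  set.seed(99)
  for (trial in 1:100) {
    s <- if (runif(1) < 0.5) sample(tr$subject, 1) else NULL
    p <- if (runif(1) < 0.5) sample(tr$predicate, 1) else NULL
    o <- if (runif(1) < 0.5) sample(tr$object, 1) else NULL
    got <- kb_query(kb, subject = s, predicate = p, object = o)
    want <- tr[oracle_query(tr, s, p, o), , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
  # fully unbound pattern returns everything; absent pattern returns nothing
  expect_equal(nrow(kb_query(kb)), nrow(tr))
  expect_equal(nrow(kb_query(kb, "nope", "nope", "nope")), 0)
})

test_that("KB RDF round-trip preserves triples and provenance in both dialects", {
  f <- kb_fixture(materialized = TRUE)
  for (fmt in c("turtle", "ntriples")) {
    path <- withr::local_tempfile(fileext = ".rdf")
    export_rdf(f$kb, path, format = fmt)
    back <- import_rdf(path)
    expect_true(kb_equal(f$kb, back), info = fmt)
    expect_equal(back$individuals[["uchl1"]]$external_ids[["entrez"]], "7345")
  }
  # a merged triple serializes one comment per provenance sentence
  path <- withr::local_tempfile(fileext = ".ttl")
  export_rdf(f$kb, path)
  lines <- readLines(path)
  stmt <- grep("rdf:predicate phare:influences", lines, value = TRUE)
  sid <- sub(" .*", "", stmt)
  expect_length(grep(paste0("^", sid, " rdfs:comment"), lines), 2)
  # empty KB -> valid empty document
  path2 <- withr::local_tempfile(fileext = ".ttl")
  export_rdf(phare:::new_kb(phare:::empty_triples(), list()), path2)
  expect_equal(nrow(import_rdf(path2)$triples), 0)
})

test_that("subnetwork filters by distinct supporting sentences", {
  onto <- fig_fixture()$ontology
  kb <- phare:::new_kb(phare:::empty_triples(), list())
  for (id in c("focus", "a", "b")) kb <- phare:::register_individual(kb, id, id)
  mk_prov <- function(n, tag) data.frame(pmid = as.character(seq_len(n)),
                                         sentence = sprintf("%s %d", tag, seq_len(n)))
  kb <- phare:::add_triple(kb, "a", "influences", "focus", kind = "role",
                           inferred = FALSE, provenance = mk_prov(6, "a"))
  kb <- phare:::add_triple(kb, "b", "influences", "focus", kind = "role",
                           inferred = FALSE, provenance = mk_prov(2, "b"))
  kb <- phare:::add_triple(kb, "focus", "rdf:type", "Disease", kind = "type",
                           inferred = FALSE)
  g <- subnetwork(kb, "focus", min_sentences = 5, top_labels = 2, onto = onto)
  expect_setequal(igraph::V(g)$name, c("focus", "a"))
  expect_equal(igraph::ecount(g), 1)
  # typing triples never become edges
  g0 <- subnetwork(kb, "focus", min_sentences = 0, top_labels = 2, onto = onto)
  expect_setequal(igraph::V(g0)$name, c("focus", "a", "b"))
  expect_equal(igraph::ecount(g0), 2)
  expect_error(subnetwork(kb, "nobody"), class = "phare_lookup_error")
})

test_that("edge labels are the most frequent role names, ties lexicographic", {
  onto <- fig_fixture()$ontology
  kb <- phare:::new_kb(phare:::empty_triples(), list())
  for (id in c("x", "y")) kb <- phare:::register_individual(kb, id, id)
  add_role_triples <- function(kb, role, n, tag) {
    phare:::add_triple(kb, "x", role, "y", kind = "role", inferred = FALSE,
                       provenance = data.frame(pmid = as.character(seq_len(n)),
                                               sentence = sprintf("%s %d", tag, seq_len(n))))
  }
  kb <- add_role_triples(kb, "influences", 4, "i")
  kb <- add_role_triples(kb, "inhibits", 2, "h")
  kb <- add_role_triples(kb, "treats", 1, "t")
  g <- subnetwork(kb, "x", min_sentences = 0, top_labels = 2, onto = onto)
  expect_equal(igraph::E(g)$label, "influences; inhibits")
  g3 <- subnetwork(kb, "x", min_sentences = 0, top_labels = 3, onto = onto)
  expect_equal(igraph::E(g3)$label, "influences; inhibits; treats")
})

test_that("GML export writes standard node/edge records", {
  f <- kb_fixture(materialized = TRUE)
  g <- subnetwork(f$kb, "vkorc1=expression", min_sentences = 0, onto = f$onto)
  path <- withr::local_tempfile(fileext = ".gml")
  export_gml(g, path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^  node$|^  node \\[$|^\\s*node\\b", txt)), igraph::vcount(g))
  expect_equal(sum(grepl("^\\s*edge\\b", txt)), igraph::ecount(g))
  back <- igraph::read_graph(path, format = "gml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(sort(igraph::E(back)$label), sort(igraph::E(g)$label))
  # empty graph still yields a loadable document
  e <- withr::local_tempfile(fileext = ".gml")
  export_gml(igraph::make_empty_graph(0, directed = FALSE), e)
  expect_equal(igraph::vcount(igraph::read_graph(e, format = "gml")), 0)
})
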