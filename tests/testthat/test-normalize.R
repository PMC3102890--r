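test_that("composite-entity normalization builds the nested modified chain", {
  fx <- fig_fixture()
  onto <- fx$ontology

  # "coumadin requirements differences" -> Variation(DrugDose(warfarin)),
  # with the synonym replaced by the preferred name
  ne <- normalize_entity(fx$fig6_tokens, onto)
  expect_s3_class(ne, "phare_entity")
  expect_equal(ne$type, "Variation")
  expect_equal(ne$modified$type, "DrugDose")
  expect_equal(ne$modified$modified$kind, "key")
  expect_equal(ne$modified$modified$key, "warfarin")
  expect_equal(entity_id(ne, onto), "warfarin=dose=variation")
  # observing Variation-over-DrugDose appends exactly one composition axiom
  expect_equal(onto$axioms, list(list(outer = "Variation", inner = "DrugDose")))
  # re-normalizing does not duplicate it
  invisible(normalize_entity(fx$fig6_tokens, onto))
  expect_length(onto$axioms, 1)

  # atomic key entity comes back unchanged
  atom <- normalize_entity("VKORC1", onto)
  expect_equal(atom$kind, "key")
  expect_equal(entity_id(atom, onto), "vkorc1")

  # multiword synonym matched longest-first
  long <- normalize_entity(
    c("vitamin", "K", "epoxide", "reductase", "complex", "subunit", "1", "expression"),
    onto)
  expect_equal(entity_id(long, onto), "vkorc1=expression")
})

test_that("the 'level' ambiguity resolves by the anchor's key category", {
  onto <- fig_fixture()$ontology
  expect_equal(entity_id(normalize_entity(c("warfarin", "level"), onto), onto),
               "warfarin=dose")
  expect_equal(entity_id(normalize_entity(c("vkorc1", "level"), onto), onto),
               "vkorc1=expression")
  # a generic class word can anchor the chain ("gene level")
  gl <- normalize_entity(c("gene", "level"), onto)
  expect_equal(gl$type, "Expression")
  expect_equal(gl$modified$kind, "class")
  expect_equal(entity_id(gl, onto), "gene=expression")
})

test_that("normalization failures carry stage and offending token", {
  onto <- fig_fixture()$ontology
  f1 <- normalize_entity(c("notathing", "level"), onto)
  expect_true(is_failure(f1))
  expect_equal(f1$stage, "key")
  f2 <- normalize_entity(c("warfarin", "blorp"), onto)
  expect_equal(f2$stage, "modifier")
  expect_equal(f2$token, "blorp")
  f3 <- normalize_type("potentiates", onto)
  expect_equal(f3$stage, "type")
})

test_that("type normalization keeps passive direction; assembly swaps", {
  onto <- fig_fixture()$ontology
  expect_equal(normalize_type("inhibits", onto)$role$id, "inhibits")
  expect_equal(normalize_type("antagonize", onto)$role$id, "inhibits")
  expect_equal(normalize_type("is$$inhibited", onto)$role$id, "isInhibitedBy")
  expect_equal(normalize_type("is$$inhibited", onto)$orientation, "as-stated")

  a <- normalize_entity("VKORC1", onto)
  b <- normalize_entity(c("warfarin", "dose"), onto)
  prov <- data.frame(pmid = "123", sentence = "s")

  # inverse expansion
  rels <- assemble(onto, "isInhibitedBy", a, b, prov)
  expect_length(rels, 2)
  expect_equal(rels[[1]]$role, "isInhibitedBy")
  expect_false(rels[[1]]$derived_by_inverse)
  expect_equal(rels[[2]]$role, "inhibits")
  expect_equal(rels[[2]]$subject_id, "warfarin=dose")
  expect_equal(rels[[2]]$object_id, "vkorc1")
  expect_true(rels[[2]]$derived_by_inverse)

  # symmetric swap, never both
  rels <- assemble(onto, "isAssociatedWith", a, b, prov)
  expect_length(rels, 2)
  expect_equal(rels[[2]]$role, "isAssociatedWith")
  expect_equal(rels[[2]]$subject_id, "warfarin=dose")

  # plain role: singleton
  expect_length(assemble(onto, "influences", a, b, prov), 1)
})

test_that("integration merges synonymous and inverse phrasings (figure example)", {
  fx <- fig_fixture()
  out <- integrate_relationships(fx$raw, fx$ontology)
  expect_equal(out$n_input, 4)
  expect_true(all(out$raw_status$ok))

  # 4 raw relationships -> 2 distinct normalized expressions
  expect_setequal(distinct_expressions(out),
                  c("influences | vkorc1 | warfarin=dose",
                    "inhibits | warfarin=dose | vkorc1=expression"))

  # the merged dose fact carries both source sentences
  infl <- Filter(function(r) r$role == "influences", out$normalized)[[1]]
  expect_equal(nrow(infl$provenance), 2)
  expect_setequal(infl$provenance$pmid, c("18250228", "17048007"))

  # s3's derived twin merged with s4's assertion: shared provenance, not derived
  inh <- Filter(function(r) r$role == "inhibits", out$normalized)[[1]]
  expect_equal(nrow(inh$provenance), 2)
  expect_false(inh$derived_by_inverse)
})

test_that("every input is accounted for exactly once (conservation)", {
  fx <- fig_fixture()
  onto <- fx$ontology
  raws <- c(fx$raw, list(
    raw_relationship("potentiates", "warfarin", "VKORC1", "999", "unknown verb."),
    raw_relationship("inhibits", "warfarin", c("VKORC1", "blorp"), "998", "unknown modifier.")
  ))
  out <- integrate_relationships(raws, onto)
  expect_equal(sum(out$raw_status$ok) + sum(!out$raw_status$ok), out$n_input)
  expect_equal(sum(!out$raw_status$ok), 2)
  expect_equal(out$raw_status$stage[!out$raw_status$ok], c("type", "modifier"))
  expect_equal(coverage(out), 4 / 6)

  empty <- integrate_relationships(list(), onto)
  expect_length(empty$normalized, 0)
  expect_equal(empty$n_input, 0)
})

test_that("integration is idempotent on its own surface forms", {
  fx <- fig_fixture()
  out <- integrate_relationships(fx$raw, fx$ontology)
  again <- integrate_relationships(surface_raws(out, fx$ontology), fx$ontology)
  expect_true(all(again$raw_status$ok))
  expect_setequal(distinct_expressions(again), distinct_expressions(out))
  tk <- function(o) sort(vapply(o$normalized, function(r)
    paste(r$role, r$subject_id, r$object_id), character(1)))
  expect_equal(tk(again), tk(out))
})

test_that("inverse closure holds after integration", {
  co <- generate_corpus(generator_config(n_facts = 30, seed = 5))
  onto <- generator_ontology()
  out <- integrate_relationships(co$raws, onto)
  keys <- vapply(out$normalized, function(r)
    paste(r$role, r$subject_id, r$object_id), character(1))
  for (r in out$normalized) {
    inv <- onto$roles[[r$role]]$inverse
    if (!is.null(inv)) {
      expect_true(paste(inv, r$object_id, r$subject_id) %in% keys,
                  info = paste("missing inverse of", r$role, r$subject_id))
    }
  }
})

test_that("integration is invariant under input permutation", {
  co <- generate_corpus(generator_config(n_facts = 15, seed = 8))
  onto1 <- generator_ontology()
  onto2 <- generator_ontology()
  out1 <- integrate_relationships(co$raws, onto1)
  set.seed(1)
  out2 <- integrate_relationships(sample(co$raws), onto2)
  tk <- function(o) sort(vapply(o$normalized, function(r)
    paste(r$role, r$subject_id, r$object_id), character(1)))
  expect_equal(tk(out1), tk(out2))
  expect_setequal(distinct_expressions(out1), distinct_expressions(out2))
})

test_that("refinement report ranks unmatched terms by frequency then name", {
  onto <- fig_fixture()$ontology
  mk <- function(ty, i) raw_relationship(ty, "warfarin", "VKORC1",
                                         as.character(1000 + i),
                                         sprintf("sentence %d.", i))
  raws <- list(mk("potentiates", 1), mk("potentiates", 2), mk("potentiates", 3),
               mk("zaps", 4), mk("blocks", 5))
  rep <- refinement_report(integrate_relationships(raws, onto))
  expect_equal(rep$term[[1]], "potentiates")
  expect_equal(rep$count[[1]], 3)
  # tie between blocks and zaps broken lexicographically
  expect_equal(rep$term[2:3], c("blocks", "zaps"))
  expect_true(all(rep$kind == "role"))
  expect_equal(rep$example[[1]], "sentence 1.")

  none <- refinement_report(integrate_relationships(fig_fixture()$raw, onto))
  expect_equal(nrow(none), 0)
  expect_equal(nrow(refinement_report(integrate_relationships(raws, onto), top_n = 2)), 2)
})
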