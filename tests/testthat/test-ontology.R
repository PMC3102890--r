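test_that("key-entity resolution is case-insensitive and synonym-aware", {
  onto <- fig_fixture()$ontology
  expect_equal(resolve_key_entity(onto, "coumadin")$preferred_name, "warfarin")
  expect_equal(resolve_key_entity(onto, "WARFARIN")$preferred_name, "warfarin")
  expect_equal(resolve_key_entity(onto, "Paralysis Agitans")$id, "parkinson=disease")
  expect_null(resolve_key_entity(onto, "notadrug"))

  # a synonym shared by two key entities is an ambiguity error with candidates
  add_key_entity(onto, key_entity("warfarin sodium", "Drug",
                                  synonyms = c("warfarin sodium", "coumadin")))
  err <- tryCatch(resolve_key_entity(onto, "coumadin"), phare_ambiguity = identity)
  expect_s3_class(err, "phare_ambiguity")
  expect_setequal(err$candidates, c("warfarin", "warfarin=sodium"))
})

test_that("entity-type lookup honours modifier scope and pluralization", {
  onto <- fig_fixture()$ontology
  expect_equal(find_entity_type(onto, "level", "Gene")$id, "Expression")
  expect_equal(find_entity_type(onto, "level", "Drug")$id, "DrugDose")
  expect_equal(find_entity_type(onto, "requirements", "Drug")$id, "DrugDose")
  expect_equal(find_entity_type(onto, "Doses", "Drug")$id, "DrugDose")
  # unique labels resolve without a category
  expect_equal(find_entity_type(onto, "polymorphism")$id, "Variant")
  expect_null(find_entity_type(onto, "banana"))
  # shared label with no selecting category and no unscoped owner: ambiguity
  expect_error(find_entity_type(onto, "level"), class = "phare_ambiguity")
  expect_error(find_entity_type(onto, "level", "Phenotype"),
               class = "phare_ambiguity")
})

test_that("role lookup matches voice-marked and inflected labels", {
  onto <- fig_fixture()$ontology
  expect_equal(find_role(onto, "represses")$id, "inhibits")
  expect_equal(find_role(onto, "inhibited")$id, "inhibits")
  expect_equal(find_role(onto, "is$$inhibited")$id, "isInhibitedBy")
  expect_equal(find_role(onto, "ANTAGONIZE")$id, "inhibits")
  expect_null(find_role(onto, "potentiates"))
})

test_that("subsumes is reflexive-transitive over parents", {
  onto <- fig_fixture()$ontology
  expect_true(subsumes(onto, "Phenotype", "Expression"))
  expect_false(subsumes(onto, "Expression", "Phenotype"))
  expect_true(subsumes(onto, "Expression", "Expression"))
  expect_true(subsumes(onto, "Variation", "Variant"))
  expect_error(subsumes(onto, "Phenotype", "NoSuchType"),
               class = "phare_lookup_error")
})

test_that("subsumes agrees with brute-force reachability and is a partial order", {
  set.seed(11)
  for (trial in 1:15) {
    dag <- random_dag_ontology(sample(3:12, 1))
    for (a in dag$ids) for (b in dag$ids) {
      expect_identical(subsumes(dag$onto, a, b), oracle_reachable(dag$parents, b, a))
    }
    # antisymmetry on an acyclic fixture
    for (a in dag$ids) for (b in dag$ids) {
      if (a != b && subsumes(dag$onto, a, b)) {
        expect_false(subsumes(dag$onto, b, a))
      }
    }
  }
})

test_that("validation flags each structural defect", {
  onto <- fig_fixture()$ontology
  expect_equal(nrow(validate_ontology(onto)), 0)

  dup <- fig_fixture()$ontology
  add_role(dup, role("stimulates", c("stimulates", "inhibit")))
  expect_true(any(validate_ontology(dup)$rule == "role-label-unique"))

  invol <- phare_ontology()
  add_role(invol, role("a", "a", inverse = "b"))
  add_role(invol, role("b", "b", inverse = "c"))
  add_role(invol, role("c", "c", inverse = "b"))
  expect_true(any(validate_ontology(invol)$rule == "role-inverse-involutive"))

  cyc <- phare_ontology()
  add_entity_type(cyc, entity_type("A", "a", parents = "B"))
  add_entity_type(cyc, entity_type("B", "b", parents = "A"))
  expect_true(any(validate_ontology(cyc)$rule == "type-acyclic"))

  sym <- phare_ontology()
  add_role(sym, role("r", "r", inverse = "s", symmetric = TRUE))
  add_role(sym, role("s", "s", inverse = "r"))
  expect_true(any(validate_ontology(sym)$rule == "role-symmetric-vs-inverse"))

  scoped <- phare_ontology()
  add_entity_type(scoped, entity_type("X", c("x", "shared")))
  add_entity_type(scoped, entity_type("Y", c("y", "shared")))
  expect_true(any(validate_ontology(scoped)$rule == "type-label-unique-in-scope"))
})

test_that("validation detects randomly seeded label-duplication violations", {
  set.seed(23)
  for (trial in 1:10) {
    onto <- fig_fixture()$ontology
    roles <- names(onto$roles)
    victim <- sample(roles, 1)
    stolen <- tolower(sample(onto$roles[[sample(setdiff(roles, victim), 1)]]$labels, 1))
    add_role(onto, role(paste0(victim, "X"), c(paste0(victim, "x"), stolen)))
    rep <- validate_ontology(onto)
    expect_true(any(rep$rule == "role-label-unique"),
                info = sprintf("trial %d stole label %s", trial, stolen))
  }
})

test_that("ontology save/load round-trips across both dialects", {
  fx <- fig_fixture()
  onto <- fx$ontology
  # add a normalization-time composition axiom before the round trip
  invisible(normalize_entity(fx$fig6_tokens, onto))
  expect_length(onto$axioms, 1)
  for (fmt in c("turtle", "ntriples")) {
    f <- withr::local_tempfile(fileext = ".rdf")
    lexf <- withr::local_tempfile(fileext = ".tsv")
    save_ontology(onto, f, format = fmt)
    write_lexicon(onto, lexf)
    back <- load_ontology(f, lexicon = lexf)
    expect_true(ontology_equal(onto, back), info = fmt)
    expect_length(back$axioms, 1)
    expect_true(back$roles[["isAssociatedWith"]]$symmetric)
    expect_equal(back$roles[["inhibits"]]$inverse, "isInhibitedBy")
    expect_equal(back$entity_types[["DrugDose"]]$modifier_category, "Drug")
  }
})

test_that("degenerate and broken ontology files are handled", {
  empty <- withr::local_tempfile(fileext = ".ttl")
  writeLines("@prefix phare: <http://phare-kb.org/phare#> .", empty)
  onto <- load_ontology(empty)
  expect_length(onto$entity_types, 0)
  expect_length(onto$roles, 0)

  # the same label asserted in two roles must be rejected at load
  dup <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix phare: <http://phare-kb.org/phare#> .",
    "phare:r1 rdf:type owl:ObjectProperty .",
    'phare:r1 rdfs:label "inhibit" .',
    "phare:r2 rdf:type owl:ObjectProperty .",
    'phare:r2 rdfs:label "inhibit" .'
  ), dup)
  expect_error(load_ontology(dup), class = "phare_validation_error")

  bad <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c("@prefix phare: <http://phare-kb.org/phare#> .",
               "phare:r1 rdf:type"), bad)
  expect_error(load_ontology(bad), class = "phare_format_error")
  expect_error(load_ontology(withr::local_tempfile(fileext = ".ttl")),
               class = "phare_io_error")
})

test_that("lexicon TSV round-trips with external identifiers", {
  onto <- fig_fixture()$ontology
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(onto, f)
  lex <- read_lexicon(f)
  expect_length(lex, 4)
  expect_equal(lex[["warfarin"]]$external_ids[["drugbank"]], "DB00682")
  expect_equal(lex[["vkorc1"]]$external_ids[["entrez"]], "79001")
  expect_setequal(lex[["warfarin"]]$synonyms, c("warfarin", "coumadin"))
  expect_equal(lex[["parkinson=disease"]]$category, "Phenotype")
})

test_that("label statistics are arithmetic means over label sets", {
  onto <- phare_ontology()
  add_role(onto, role("a", c("a", "b")))
  add_role(onto, role("c", c("c", "d", "e", "f")))
  add_entity_type(onto, entity_type("T", "t"))
  s <- label_stats(onto)
  expect_equal(s$labels_per_role, 3)
  expect_equal(s$labels_per_entity_type, 1)
  expect_error(label_stats(phare_ontology()), class = "phare_empty_error")
})
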