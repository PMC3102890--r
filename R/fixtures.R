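#' In-code fixture reproducing the worked figure examples
#'
#' Builds a miniature ontology with the content the worked examples need:
#' inverse role pair `inhibits`/`isInhibitedBy`, the `influences` family,
#' the symmetric `isAssociatedWith`, treatment and metabolism role pairs;
#' entity types `Expression` (a `Phenotype`, Gene-scoped, labels including
#' the ambiguous "level"), `DrugDose` (Drug-scoped, labels including
#' "requirement" and "level"), `Variation` with `Variant` below it, plus the
#' key-category classes; and a lexicon with warfarin (synonym coumadin),
#' VKORC1, UCHL1 and parkinson disease with their external identifiers.
#'
#' Also returns:
#' * `raw`: the four heterogeneous raw relationships whose integration
#'   yields two normalized expressions (two synonymous phrasings of the
#'   dose-influence fact, and an inverse pair stated once passively and once
#'   in the simple past);
#' * `fig6_tokens`: the composite entity `coumadin requirements differences`
#'   that normalizes to the nested Variation -> DrugDose -> warfarin chain;
#' * `uchl1_raw`: the association of UCHL1 with parkinson disease carrying
#'   the worked provenance sentence.
#'
#' @return list with elements `ontology`, `raw`, `fig6_tokens`, `uchl1_raw`.
#' @export
figure_fixture <- function() {
  onto <- phare_ontology()

  add_entity_type(onto, entity_type("Gene", c("gene", "genes")))
  add_entity_type(onto, entity_type("Drug", c("drug", "drugs")))
  add_entity_type(onto, entity_type("Phenotype", "phenotype"))
  add_entity_type(onto, entity_type("Disease", c("disease", "disorder", "illness"),
                                    parents = "Phenotype"))
  add_entity_type(onto, entity_type(
    "Expression", c("expression", "level", "transcription", "abundance"),
    parents = "Phenotype", modifier_category = "Gene"))
  add_entity_type(onto, entity_type(
    "DrugDose", c("dose", "requirement", "level", "dosage", "amount"),
    modifier_category = "Drug"))
  add_entity_type(onto, entity_type(
    "Variation", c("variation", "difference", "change", "variability", "fluctuation")))
  add_entity_type(onto, entity_type(
    "Variant", c("variant", "polymorphism", "mutation", "allele"),
    parents = "Variation", modifier_category = "Gene"))
  add_entity_type(onto, entity_type(
    "Treatment", c("treatment", "therapy", "management"),
    modifier_category = "Phenotype"))

  add_role(onto, role("influences",
                      c("influences", "influence", "influenced",
                        "affects", "affect", "affected",
                        "modulates", "modulate", "modulated",
                        "alters", "alter", "altered")))
  add_role(onto, role("inhibits",
                      c("inhibits", "inhibit", "inhibited",
                        "represses", "repress", "repressed",
                        "antagonizes", "antagonize", "antagonized",
                        "suppresses", "suppress", "suppressed",
                        "downregulates", "downregulate", "downregulated"),
                      parent = "influences", inverse = "isInhibitedBy"))
  add_role(onto, role("isInhibitedBy",
                      c("isInhibitedBy", "is$$inhibited", "is$$repressed",
                        "is$$antagonized", "is$$suppressed", "is$$downregulated"),
                      inverse = "inhibits"))
  add_role(onto, role("isAssociatedWith",
                      c("isAssociatedWith", "is$$associated", "is$$linked",
                        "is$$correlated", "correlates", "correlate",
                        "correlated", "associates", "associate", "associated"),
                      symmetric = TRUE))
  add_role(onto, role("treats",
                      c("treats", "treat", "treated",
                        "alleviates", "alleviate", "alleviated",
                        "ameliorates", "ameliorate", "ameliorated"),
                      inverse = "isTreatedBy"))
  add_role(onto, role("isTreatedBy",
                      c("isTreatedBy", "is$$treated", "is$$alleviated",
                        "is$$ameliorated"),
                      inverse = "treats"))
  add_role(onto, role("metabolizes",
                      c("metabolizes", "metabolize", "metabolized",
                        "degrades", "degrade", "degraded"),
                      inverse = "isMetabolizedBy"))
  add_role(onto, role("isMetabolizedBy",
                      c("isMetabolizedBy", "is$$metabolized", "is$$degraded"),
                      inverse = "metabolizes"))

  add_key_entity(onto, key_entity(
    "warfarin", "Drug", synonyms = c("warfarin", "coumadin"),
    external_ids = c(drugbank = "DB00682", mesh = "D014859")))
  add_key_entity(onto, key_entity(
    "VKORC1", "Gene",
    synonyms = c("VKORC1", "vitamin K epoxide reductase complex subunit 1"),
    external_ids = c(entrez = "79001")))
  add_key_entity(onto, key_entity(
    "UCHL1", "Gene", synonyms = c("UCHL1", "UCH-L1", "PARK5"),
    external_ids = c(entrez = "7345")))
  add_key_entity(onto, key_entity(
    "parkinson disease", "Phenotype",
    synonyms = c("parkinson disease", "parkinson's disease", "paralysis agitans"),
    external_ids = c(mesh = "D010300")))

  raw <- list(
    # s1/s2: one fact, two phrasings ("dose" vs "requirements", synonym coumadin)
    raw_relationship("influences", "VKORC1", c("warfarin", "dose"),
                     "18250228",
                     "Common VKORC1 variants influence the dose of warfarin needed for stable anticoagulation."),
    raw_relationship("affects", "vkorc1", c("coumadin", "requirements"),
                     "17048007",
                     "VKORC1 genotype affects coumadin requirements in most patients."),
    # s3/s4: an inverse pair; "level" is disambiguated by gene vs drug anchors
    raw_relationship("is$$repressed", c("vkorc1", "level"), c("warfarin", "level"),
                     "16270629",
                     "The level of VKORC1 is repressed when the warfarin level rises."),
    raw_relationship("inhibited", c("coumadin", "level"), c("VKORC1", "level"),
                     "15930419",
                     "A higher coumadin level inhibited the level of VKORC1 transcript.")
  )

  uchl1_raw <- raw_relationship(
    "is$$linked", "UCH-L1", c("parkinson's", "disease"),
    "14522054",
    paste0("Neuronal ubiquitin C-terminal hydrolase (UCH-L1) has been linked ",
           "to Parkinson's disease (PD), the progression of certain ",
           "nonneuronal tumors, and neuropathic pain")
  )

  list(ontology = onto, raw = raw,
       fig6_tokens = c("coumadin", "requirements", "differences"),
       uchl1_raw = uchl1_raw)
}

#' Ontology used by the synthetic generator
#'
#' The figure fixture ontology extended with synthetic key entities so the
#' fact space comfortably exceeds the number of ground-truth facts sampled.
#' Synthetic entries are plainly labelled as such (`GENE01`, `drugex01`,
#' `syndrome01`) and each carries two synonyms so synonym substitution
#' always has a non-preferred choice.
#'
#' @param n_genes,n_drugs,n_phenotypes how many synthetic key entities to add.
#' @return a `phare_ontology`.
#' @export
generator_ontology <- function(n_genes = 8, n_drugs = 6, n_phenotypes = 4) {
  onto <- figure_fixture()$ontology
  for (i in seq_len(n_genes)) {
    nm <- sprintf("GENE%02d", i)
    add_key_entity(onto, key_entity(
      nm, "Gene", synonyms = c(nm, sprintf("gn%02d", i), sprintf("g%02dsyn", i)),
      external_ids = c(entrez = as.character(900000 + i))))
  }
  for (i in seq_len(n_drugs)) {
    nm <- sprintf("drugex%02d", i)
    add_key_entity(onto, key_entity(
      nm, "Drug", synonyms = c(nm, sprintf("dx%02d", i), sprintf("d%02dsyn", i)),
      external_ids = c(drugbank = sprintf("DB9%04d", i))))
  }
  for (i in seq_len(n_phenotypes)) {
    nm <- sprintf("syndrome%02d", i)
    add_key_entity(onto, key_entity(
      nm, "Phenotype", synonyms = c(nm, sprintf("sd%02d", i), sprintf("s%02dsyn", i)),
      external_ids = c(mesh = sprintf("D9%05d", i))))
  }
  onto
}
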