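Package: phare
Title: Ontology-Driven Normalization of Text-Mined Pharmacogenomic Relationships
Version: 0.1.0
Authors@R:
    person("PHARE", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous text-mined pharmacogenomic relationships
    through a relationship ontology. Provides a data model for entity-type and
    role hierarchies with inverse and symmetric roles and modifier restrictions,
    a normalization algorithm that resolves composite noun-phrase entities
    (key entity plus modifier chain) against the ontology, a knowledge-base
    builder with sentence-level provenance and materialization of inferred
    triples, automatic ontology induction from synonym sets, evaluation
    metrics (coverage, reduction, duplicate identification), network export
    to GML, and a synthetic paraphrase generator with retained ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
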