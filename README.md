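# phare

Ontology-driven normalization and integration of heterogeneous text-mined
pharmacogenomic relationships, in R.

## The problem

NLP pipelines that mine MEDLINE for pharmacogenomic (PGx) facts emit *raw
relationships* of the form `R(a, b)` — an untyped verb string linking two
noun phrases, with the source PMID and sentence attached. The same
underlying fact surfaces in many guises:

* synonymous verbs (`inhibit`, `repress`, `antagonize`);
* passive voice versus simple past (`A is inhibited by B` yields the
  extractor form `is$$inhibited(A, B)`; `B inhibited A` yields
  `inhibited(A, B)`);
* swapped argument order via inverse phrasings;
* composite noun phrases whose head is modified by a *key entity* — a gene,
  drug, or phenotype (`coumadin requirements differences`, read left to
  right with the head last).

A knowledge base built from such output is full of near-duplicates that
string matching cannot merge: `gene level` means gene *expression* while
`drug level` means drug *dose*, and `isInhibitedBy(a, b)` is the same fact
as `inhibits(b, a)`.

This package implements the ontology-driven answer for users who build
knowledge bases from relation-extraction output: a relationship ontology —
entity-type and role hierarchies carrying synonym labels, inverse and
symmetric role declarations, and modifier restrictions (the existential
pattern "∃ modified.Drug" that scopes a label like *level* to drug-anchored
phrases) — and the normalization algorithm that maps raw relationships onto
it.

## The method

For a raw relationship `R(a, b)`:

1. **Subject and object normalization.** The longest token prefix matching a
   key-entity synonym anchors the phrase (the synonym is replaced by the
   preferred name: *coumadin* → *warfarin*). Each remaining token, read
   left to right, is looked up among entity-type labels — disambiguated by
   the anchor's key category — and wraps the current entity through a
   `modified` link, e.g.
   `coumadin requirements differences` →
   `Variation(modified → DrugDose(modified → warfarin))`.
   The first time an outer type is seen wrapping an inner type, a
   composition axiom (the restricted class is a subclass of the outer type)
   is appended to the ontology.
2. **Type normalization.** `R` is matched case-insensitively (with a light
   pluralization fallback) against role labels; passive `$$` labels belong
   to the passive-direction role, so no argument swap happens here.
3. **Assembly.** The normalized role, subject and object form a triple; if
   the role has an inverse, the swapped inverse triple is added
   (`isInhibitedBy(a,b)` ⇒ `inhibits(b,a)`), and symmetric roles add the
   swapped twin. Triples identical after normalization merge, concatenating
   their `(PMID, sentence)` provenance.

The resulting knowledge base supports materialization of inferred triples
(supertype classification — `Expression ⊑ Phenotype` makes every expression
individual a phenotype — plus inverse/symmetric closure), triple-pattern
queries over asserted + inferred facts, RDF (Turtle / N-Triples) round-trips
with provenance serialized as `"[PMID, sentence]"` comments, and GML export
of frequency-filtered subnetworks around a focus individual.

Two more components round out the toolkit: a fully automatic
ontology-induction mode that merges relationship/modifier terms into roles
and entity types by connected components over a synonym (synset) resource,
and evaluation metrics — **coverage** (fraction of raw relationships
normalized), **reduction** (1 − distinct normalized expressions / distinct
raw expressions), label-count statistics, and the duplicate-identification
histogram (classes identified 2–4, 5–9, ≥10 times).

## Worked example

```r
library(phare)
fx <- figure_fixture()          # miniature ontology + 4 heterogeneous raws
out <- integrate_relationships(fx$raw, fx$ontology)
out
#> <phare_outcome: 4 raw in, 3 normalized triples (2 expressions), 0 failed>
distinct_expressions(out)
#> [1] "influences | vkorc1 | warfarin=dose"
#> [2] "inhibits | warfarin=dose | vkorc1=expression"
```

Four raw relationships — two synonymous phrasings of the dose-influence
fact and an inverse pair stated once passively, once in the simple past —
collapse to two normalized expressions (three directed triples: the inverse
pair is stored in both directions). Metrics and the knowledge base:

```r
metrics_report(fx$ontology, fx$raw, out)
#> PHARE-style metrics
#>   entity types:            9
#>   roles:                   8
#>   labels per entity type:  3.22
#>   labels per role:         8.12
#>   reduction:               50.0%
#>   coverage:                100.0%
#>   duplicates (classes):    2<=n<5: 2, 5<=n<10: 0, n>=10: 0

kb <- materialize(build_kb(out, fx$ontology), fx$ontology)
kb_query(kb, subject = "vkorc1=expression", predicate = "rdf:type")[, 1:5]
#>             subject predicate     object kind inferred
#> 1 vkorc1=expression  rdf:type Expression type    FALSE
#> 2 vkorc1=expression  rdf:type  Phenotype type     TRUE
```

The second typing triple is inferred by classification: a gene expression
is a phenotype. Reduction is 50% here (4 distinct raw strings → 2
expressions); on the synthetic paraphrase corpus (100 facts × 5
paraphrases, `generate_corpus()`) integration recovers exactly the 100
ground-truth facts, i.e. coverage 1.0 and reduction 0.8.

A command-line entry point wraps the pipeline; see `inst/cli/phare.R`:

```sh
Rscript inst/cli/phare.R normalize --ontology onto.ttl --lexicon lex.tsv \
    --raw raw.jsonl --out kb.ttl --report failures.tsv
```

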