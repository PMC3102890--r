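---
title: "Normalizing text-mined pharmacogenomic relationships with a relationship ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing text-mined pharmacogenomic relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phare)
```

## The model

Relation-extraction pipelines produce raw binary relationships
`R(a, b)` where `R` is a verb string and `a`, `b` are noun-phrase token
sequences. The package's data model separates three vocabularies:

* **Entity types** form a subsumption hierarchy (directed acyclic graph via
  `parents`). Each type owns an ordered label set; the first label is the
  preferred name. A type may carry a *modifier restriction*: the key
  category `X` in "∃ modified.X". The restriction is what disambiguates a
  label owned by several types: *level* belongs to `Expression` under a
  Gene anchor and to `DrugDose` under a Drug anchor.
* **Roles** own ordered label sets too, may have a parent role, an inverse
  role (involutive), or a symmetry flag — never both a distinct inverse and
  symmetry. Labels containing the `$$` separator are passive-voice surface
  forms inserted by the upstream extractor (`is$$inhibited`); they are
  treated as opaque strings and belong to the passive-direction role.
* **Key entities** (genes, drugs, phenotypes) carry synonyms, a preferred
  name, and external identifiers (Entrez Gene, DrugBank, MeSH).

A normalized composite entity is a finite `modified` chain ending in an
anchor. The anchor is normally a key entity; a generic class word may also
anchor a chain (the phrase *gene level* has no specific gene), which is why
the chain's terminal may be a bare entity type.

## The normalization algorithm and its choices

Tokens arrive in extractor order: key tokens first, modifiers left to
right, head last. The algorithm:

1. match the longest token prefix against key-entity synonyms
   (case-insensitive); replace the matched synonym with the preferred name;
2. for each remaining token, look up entity-type labels with a light
   pluralization fallback (strip trailing `s`, then `es`, and retry — needed
   because surface forms like *requirements* are plural while labels are
   singular), wrap the current entity;
3. match the raw type against role labels the same way;
4. assemble, expanding inverses and symmetry by swapping arguments.

Decisions worth recording:

* **Modifier-category propagation.** The disambiguation category for every
  lookup in a chain is the *anchor's* key category, propagated outward. A
  depth-2 chain like `Variation(DrugDose(warfarin))` therefore resolves
  *differences* in the Drug scope first and falls back to the unscoped label
  space, where `Variation` is the unique owner. Scoped matches win over
  unscoped ones; a label shared with no unique winner is an ambiguity routed
  to the curation report, never a silent pick — the refinement loop exists
  precisely to resolve these.
* **Composition axioms.** When an outer type first wraps an inner *typed*
  entity (not a bare key entity — those are already covered by the modifier
  restriction), the package appends an axiom stating that the composed
  class (outer restricted to `modified` some inner) is a subclass of the
  outer type. A subclass rather than an equivalence axiom is asserted: it is
  the weakest statement consistent with the observation, and nothing in the
  pipeline needs the stronger form.
* **Failure policy.** Any unmatched token fails the whole relationship; no
  partial triples enter the knowledge base. Failures are data
  (stage + offending token) feeding `refinement_report()`, which ranks
  unmatched verbs and modifiers by frequency (ties lexicographic) for
  curator review.
* **Merging and counting.** Merged triples are keyed on (role, canonical
  subject id, canonical object id); canonical ids join the anchor's
  preferred name and the chain's preferred labels with `=` replacing spaces
  (`warfarin=dose=variation`), which keeps merges stable across runs. The
  knowledge base stores *both* directions of an inverse pair (that is the
  convention under which materialized triple counts exceed asserted ones),
  while "distinct expressions" — the quantity behind the reduction metric —
  counts inverse/symmetry *orbits*, so an assertion and its derived twin
  count once.
* **Fig-style subject restriction dropped.** Composite entities are allowed
  on both sides of a relationship (phrases like *gene level* occur as
  subjects); restricting subjects to key entities would cost generality for
  no benefit.

## Knowledge base, inference, provenance

`build_kb()` turns an integration outcome into role triples plus typing
triples; `materialize()` computes the closure under (i) supertype typing via
subsumption, (ii) inverse completion, (iii) symmetric swaps — a monotone,
idempotent fixpoint, with inferred triples flagged and sharing the source
triple's provenance (whether a derived triple should carry provenance of
its own is underdetermined; sharing is the conservative choice). Provenance is
serialized as `rdfs:comment` strings `"[PMID, sentence]"` on reified
statements, so the RDF round-trip preserves it exactly. SPARQL itself is
out of scope; the testable surface is the triple-pattern query
`kb_query(kb, s?, p?, o?)`, which a thin adapter could wrap.

RDF files use a restricted Turtle profile (one statement per line, prefixed
names, a single one-line blank-node restriction pattern) written and read
by the package itself. No pre-installed R library parses RDF, and the `=`
space-encoding convention in local names is outside strict Turtle anyway;
the reader accepts exactly the profile the writer emits, and N-Triples
export expands the blank-node pattern into numbered blank nodes.

Structural reasoning (subsumption reachability, inverse involution,
symmetry) is bespoke rather than delegated to a DL reasoner: the method
uses only these constructs, and a full reasoner would add a heavyweight
dependency without changing any result.

## Ontology induction

The automatic mode merges relationship-type terms (and modifier terms) into
groups by synset co-membership and promotes each group to a role (entity
type) with the lexicographically first member as preferred label. Grouping
is by *connected components* — overlapping synsets chain transitively. The
alternative reading (each synset a separate group, a term joining the first
synset that mentions it) is available as `transitive = FALSE`; components
are the stronger, order-independent convention and are the default. Induced ontologies are flat — no hierarchy,
no inverses — which is exactly why they identify fewer duplicates than a
curated ontology despite higher coverage.

## Evaluation metrics

* **Coverage** = normalized raws / all raws.
* **Reduction** = 1 − distinct normalized expressions / distinct raw
  surface strings, over successfully normalized inputs. There is no single
  agreed formula for this quantity; this definition is the package's stated
  convention, chosen because it is computable from the outcome alone and
  reproduces the "fewer distinct expressions" intuition.
* **Duplicate histogram** counts equivalence classes (not records; a
  `mode = "records"` flag gives the alternative) with multiplicity in
  [2, 5), [5, 10), [10, ∞).

## What the synthetic generator emulates — and what it does not

`generate_corpus()` states a world of `n_facts = 100` distinct ground-truth
facts rendered as `paraphrases_per_fact = 5` distinct surface forms each —
the paraphrase variety of the worked figure examples: synonym substitution
(`p_synonym_substitution = 0.5`), passive `$$` forms (`p_passive = 0.3`),
inverse orientation (`p_inverse_orientation = 0.3`), pluralized modifiers
(`p_plural = 0.25`). The probabilities are uniform sampling weights; no
distributional claim about MEDLINE is being matched, so defaults were
chosen once as plausible mid-range rates and are not tuned. Facts are
sampled over the fixture lexicon extended with clearly-labelled synthetic
key entities (8 genes, 6 drugs, 4 phenotypes — enough that 100 distinct
orbits are sampled without exhausting the space), each with two extra
synonyms so substitution always has a choice.

Every emitted surface uses only labels the ontology owns. A green recovery
test therefore establishes that normalization inverts the generator's
rendering exactly — it does *not* establish robustness to extraction noise,
tokenization errors, out-of-lexicon mentions, or real MEDLINE syntax, all
of which the upstream extractor owns. Distinct paraphrases are best-effort:
when the variant space is smaller than requested (a degenerate
all-probabilities-zero config), the first rendering is repeated rather than
erroring.

## Numerical and degenerate-input conventions

* Label matching is case-insensitive; `$$` is never morphologically
  analysed.
* Coverage, reduction and label statistics are errors (not `NaN`) on empty
  input.
* Subnetwork filtering counts *distinct* (PMID, sentence) pairs across all
  role triples linking two nodes and keeps pairs with strictly more than
  `min_sentences` of them; edge labels are the `top_labels` most frequent
  role preferred names, ties lexicographic. Typing triples never become
  edges.
* Ranked outputs (refinement report, top-n terms, edge labels) break ties
  lexicographically so results are deterministic.

## Known limitations

* The Turtle reader handles the package's own profile, not arbitrary RDF.
* Induction from a full WordNet distribution needs an adapter; the synset
  file format (one synset per line) is the supported interface.
* The ontology content shipped in `figure_fixture()` is a miniature for the
  worked examples; the real curated ontology (hundreds of classes, ~77
  roles) is external content this package loads but does not contain.
* Entity normalization assumes the extractor's left-to-right modifier
  order; free word order is out of scope.
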