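---
title: "Decomposing postcoordinated SNOMED CT expressions into FHIR elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing postcoordinated SNOMED CT expressions into FHIR elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctfhir)
```

## The problem

SNOMED CT supports *postcoordination*: instead of waiting for a
precoordinated concept to be released, an author combines existing concepts
into a postcoordinated expression (PCE) under the Compositional Grammar,
e.g. `71620000:{363698007=722738000}` — a fracture of the femur whose
finding site is refined to the left femur. PCEs are expressive but hard to
store and process: most clinical systems, and FHIR search in particular,
expect single codes in well-known elements. At the same time the FHIR
information model itself can carry parts of the meaning (a body site in
`Condition.bodySite`, a causative substance in `AllergyIntolerance.code`),
the overlap known as the TermInfo problem.

`sctfhir` exploits that overlap: a PCE is decomposed into

1. a **Superconcept** — the released concept most similar to the PCE among
   its direct subsumers, stored where a single code is expected, and
2. a **Delta** — the attribute–value pairs of the PCE that the
   Superconcept's definition does not cover, each stored in the FHIR
   element a StructureMap rule assigns to its attribute.

The reverse direction recomposes a PCE from the stored codings and checks
the round trip by structural subsumption. All reasoning happens in a
built-in, desk-scale terminology engine; no terminology server is needed.

## The terminology model

`load_rf2()` reads tab-separated concept, relationship and description
files in the RF2 snapshot dialect. Only active rows enter the model;
inactive rows are kept in an index but excluded from all reasoning (the
snapshot view of a release is the reasoning substrate). Hierarchy (is-a)
rows form a DAG — acyclicity is verified with igraph at load time — and all
other relationship rows become per-concept *definitions*: ungrouped
attribute pairs plus role groups. Ancestor sets are self-inclusive and
computed over is-a edges only; attribute edges are stored separately in the
definitions. The is-a marker id and the Verhoeff check-digit validation are
configuration, so synthetic fixtures with short ids load unchanged while a
real release can be loaded strictly.

Concept-model (MRCM-lite) rules come from a declarative YAML/TSV table: per
attribute a domain constraint, range constraint, per-group cardinality and
a grouping flag, all expressed in ECL-lite (`<<`, `<`, `AND`, `MINUS`,
parentheses). `validate_semantics()` reports all violations as issues
rather than hard errors, so a user sees every problem at once.

## Structural subsumption instead of a reasoner

Classification of a PCE is performed by a structural EL subsumption check
(`expr_subsumed_by()`) over normal forms. `normalize_expression()` expands
every fully defined focus concept through its parents down to *proximal
primitive* supertypes, merging definitional pairs into the refinement;
pairs implied by a more specific sibling are removed. Three choices matter:

* **Expansion stops at primitive concepts.** A primitive supertype's own
  differentia are necessary conditions already captured by the ancestor
  test, so they are not imposed on the expression being classified.
* **Group merging is conservative.** A definitional role group folds into
  a refinement group only when the refinement group refines one of its
  pairs (attribute and value each subsumed); otherwise groups stay side by
  side, mirroring normal-form guidance.
* **Grouping is significant.** A grouped definitional requirement is
  satisfied only inside a single expression group; an ungrouped
  requirement may be satisfied by a grouped pair, not vice versa.

This engine is sound but deliberately incomplete with respect to full OWL
semantics: property chains, transitive attributes other than is-a, and
concrete domains are out of scope, and the fixtures avoid them. For an
external cross-check, `ontology_axioms()` and `write_functional_syntax()`
export the terminology and any expression as OWL functional syntax (the
role-group property defaults to the conventional role-group concept id and
is configurable).

`superconcept_candidates()` enumerates all active concepts through the
subsumption test and keeps the minimal (pairwise is-a incomparable)
subsumers. When some candidate also subsumes in the converse direction the
expression is equivalent to it; that concept is returned alone and scoring
is short-circuited, since a similarity against an equivalent concept is
degenerate.

## Choosing the Superconcept

Candidates are scored with a shared-ancestor similarity. A transient node
`pce` is inserted below the expression's focus concepts and all candidates;
with `T(x)` the self-inclusive ancestor set on that augmented graph, a
candidate `c` scores

```
sim(pce, c) = -log2( (|T(pce) \ T(c)| - 1) / |T(pce) ∪ T(c)| )
```

The subtracted 1 removes the transient `pce` node itself from the
nonshared count; when nothing else is nonshared the candidate is equivalent
and the score is `+Inf`. From the counts (8, 30) the score is 2.10 and
from (29, 30) it is 0.10, so the candidate sharing more ancestors always
wins; the measure is strictly decreasing in the nonshared count and
strictly increasing in the union. Ties are broken deterministically:
larger candidate ancestor set first (the more specific candidate), then
the lower numeric id. Ties are rare and any plausible choice is acceptable
downstream, because whatever the Superconcept misses reappears in the
Delta; the tie-break only pins the output.

```{r}
round(similarity_from_counts(8, 30), 2)
round(similarity_from_counts(29, 30), 2)
```

`compute_delta()` is pure edge subtraction: the expression's flattened
(attribute, value) pairs minus the Superconcept's own defining pairs under
*exact* equality. A pair whose value is only approximately covered (a more
specific value than the definition's) stays in the Delta — imprecise
coverage is not coverage. Role-group structure is flattened here: the
mapping rules address attributes, not groups.

## Mapping to FHIR elements

Expressions are first assigned to one of five content categories
(allergic reactions, allergies, diseases due to allergy, general clinical
findings, procedures), each defined by an ECL-lite constraint; the
constraints must be pairwise disjoint and this is checked over the whole
terminology at load time. Membership is tested on the focus concepts, so
assignment can precede classification, with the Superconcept as fallback.

Each category/profile-set combination has one FHIR R4 StructureMap with
exactly one `Superconcept` rule and one rule per mappable attribute; a
rule marked `extension` records that the element is representable only by
introducing a standard extension into the profile. The FHIRPath subset
covers dotted element names, `:slice` suffixes and `extension(<url>)`
steps — the shipped maps use nothing more. `apply_mapping()` binds the
Superconcept and every Delta edge (falling back to the nearest ancestor
attribute that has a rule) and reports uncovered edges in `unmapped`,
never silently.

`emit_resources()` writes each binding as a SNOMED Coding at its path; in
the emitted dialect every mapped element holds an array (of Codings under
a `coding` segment, of extension entries, or of CodeableConcepts),
intermediate elements are created as single objects, declared references
between the emitted resources are materialised, and the original
expression is stored in `meta.tag` as a safeguard against lossy maps.
Extraction mirrors emission and ignores non-SNOMED codings, so resources
edited by other systems only contribute the codings this pipeline is
about.

Reverse mapping must resolve paths shared by several attributes. The case
distinctions run in order: (1) keep the candidates whose range constraint
admits the code — if one remains, done; (2) if the rest form a single
hierarchy chain, take the most general; (3) otherwise take the attribute
most often used with that value across the terminology's definitions;
final ties go to the lowest id. Rule 2 intentionally generalizes (a
using-access-device coding recomposes as using-device when both share a
path), which is why round trips can end one-directional rather than
equivalent.

## Coverage accounting

`coverage_report()` counts, per map, the category elements with a direct
rule, with an extension rule, and with none. Aggregates are
element-weighted — sums over all rows, not means of row percentages; that
is the only aggregation under which the shipped bundle's direct coverage
(76.1%) and with-extension coverage (93.5%) are simultaneously consistent
with its row extremes (56–92% direct, 67% minimum with extensions), and
the tests pin all five figures.

## The synthetic fixtures

The bundled `allergy-mini` fixture is a static ~80-concept polyhierarchy:
finding, procedure, substance, body-structure, morphology, device and
qualifier subtrees, an attribute subtree containing the three-level device
attribute chain needed by reverse-mapping rule 2, five disjoint category
subtrees, a full MRCM table, and the 10-map StructureMap bundle. Its
flagship expression — an allergic reaction caused by a tree nut, with
swelling — classifies to exactly two incomparable candidates, of which the
tree-nut reaction concept wins the similarity and the swelling morphology
forms the Delta.

`generate_terminology()` builds randomized fixtures from a
`fixture_spec()`: seeded, byte-identical for equal specs, with
configurable concept count, parent fan-in, defined fraction and role-group
probability. `generate_pce_corpus()` draws semantically valid expressions
from a terminology's MRCM-admissible attribute/value ranges; 33 such
expressions mirror the scale of a realistic evaluation corpus.
Corpus refinements are ungrouped by default: under strict grouping
semantics, a grouped original can never be equivalent to the recomposed
expression (recomposition always produces ungrouped refinements), so the
lossless round-trip condition is only attainable for ungrouped authoring —
grouped expressions still round-trip to a one-directional subsumption
verdict.

What the fixtures do *not* emulate: the degree distribution, depth and
multiple inheritance density of a full terminology release, description
logic beyond EL with role groups, and profile-level validation of the
emitted resources. Passing the suite therefore demonstrates the algebra of
the pipeline — subsumption, scoring, subtraction, mapping, reversal — not
performance or completeness on a real release.

## Problem sizes and numerical choices

The test suite classifies against fixtures of 20–80 concepts and checks
the classifier against a brute-force subsumer enumeration on 100 random
fixtures (two expressions each); similarity values are compared after
rounding to two decimals, which is also how scores are displayed.
Similarity is computed in log space directly; the only special value is
the `+Inf` equivalence score, kept rather than dividing by zero. All set
computations are over character id vectors with a numeric-order sort
(length, then lexicographic) so that identifiers beyond double precision
remain exact.

## Limitations

* Structural subsumption is incomplete w.r.t. full SNOMED CT OWL
  semantics; an external reasoner can be cross-checked via the OWL export.
* Delta subtraction is exact-match only; subsumption-aware coverage is a
  deliberate non-goal (imprecise matches must surface in the Delta).
* The emitted resource dialect is a faithful carrier for round-tripping,
  not a profile-validated rendering of any national profile set.
* Reverse mapping of many-to-one paths loses precision by design; the
  original expression is preserved in `meta.tag` for exact recovery.
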