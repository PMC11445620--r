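# sctfhir

Store SNOMED CT **postcoordinated expressions** (PCEs) in **FHIR R4
resources** using only precoordinated codes — and get them back.

Clinical systems and FHIR search expect single codes in well-known
elements, but SNOMED CT's Compositional Grammar lets authors build
arbitrarily rich expressions such as

```
71620000:{363698007=722738000}    # Fracture of femur : {Finding site = Bone structure of left femur}
```

`sctfhir` decomposes such an expression into

* a **Superconcept** — the released concept most similar to the PCE among
  its direct subsumers, found by structural EL classification and a
  shared-ancestor similarity
  `sim = -log2((|T(pce) \ T(c)| - 1) / |T(pce) ∪ T(c)|)`
  over self-inclusive ancestor sets `T(·)`, and
* a **Delta** — the attribute–value pairs the Superconcept's definition
  does not cover, obtained by exact graph subtraction,

then binds both to FHIRPath elements of Condition, AllergyIntolerance,
Procedure and Observation resources via FHIR **StructureMap** rules, emits
the resource JSON, and can reverse the whole process: extract the codings,
resolve each element path back to a SNOMED attribute (by value range,
attribute hierarchy, then an occurrence heuristic), recompose a PCE and
compare it with the original by structural subsumption.

Everything runs against a terminology loaded from RF2-snapshot-dialect TSV
files with a built-in desk-scale engine — no terminology server, no
external reasoner (an OWL functional-syntax export is available for
cross-checking). A synthetic ~80-concept `allergy-mini` fixture with
concept-model rules, five disjoint content categories and a bundle of 10
StructureMaps (5 categories × 2 profile sets) ships with the package.

## Worked example

```r
library(sctfhir)

mini <- build_allergy_mini()        # bundled fixture: terminology, MRCM, categories, maps
pl <- list(term = mini$terminology, mrcm = mini$mrcm, categories = mini$categories,
           maps = mini$maps, elements = mini$elements, profileSet = "nashp-like")

# an allergic reaction caused by tree nut, with swelling
report <- cmd_decompose("400001:116676008=320001,246075003=300002", pl)
print(report)
```

```
expression: 400001:116676008=320001,246075003=300002
validation: ok
candidates: 400002, 400003
superconcept: 400003
  400002: nonshared 4, union 7, similarity 1.22
  400003: nonshared 2, union 7, similarity 2.81
delta: 116676008=320001
category: allergic-reaction
bindings:
  Condition.code <- 400003 (Superconcept)
  AllergyIntolerance.reaction.manifestation.coding:snomed <- 320001 (116676008)
```

Classification finds two incomparable candidates: `400003` (allergic
reaction caused by tree nut) and `400002` (swelling). `400003` shares 5 of
the 7 ancestors of the inserted pce node (nonshared 2, union 7 →
similarity 2.81) versus 3 for `400002` (similarity 1.22), so it becomes
the Superconcept and is bound to `Condition.code`; the uncovered swelling
morphology is the Delta and lands in the allergy manifestation element.
The round trip closes:

```r
res <- cmd_recompose(report$resources, pl,
                     original = "400001:116676008=320001,246075003=300002")
res$text        # "400003:116676008=320001"
res$comparison  # "equivalent"
```

Coverage of the shipped map bundle (element-weighted over all 10 maps):

```r
print(cmd_coverage(pl))
#> direct coverage: 76.1% (rows 56%-92%)
#> with extensions: 93.5% (rows 67%-100%)
```

## Package layout

| Area | Contents |
|---|---|
| `R/terminology.R`, `R/validate.R` | RF2 loading, ancestor closure, MRCM validation |
| `R/expression.R`, `R/normalize.R` | Compositional Grammar parser/serializer, normal forms |
| `R/classification.R`, `R/superdelta.R` | structural subsumption, candidates, similarity, Delta |
| `R/owl.R` | OWL functional-syntax export/import |
| `R/ecl.R`, `R/structuremap.R`, `R/fhir_resources.R`, `R/recompose.R` | ECL-lite, StructureMaps, resource emission/extraction, reverse mapping |
| `R/fixtures.R`, `R/allergy_mini.R` | synthetic terminology generator, bundled fixture |
| `R/app.R`, `inst/cli/sctfhir` | pipeline commands and CLI |

See the vignette
(`vignettes/decomposing-postcoordinated-expressions.Rmd`) for the model,
its assumptions and the design decisions.
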