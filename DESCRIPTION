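Package: sctfhir
Title: Decompose SNOMED CT Postcoordinated Expressions into FHIR R4 Resource Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for storing SNOMED CT postcoordinated expressions (PCEs)
    in HL7 FHIR R4 resources using only precoordinated codes. A PCE written
    in the SNOMED Compositional Grammar is parsed, validated against
    concept-model (MRCM) rules, and classified within a terminology loaded
    from RF2-snapshot files by a built-in structural EL subsumption engine.
    The most similar precoordinated subsumer (the Superconcept) is chosen
    with a shared-ancestor semantic similarity measure, the residual
    attribute-value pairs (the Delta) are obtained by graph subtraction, and
    both are bound to FHIRPath elements of Condition, AllergyIntolerance,
    Procedure and Observation resources via FHIR StructureMap rules. The
    reverse direction recomposes a PCE from stored resources and checks
    round-trip equivalence. Includes an OWL functional-syntax export, a
    synthetic mini-terminology generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
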