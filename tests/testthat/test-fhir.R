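test_that("ECL-lite membership follows is-a evaluation", {
  term <- mini$terminology
  # universal constraint
  expect_true(all(vapply(term$concepts$id, function(c)
    eval_ecl_lite(term, "<< 100001", c), logical(1))))
  # strict descendant excludes the concept itself
  expect_false(eval_ecl_lite(term, "< 400001", "400001"))
  expect_true(eval_ecl_lite(term, "< 400001", "400003"))
  # MINUS removes the subtrahend subtree
  expect_false(eval_ecl_lite(term, "<< 100002 MINUS << 400001", "400003"))
  expect_true(eval_ecl_lite(term, "<< 100002 MINUS << 400001", "400002"))
  # AND and parentheses
  expect_true(eval_ecl_lite(term, "(<< 100002 AND << 400001) MINUS << 400003", "400004"))
  expect_false(eval_ecl_lite(term, "<< 100002 AND << 100003", "400001"))
  expect_error(eval_ecl_lite(term, "<< ", "400001"), class = "sctfhir_ecl_error")
  expect_error(eval_ecl_lite(term, ">> 100002", "400001"), class = "sctfhir_ecl_error")
})

test_that("category assignment is unique and error-guarded", {
  term <- mini$terminology
  cat <- assign_category(term, parse_expression("500003"), mini$categories)
  expect_equal(cat$id, "procedure")
  expect_equal(assign_category(term, mini$flagship, mini$categories)$id,
               "allergic-reaction")
  expect_equal(assign_category(term, parse_expression("400002"), mini$categories)$id,
               "clinical-finding")
  # outside all constraints
  expect_error(assign_category(term, parse_expression("300001"), mini$categories),
               class = "sctfhir_uncategorized_error")
  # superconcept fallback
  cat <- assign_category(term, parse_expression("300001"), mini$categories,
                         superconcept = "400002")
  expect_equal(cat$id, "clinical-finding")
  # overlapping configuration is detected
  overlap <- c(mini$categories, list(structure(
    list(id = "dup", name = "dup", constraint = "<< 400001",
         profileSets = "nashp-like"), class = "sct_category")))
  expect_error(check_category_disjointness(term, overlap),
               class = "sctfhir_disjointness_error")
  expect_error(assign_category(term, mini$flagship, overlap),
               class = "sctfhir_disjointness_error")
})

test_that("the shipped bundle loads with the documented rule tables", {
  dir <- file.path(system.file("extdata", "allergy-mini", package = "sctfhir"), "maps")
  maps <- load_structuremap_bundle(dir)
  # 5 categories x 2 profile sets
  expect_length(maps, 10)
  expect_length(unique(vapply(maps, function(m) m$categoryId, character(1))), 5)
  expect_length(unique(vapply(maps, function(m) m$profileSetId, character(1))), 2)
  # causative agent binds to AllergyIntolerance.code in the allergic-reaction map
  ar <- maps[["allergic-reaction--nashp-like"]]
  expect_equal(ar$rules$targetPath[ar$rules$source == "246075003"],
               "AllergyIntolerance.code")
  expect_equal(ar$rules$targetPath[ar$rules$source == "Superconcept"],
               "Condition.code")
  expect_equal(unname(ar$profiles["AllergyIntolerance"]), "KBV_PR_Base_AllergyIntolerance")
})

test_that("malformed StructureMaps are rejected", {
  doc <- sctfhir:::structuremap_document(list(
    category = "c", profileSet = "p",
    rules = list(list(source = "Superconcept", path = "Condition.code", ext = FALSE),
                 list(source = "Superconcept", path = "Condition.bodySite", ext = FALSE)),
    references = list(), profiles = character(0)))
  expect_error(load_structuremap(doc), class = "sctfhir_schema_error")
  doc2 <- sctfhir:::structuremap_document(list(
    category = "c", profileSet = "p",
    rules = list(list(source = "Superconcept", path = "not a path", ext = FALSE)),
    references = list(), profiles = character(0)))
  expect_error(load_structuremap(doc2), class = "sctfhir_schema_error")
})

test_that("mapping binds the superconcept and delta edges by rule", {
  term <- mini$terminology
  map <- mini$maps[["allergic-reaction--nashp-like"]]
  delta <- compute_delta(term, mini$flagship, "400003")
  res <- apply_mapping(map, "400003", delta, term)
  expect_equal(nrow(res$bindings), 1 + length(delta$edges))
  expect_equal(res$bindings$path[res$bindings$source == "Superconcept"], "Condition.code")
  expect_equal(res$bindings$code[res$bindings$source == "116676008"], "320001")
  expect_equal(res$bindings$display[res$bindings$source == "Superconcept"],
               "Allergic reaction caused by tree nut (finding)")
  # a delta edge with no applicable rule lands in unmapped
  d2 <- structure(list(edges = list(attribute_pair("363702006", "400002")),
                       matched = list(), dummyRoot = "dummy-root"), class = "sct_delta")
  res2 <- apply_mapping(map, "400003", d2, term)
  expect_length(res2$unmapped, 1)
  expect_equal(nrow(res2$bindings), 1)
})

test_that("an attribute without its own rule falls back to the nearest ancestor rule", {
  term <- mini$terminology
  map <- mini$maps[["procedure--nashp-like"]]
  # the map has rules for using-device and using-access-device; an edge with
  # the (ancestor) procedure-device attribute has no rule and stays unmapped,
  # while a device edge under a map with only the using-device rule
  # generalises to it
  slim <- map
  slim$rules <- map$rules[map$rules$source %in% c("Superconcept", "424226004"), , drop = FALSE]
  d <- structure(list(edges = list(attribute_pair("425391005", "330001")),
                      matched = list(), dummyRoot = "dummy-root"), class = "sct_delta")
  res <- apply_mapping(slim, "500002", d, term)
  expect_equal(res$bindings$source[2], "424226004")
  expect_equal(res$bindings$path[2], "Device.type")
})

test_that("emitted resources round-trip through extraction", {
  term <- mini$terminology
  map <- mini$maps[["allergic-reaction--nashp-like"]]
  delta <- compute_delta(term, mini$flagship, "400003")
  res <- apply_mapping(map, "400003", delta, term)
  docs <- emit_resources(res, context = list(originalExpression = mini$flagship))
  expect_setequal(names(docs), c("Condition", "AllergyIntolerance"))
  expect_equal(docs$Condition$meta$profile[[1]], "KBV_PR_Base_Condition")
  expect_equal(docs$AllergyIntolerance$patient$reference, "Patient/example")
  # JSON serialization round-trip keeps the structure
  json <- jsonlite::toJSON(docs$AllergyIntolerance, auto_unbox = TRUE)
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  extracted <- extract_bindings(list(docs$Condition, parsed), map)
  expect_setequal(paste(extracted$path, extracted$code),
                  paste(res$bindings$path, res$bindings$code))
  # non-SNOMED codings at a mapped path are ignored
  docs2 <- docs
  docs2$Condition$code <- c(docs2$Condition$code,
                            list(list(coding = list(list(system = "http://loinc.org",
                                                         code = "1234-5")))))
  extracted2 <- extract_bindings(list(docs2$Condition, docs$AllergyIntolerance), map)
  expect_false("1234-5" %in% extracted2$code)
  # a deleted superconcept element leaves the slot empty downstream
  docs3 <- docs
  docs3$Condition$code <- NULL
  extracted3 <- extract_bindings(list(docs3$Condition, docs$AllergyIntolerance), map)
  expect_false(any(extracted3$path == "Condition.code"))
  expect_error(recompose(extracted3, map, term, mini$mrcm),
               class = "sctfhir_recomposition_error")
  # empty bindings signal a broken map
  empty <- structure(list(bindings = res$bindings[0, ], unmapped = list(),
                          referencesUsed = res$referencesUsed[0, ],
                          profiles = character(0)), class = "sct_mapping_result")
  expect_error(emit_resources(empty), class = "sctfhir_emission_error")
})

test_that("reference rules materialise between emitted resources", {
  term <- mini$terminology
  map <- mini$maps[["procedure--nashp-like"]]
  d <- structure(list(edges = list(attribute_pair("424226004", "330003")),
                      matched = list(), dummyRoot = "dummy-root"), class = "sct_delta")
  res <- apply_mapping(map, "500003", d, term)
  docs <- emit_resources(res)
  expect_setequal(names(docs), c("Procedure", "Device"))
  expect_equal(docs$Procedure$usedReference$reference, "Device/device-1")
})

test_that("reverse attribute resolution applies the case-distinction rules", {
  term <- mini$terminology; rules <- mini$mrcm
  # single-candidate path: rules never consulted
  map <- mini$maps[["allergic-reaction--nashp-like"]]
  expect_equal(reverse_attribute(list(path = "AllergyIntolerance.code", code = "300002"),
                                 map, term, rules), "246075003")
  # rule 1: only the associated-morphology range admits a morphology code
  b <- list(path = "AllergyIntolerance.reaction.manifestation.coding:snomed",
            code = "320001")
  expect_equal(reverse_attribute(b, map, term, rules), "116676008")
  # rule 1 undecided, rule 2 skipped (different hierarchies), rule 3 counts:
  # pathological process is used in definitions, has-realization never
  b <- list(path = "AllergyIntolerance.reaction.manifestation.coding:snomed",
            code = "360002")
  expect_equal(reverse_attribute(b, map, term, rules), "370135005")
  # rule 2: a chain of device attributes resolves to the most general
  chain_map <- load_structuremap(sctfhir:::structuremap_document(list(
    category = "procedure", profileSet = "box2",
    rules = list(list(source = "Superconcept", path = "Procedure.code", ext = FALSE),
                 list(source = "405815000", path = "Device.type", ext = FALSE),
                 list(source = "424226004", path = "Device.type", ext = FALSE),
                 list(source = "425391005", path = "Device.type", ext = FALSE)),
    references = list(), profiles = character(0))))
  expect_equal(reverse_attribute(list(path = "Device.type", code = "330001"),
                                 chain_map, term, rules), "405815000")
  # shipped procedure map: using-device wins over using-access-device
  pmap <- mini$maps[["procedure--nashp-like"]]
  expect_equal(reverse_attribute(list(path = "Device.type", code = "330001"),
                                 pmap, term, rules), "424226004")
  # a non-access device is admitted only by the using-device range (rule 1)
  expect_equal(reverse_attribute(list(path = "Device.type", code = "330003"),
                                 pmap, term, rules), "424226004")
  # an unmapped path has no candidates
  expect_error(reverse_attribute(list(path = "Condition.stage", code = "300001"),
                                 map, term, rules), class = "sctfhir_reverse_error")
})

test_that("coverage accounting reproduces the bundle's aggregate figures", {
  cov <- coverage_report(mini$maps, mini$elements)
  expect_equal(nrow(cov$rows), 10)
  al <- cov$rows[cov$rows$category == "allergy" & cov$rows$profileSet == "nashp-like", ]
  expect_equal(c(al$totalElements, al$mappable, al$unmappable, al$viaExtension),
               c(9, 5, 4, 1))
  expect_true(all(cov$rows$mappable + cov$rows$unmappable == cov$rows$totalElements))
  expect_true(all(cov$rows$viaExtension <= cov$rows$unmappable))
  expect_equal(round(cov$aggregates$directPct, 1), 76.1)
  expect_equal(round(cov$aggregates$withExtensionPct, 1), 93.5)
  # a rule outside the category's element list is a schema error
  broken <- mini$maps
  broken[[1]]$rules$source[2] <- "999999"
  expect_error(coverage_report(broken, mini$elements), class = "sctfhir_schema_error")
})
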