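test_that("decomposition produces a complete report on the flagship expression", {
  report <- cmd_decompose("400001:116676008=320001,246075003=300002", mini_pipeline)
  expect_true(report$validation$ok)
  expect_setequal(report$candidates$candidates, c("400002", "400003"))
  expect_equal(report$scores$chosen, "400003")
  expect_length(report$delta$edges, 1)
  expect_equal(report$category$id, "allergic-reaction")
  expect_gt(nrow(report$mapping$bindings), 1)
  expect_true("Condition" %in% names(report$resources))
  json <- render_report(report, "json")
  expect_silent(jsonlite::fromJSON(json))
  expect_match(render_report(report, "text"), "superconcept: 400003")
})

test_that("invalid input stops after the validation stage", {
  report <- cmd_decompose("400001:{", mini_pipeline)
  expect_false(report$validation$ok)
  expect_equal(report$validation$issues$code, "syntax")
  expect_null(report$candidates)
  report2 <- cmd_decompose("400001:{246075003=310001}", mini_pipeline)
  expect_false(report2$validation$ok)
  expect_null(report2$candidates)
})

test_that("an expression equivalent to a precoordinated concept yields an empty delta", {
  report <- cmd_decompose("400003", mini_pipeline)
  expect_equal(report$candidates$equivalentTo, "400003")
  expect_length(report$delta$edges, 0)
  expect_equal(nrow(report$mapping$bindings), 1)
})

test_that("emit-then-recompose closes the loop on the flagship expression", {
  report <- cmd_decompose("400001:116676008=320001,246075003=300002", mini_pipeline)
  files <- write_resources(report$resources, tempfile())
  res <- cmd_recompose(files, mini_pipeline,
                       original = "400001:116676008=320001,246075003=300002")
  expect_equal(res$text, "400003:116676008=320001")
  expect_equal(res$comparison, "equivalent")
  unlink(dirname(files[1]), recursive = TRUE)
})

test_that("a generalized attribute gives a one-directional comparison", {
  # using-access-device reverses to using-device through the shared path
  report <- cmd_decompose("500001:425391005=330001", mini_pipeline)
  expect_true(report$validation$ok)
  res <- cmd_recompose(report$resources, mini_pipeline,
                       original = "500001:425391005=330001")
  expect_equal(res$text, "500001:424226004=330001")
  expect_equal(res$comparison, "recomposed-subsumes-original")
})

test_that("round trips over a random corpus preserve or generalize the expression", {
  term <- mini$terminology
  focus_pool <- term$concepts$id[vapply(term$concepts$id, function(c)
    is_subtype(term, c, "100002") || is_subtype(term, c, "100003"), logical(1))]
  corpus <- generate_pce_corpus(term, 12, seed = 9, mrcm = mini$mrcm,
                                focus_pool = focus_pool)
  for (e in corpus) {
    report <- cmd_decompose(e, mini_pipeline)
    expect_true(report$validation$ok)
    res <- cmd_recompose(report$resources, mini_pipeline, original = e)
    map <- mini$maps[[paste0(report$category$id, "--nashp-like")]]
    b <- report$mapping$bindings
    reversed <- vapply(seq_len(nrow(b)), function(i) {
      if (b$source[i] == "Superconcept") "Superconcept"
      else reverse_attribute(b[i, ], map, term, mini$mrcm)
    }, character(1))
    if (length(report$mapping$unmapped) == 0 && all(reversed == b$source) &&
        !anyDuplicated(paste(b$path, b$code))) {
      # lossless map for this expression: the cycle is equivalence-preserving
      expect_equal(res$comparison, "equivalent")
    } else if (all(mapply(function(r, s) {
      s == "Superconcept" || is_subtype(term, s, r)
    }, reversed, b$source))) {
      # every substitution generalizes its attribute: one direction holds
      expect_true(res$comparison %in% c("equivalent", "recomposed-subsumes-original"))
    } else {
      expect_true(res$comparison %in% c("equivalent", "recomposed-subsumes-original",
                                        "original-subsumes-recomposed", "incomparable"))
    }
  }
})

test_that("missing superconcept elements fail recomposition", {
  report <- cmd_decompose("400001:116676008=320001,246075003=300002", mini_pipeline)
  res <- report$resources
  res$Condition$code <- NULL
  expect_error(cmd_recompose(res, mini_pipeline), class = "sctfhir_recomposition_error")
})

test_that("coverage command renders both aggregates", {
  cov <- cmd_coverage(mini_pipeline)
  expect_equal(round(cov$aggregates$directPct, 1), 76.1)
  expect_equal(round(cov$aggregates$withExtensionPct, 1), 93.5)
  out <- capture.output(print(cov))
  expect_true(any(grepl("76.1%", out, fixed = TRUE)))
  expect_true(any(grepl("93.5%", out, fixed = TRUE)))
})

test_that("pipeline configuration and disk loading work end to end", {
  dir <- system.file("extdata", "allergy-mini", package = "sctfhir")
  cfg <- pipeline_config(terminologyDir = dir,
                         mrcmPath = file.path(dir, "mrcm.yaml"),
                         categoriesPath = file.path(dir, "categories.yaml"),
                         mapsDir = file.path(dir, "maps"),
                         profileSet = "mii-like")
  report <- cmd_decompose("400001:116676008=320001,246075003=300002", cfg)
  expect_equal(report$scores$chosen, "400003")
  # the MII-flavoured maps route the delta through Condition.evidence
  expect_true(any(grepl("^Condition\\.evidence", report$mapping$bindings$path)))
  expect_error(pipeline_config(tempfile(), file.path(dir, "mrcm.yaml"),
                               file.path(dir, "categories.yaml"), file.path(dir, "maps")),
               class = "sctfhir_config_error")
})
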