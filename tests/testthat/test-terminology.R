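test_that("loading the bundled fixture reproduces its declared content", {
  dir <- system.file("extdata", "allergy-mini", package = "sctfhir")
  term <- load_rf2(dir)
  expect_s3_class(term, "sct_terminology")
  expect_equal(nrow(term$concepts), mini$manifest$activeConceptCount)
  expect_equal(nrow(term$inactive$concepts),
               mini$manifest$totalConceptCount - mini$manifest$activeConceptCount)
  # the deactivated concept is absent from the is-a adjacency
  expect_false("999999" %in% names(term$parents))
  expect_true("999999" %in% term$inactive$concepts$id)
})

test_that("integrity problems are rejected at load time", {
  # dangling destination
  expect_error(
    terminology(concept_table(c("100001", "100002")),
                relationship_table("100002", "999001")),
    class = "sctfhir_integrity_error")
  # cyclic is-a
  expect_error(
    terminology(concept_table(c("100001", "100002", "100003")),
                relationship_table(c("100002", "100003", "100002"),
                                   c("100001", "100002", "100003"))),
    class = "sctfhir_integrity_error")
  # grouped is-a edge
  expect_error(
    terminology(concept_table(c("100001", "100002")),
                relationship_table("100002", "100001", group = 1)),
    class = "sctfhir_integrity_error")
  # more than one parentless concept
  expect_error(
    terminology(concept_table(c("100001", "100002", "100003")),
                relationship_table("100003", "100001")),
    class = "sctfhir_integrity_error")
  # missing file
  expect_error(load_rf2(tempfile()), class = "sctfhir_load_error")
})

test_that("concept id validation follows the identifier rules", {
  expect_equal(is_concept_id(c("71620000", "012345", "12345", "100001")),
               c(TRUE, FALSE, FALSE, TRUE))
  # real SNOMED CT ids carry a Verhoeff check digit, synthetic ones do not
  expect_true(is_concept_id("71620000", check_digit = TRUE))
  expect_true(is_concept_id("363698007", check_digit = TRUE))
  expect_false(is_concept_id("71620001", check_digit = TRUE))
})

test_that("ancestor sets are self-inclusive and follow the is-a closure", {
  ch <- chain_term()
  expect_equal(ancestors(ch, "100001"), "100001")
  expect_setequal(ancestors(ch, "100003"), c("100003", "100002", "100001"))
  di <- diamond_term()
  expect_length(ancestors(di, "100013"), 4)
  expect_true(is_subtype(di, "100013", "100012"))
  expect_true(is_subtype(ch, "100003", "100003"))
  expect_true(is_subtype(ch, "100003", "100001"))
  expect_false(is_subtype(ch, "100001", "100003"))
})

test_that("ancestors agree with the igraph reachability oracle on all fixtures", {
  for (term in list(chain_term(), diamond_term(), mini$terminology)) {
    for (c in term$concepts$id) {
      expect_equal(sort(ancestors(term, c)), igraph_ancestors(term, c))
    }
  }
})

test_that("ancestor monotonicity holds on the bundled fixture", {
  term <- mini$terminology
  ids <- term$concepts$id
  for (a in sample(ids, 20)) {
    for (b in ancestors(term, a)) {
      expect_true(all(ancestors(term, b) %in% ancestors(term, a)))
    }
  }
})

test_that("lookups of unknown ids signal lookup errors", {
  expect_error(ancestors(mini$terminology, "123456"), class = "sctfhir_lookup_error")
  expect_error(is_subtype(mini$terminology, "400001", "123456"),
               class = "sctfhir_lookup_error")
  expect_error(attribute_usage_counts(mini$terminology, "123456"),
               class = "sctfhir_lookup_error")
})

test_that("attribute usage counts scan the definitions", {
  term <- mini$terminology
  # tree nut substance: only Causative agent ever takes values under it
  counts <- attribute_usage_counts(term, "300002")
  expect_equal(counts, c("246075003" = 1L))
  # values under the substance root: four causative-agent uses
  # (nut twice, tree nut, drug), no other attribute
  counts <- attribute_usage_counts(term, "100005")
  expect_equal(counts, c("246075003" = 4L))
  # a value that never occurs
  expect_length(attribute_usage_counts(term, "370002"), 0)
  # process qualifiers: pathological process used twice, never has-realization
  counts <- attribute_usage_counts(term, "360001")
  expect_equal(counts, c("370135005" = 2L))
})
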