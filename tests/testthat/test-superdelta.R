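test_that("similarity from counts reproduces the reference values", {
  expect_equal(round(similarity_from_counts(8, 30), 2), 2.10)
  expect_equal(round(similarity_from_counts(29, 30), 2), 0.10)
  expect_equal(round(similarity_from_counts(15, 30), 2), 1.10)
  expect_identical(similarity_from_counts(1, 30), Inf)
  expect_error(similarity_from_counts(0, 30), class = "sctfhir_argument_error")
  expect_error(similarity_from_counts(31, 30), class = "sctfhir_argument_error")
  expect_error(similarity_from_counts(2, 0), class = "sctfhir_argument_error")
})

test_that("similarity is monotone in both counts", {
  for (un in c(10, 30, 100)) {
    vals <- vapply(2:un, function(ns) similarity_from_counts(ns, un), numeric(1))
    expect_true(all(diff(vals) < 0))        # grows nonshared -> less similar
  }
  for (ns in c(2, 5, 20)) {
    vals <- vapply(ns:60, function(un) similarity_from_counts(ns, un), numeric(1))
    expect_true(all(diff(vals) > 0))        # grows union -> more similar
  }
  # ordering by similarity equals ordering by ascending nonshared/union ratio
  set.seed(1)
  un <- sample(5:50, 20, replace = TRUE)
  ns <- vapply(un, function(u) sample(2:u, 1), integer(1))
  vals <- mapply(similarity_from_counts, ns, un)
  expect_equal(order(vals), order((ns - 1) / un, decreasing = TRUE))
})

test_that("the pce node is inserted under focus, candidates and values", {
  term <- mini$terminology
  # focus-only expression whose only candidate is its focus: edges collapse
  e <- parse_expression("400001")
  h <- insert_pce_node(term, e, structure(list(candidates = "400001",
                                               equivalentTo = "400001"),
                                          class = "sct_candidates"))
  expect_equal(h$parents, "400001")
  # flagship: focus plus two candidates, minus the duplicate
  cand <- superconcept_candidates(term, mini$flagship)
  h2 <- insert_pce_node(term, mini$flagship, cand)
  expect_setequal(h2$parents, c("400001", "400002", "400003"))
  expect_length(h2$attributeValues, 2)
  expect_true("pce" %in% h2$ancestorSet)
})

test_that("scoring prefers the candidate sharing more ancestors", {
  term <- mini$terminology
  cand <- superconcept_candidates(term, mini$flagship)
  res <- score_candidates(term, mini$flagship, cand)
  expect_equal(res$chosen, "400003")
  expect_false(res$tieBreakUsed)
  s <- res$scores
  # both candidates are parents of the pce node, so the union is T(pce)
  expect_equal(unique(s$union), length(unique(c("pce",
    ancestors(term, "400001"), ancestors(term, "400002"), ancestors(term, "400003")))))
  expect_lt(s$nonshared[s$candidateId == "400003"],
            s$nonshared[s$candidateId == "400002"])
  # single candidate wins regardless of value
  single <- structure(list(candidates = "400002", equivalentTo = NULL),
                      class = "sct_candidates")
  expect_equal(score_candidates(term, mini$flagship, single)$chosen, "400002")
})

test_that("equivalence short-circuits scoring with infinite similarity", {
  term <- mini$terminology
  e <- parse_expression("400003")
  cand <- superconcept_candidates(term, e)
  res <- score_candidates(term, e, cand)
  expect_equal(res$chosen, "400003")
  expect_identical(res$scores$value[res$scores$candidateId == "400003"], Inf)
})

test_that("ties break toward the more specific candidate, then the lower id", {
  # symmetric diamond: two incomparable fully defined candidates with equal
  # ancestor counts
  scores <- data.frame(candidateId = c("100020", "100003"),
                       nonshared = c(3L, 3L), union = c(9L, 9L),
                       value = c(1.5, 1.5), stringsAsFactors = FALSE)
  pick <- choose_superconcept(scores)
  expect_true(pick$tieBreakUsed)
  expect_equal(pick$chosen, "100003")  # numerically lower id
  # a larger candidate ancestor set wins before the id comparison
  scores$nonshared <- c(2L, 3L)
  scores$value <- c(1.5, 1.5)
  expect_equal(choose_superconcept(scores)$chosen, "100020")
})

test_that("delta is the exact-match edge subtraction", {
  term <- mini$terminology
  # all pairs covered verbatim by the superconcept definition
  d <- compute_delta(term, parse_expression("400001:246075003=300002"), "400003")
  expect_length(d$edges, 0)
  expect_length(d$matched, 1)
  # partial coverage
  d <- compute_delta(term, mini$flagship, "400003")
  expect_length(d$edges, 1)
  expect_equal(d$edges[[1]]$attribute, "116676008")
  # information conservation: matched and delta partition the flattened pairs
  all_keys <- sort(vapply(sctfhir:::flatten_pairs(mini$flagship),
                          sctfhir:::pair_key, character(1)))
  got <- sort(vapply(c(d$edges, d$matched), sctfhir:::pair_key, character(1)))
  expect_equal(got, all_keys)
  # a more specific value than the definition's stays in the delta
  d <- compute_delta(term, parse_expression("400001:246075003=300002"), "400004")
  expect_length(d$edges, 1)
  expect_equal(d$edges[[1]]$value, "300002")
})
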