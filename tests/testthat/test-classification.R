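test_that("structural subsumption follows the matching clauses", {
  term <- mini$terminology
  ne <- normalize_expression(term, mini$flagship)
  # the root subsumes everything
  expect_true(expr_subsumed_by(term, ne, "100001"))
  # primitive ancestor of a proximal primitive
  expect_true(expr_subsumed_by(term, ne, "400001"))
  # fully defined: definitional pair matched by a more specific pair
  expect_true(expr_subsumed_by(term, ne, "400004"))
  expect_true(expr_subsumed_by(term, ne, "400003"))
  # fully defined concept demanding an absent pair
  expect_false(expr_subsumed_by(term, ne, "400005"))
  expect_false(expr_subsumed_by(term, ne, "400006"))
  # unrelated primitive subtree
  expect_false(expr_subsumed_by(term, ne, "400010"))
})

test_that("role-group structure is significant for definitional groups", {
  concepts <- rbind(concept_table(c("100001", "100002", "910001", "930001")),
                    concept_table("200001", status = "fullyDefined"))
  rels <- rbind(
    relationship_table(c("100002", "910001", "930001", "200001"),
                       c("100001", "100001", "100001", "100002")),
    relationship_table("200001", "930001", type = "910001", group = 1))
  rels$id <- as.character(seq_len(nrow(rels)))
  term <- terminology(concepts, rels)
  grouped <- parse_expression("100002:{910001=930001}")
  ungrouped <- parse_expression("100002:910001=930001")
  # the grouped definition of 200001 is satisfied only by a grouped pair
  expect_true(expr_subsumed_by(term, normalize_expression(term, grouped), "200001"))
  expect_false(expr_subsumed_by(term, normalize_expression(term, ungrouped), "200001"))
  # and the two spellings of the refinement are not equivalent
  expect_false(expr_equivalent(term, grouped, ungrouped))
  # but the ungrouped requirement is satisfied by a grouped pair
  expect_equal(expr_subsumption(term, ungrouped, grouped), "e1-subsumes-e2")
})

test_that("candidate sets are minimal and detect equivalence", {
  term <- mini$terminology
  # a bare precoordinated concept is equivalent to itself
  cand <- superconcept_candidates(term, parse_expression("400003"))
  expect_equal(cand$equivalentTo, "400003")
  expect_equal(cand$candidates, "400003")
  # an expression spelling out a concept's definition is equivalent to it
  cand <- superconcept_candidates(term, parse_expression("400001:246075003=300002"))
  expect_equal(cand$equivalentTo, "400003")
  # the flagship expression has exactly the two incomparable candidates
  cand <- superconcept_candidates(term, mini$flagship)
  expect_null(cand$equivalentTo)
  expect_setequal(cand$candidates, c("400002", "400003"))
  expect_false(is_subtype(term, "400002", "400003"))
  expect_false(is_subtype(term, "400003", "400002"))
})

test_that("every candidate subsumes the expression and no strict descendant does", {
  term <- mini$terminology
  corpus <- generate_pce_corpus(term, 10, seed = 11, mrcm = mini$mrcm)
  for (e in corpus) {
    ne <- normalize_expression(term, e)
    cand <- superconcept_candidates(term, e)
    for (c in cand$candidates) {
      expect_true(expr_subsumed_by(term, ne, c))
      descendants <- setdiff(term$concepts$id[vapply(term$concepts$id, function(x)
        c %in% setdiff(ancestors(term, x), x), logical(1))], cand$candidates)
      expect_false(any(vapply(descendants, function(d)
        expr_subsumed_by(term, ne, d), logical(1))))
    }
  }
})

test_that("candidates equal the brute-force oracle on random terminologies", {
  for (seed in 1:5) {
    fx <- generate_terminology(fixture_spec(seed = seed, conceptCount = 40,
                                            definedFraction = 0.4))
    corpus <- generate_pce_corpus(fx$terminology, 3, seed = seed + 100, mrcm = fx$mrcm)
    for (e in corpus) {
      cand <- superconcept_candidates(fx$terminology, e)
      if (is.null(cand$equivalentTo)) {
        expect_equal(sort(cand$candidates), oracle_candidates(fx$terminology, e))
      } else {
        expect_true(cand$equivalentTo %in% oracle_candidates(fx$terminology, e))
      }
    }
  }
})

test_that("refining an expression is monotone for subsumers", {
  # a more refined expression is more specific, so every subsumer of the
  # base expression still subsumes the refined one
  term <- mini$terminology
  base <- parse_expression("400001:246075003=300002")
  refined <- parse_expression("400001:246075003=300002,116676008=320001")
  nb <- normalize_expression(term, base)
  nr <- normalize_expression(term, refined)
  sb <- term$concepts$id[vapply(term$concepts$id, function(c)
    expr_subsumed_by(term, nb, c), logical(1))]
  sr <- term$concepts$id[vapply(term$concepts$id, function(c)
    expr_subsumed_by(term, nr, c), logical(1))]
  expect_true(all(sb %in% sr))
  expect_true("400002" %in% setdiff(sr, sb))
})

test_that("value generalization gives one-directional subsumption", {
  term <- mini$terminology
  specific <- parse_expression("400001:246075003=300002")
  general <- parse_expression("400001:246075003=300001")
  expect_false(expr_equivalent(term, specific, general))
  expect_equal(expr_subsumption(term, specific, general), "e2-subsumes-e1")
  expect_true(expr_equivalent(term, specific, specific))
})
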