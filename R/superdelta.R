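# Superconcept choice via shared-ancestor semantic similarity, and the Delta
# (residual attribute-value pairs) by graph subtraction.

#' Insert the transient "pce" node over a terminology
#'
#' Builds the augmented-graph handle used for similarity scoring: a
#' transient node `pce` with is-a edges to every focus concept of the
#' expression and every Superconcept candidate (deduplicated), and attribute
#' edges to each attribute value. The underlying terminology is never
#' modified.
#'
#' @param term An `sct_terminology`.
#' @param e An `sct_expression`.
#' @param candidates An `sct_candidates` from [superconcept_candidates()].
#' @return An `sct_pce_node` with fields `parents`, `attributeValues`, and
#'   `ancestorSet` (the self-inclusive ancestor set T(pce), in which the
#'   transient node is represented by the label `"pce"`).
#' @export
insert_pce_node <- function(term, e, candidates) {
  parents <- sort_ids(unique(c(e$focus, candidates$candidates)))
  values <- vapply(flatten_pairs(e), function(p) serialize_value(p$value), character(1))
  anc <- unique(c("pce", unlist(lapply(parents, function(p) ancestors(term, p)), use.names = FALSE)))
  structure(list(parents = parents,
                 attributeValues = unique(values),
                 ancestorSet = anc),
            class = "sct_pce_node")
}

#' Shared-ancestor semantic similarity from ancestor counts
#'
#' The similarity between a postcoordinated expression and a Superconcept
#' candidate, computed from `nonshared` (the number of ancestors of the
#' inserted pce node that the candidate does not share, the pce node itself
#' included) and `union` (the size of the union of both self-inclusive
#' ancestor sets): `-log2((nonshared - 1) / union)`. The subtracted 1
#' removes the transient pce node from the nonshared count. When
#' `nonshared == 1` the candidate shares every named ancestor and the
#' similarity is `+Inf` (the equivalence case).
#'
#' @param nonshared Integer, `1 <= nonshared <= union`.
#' @param union Integer, `union >= 1`.
#' @return A non-negative number or `Inf`. Values are reported rounded to
#'   two decimals in user output but returned unrounded.
#' @examples
#' round(similarity_from_counts(8, 30), 2)   # 2.10
#' round(similarity_from_counts(29, 30), 2)  # 0.10
#' @export
similarity_from_counts <- function(nonshared, union) {
  if (!is.numeric(nonshared) || !is.numeric(union) ||
      length(nonshared) != 1 || length(union) != 1 ||
      union < 1 || nonshared < 1 || nonshared > union) {
    sct_error("sctfhir_argument_error",
              "similarity counts must satisfy 1 <= nonshared <= union and union >= 1")
  }
  if (nonshared == 1) return(Inf)
  -log2((nonshared - 1) / union)
}

#' Choose the Superconcept from a scored candidate table
#'
#' The candidate with the maximal similarity wins. Ties are broken
#' deterministically: larger candidate ancestor set (`union - nonshared`,
#' the more specific candidate) first, then the lower numeric id.
#'
#' @param scores Data frame with columns `candidateId`, `nonshared`,
#'   `union`, `value`.
#' @return List with `chosen` (id) and `tieBreakUsed` (flag).
#' @export
choose_superconcept <- function(scores) {
  stopifnot(nrow(scores) >= 1)
  top <- scores[scores$value == max(scores$value), , drop = FALSE]
  tie <- nrow(top) > 1
  if (tie) {
    size <- top$union - top$nonshared  # |T(candidate)|
    top <- top[order(-size, nchar(top$candidateId), top$candidateId, method = "radix"), , drop = FALSE]
  }
  list(chosen = top$candidateId[1], tieBreakUsed = tie)
}

#' Score Superconcept candidates and choose the Superconcept
#'
#' Inserts the transient pce node, computes for each candidate the
#' nonshared-ancestor and ancestor-union counts over self-inclusive ancestor
#' sets, scores them with [similarity_from_counts()], and picks the argmax
#' (see [choose_superconcept()] for the tie-break). When the candidate set
#' records an equivalence, the equivalent concept is chosen with similarity
#' `+Inf`.
#'
#' @param term An `sct_terminology`.
#' @param e An `sct_expression`.
#' @param candidates A non-empty `sct_candidates`.
#' @return An `sct_superconcept_result` with fields `scores` (data frame),
#'   `chosen`, `tieBreakUsed`.
#' @export
score_candidates <- function(term, e, candidates) {
  if (length(candidates$candidates) == 0) {
    sct_error("sctfhir_argument_error", "candidate set is empty")
  }
  handle <- insert_pce_node(term, e, candidates)
  t_pce <- handle$ancestorSet
  rows <- lapply(candidates$candidates, function(c) {
    t_c <- ancestors(term, c)
    nonshared <- length(setdiff(t_pce, t_c))
    un <- length(union(t_pce, t_c))
    data.frame(candidateId = c, nonshared = nonshared, union = un,
               value = similarity_from_counts(nonshared, un),
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  if (!is.null(candidates$equivalentTo)) {
    chosen <- candidates$equivalentTo
    tie <- FALSE
    scores$value[scores$candidateId == chosen] <- Inf
    scores$nonshared[scores$candidateId == chosen] <- 1L
  } else {
    pick <- choose_superconcept(scores)
    chosen <- pick$chosen
    tie <- pick$tieBreakUsed
  }
  structure(list(scores = scores, chosen = chosen, tieBreakUsed = tie),
            class = "sct_superconcept_result")
}

#' @export
print.sct_superconcept_result <- function(x, ...) {
  s <- x$scores
  s$value <- round(s$value, 2)
  print(s, row.names = FALSE)
  cat(sprintf("chosen Superconcept: %s%s\n", x$chosen,
              if (x$tieBreakUsed) " (tie-break used)" else ""))
  invisible(x)
}

#' Compute the Delta between an expression and its Superconcept
#'
#' Both the expression and the Superconcept's definition are flattened to
#' sets of (attribute, value) edges under a shared dummy root, and the
#' Superconcept's edges are subtracted from the expression's under exact
#' attribute-and-value equality. Pairs whose value is only imprecisely
#' represented in the Superconcept (for example a more specific value)
#' therefore stay in the Delta.
#'
#' @param term An `sct_terminology`.
#' @param e An `sct_expression`.
#' @param superconcept The chosen Superconcept id.
#' @return An `sct_delta` with fields `edges` (residual pairs), `matched`
#'   (pairs covered by the Superconcept definition), and `dummyRoot`.
#' @export
compute_delta <- function(term, e, superconcept) {
  assert_concept(term, superconcept)
  pce_pairs <- flatten_pairs(e)
  pce_keys <- vapply(pce_pairs, pair_key, character(1))
  ord <- order(pce_keys, method = "radix")
  pce_pairs <- pce_pairs[ord][!duplicated(pce_keys[ord])]
  pce_keys <- sort(unique(pce_keys))

  def <- term$definitions[[superconcept]] %||% list(ungrouped = list(), groups = list())
  sc_keys <- vapply(c(def$ungrouped, do.call(c, c(def$groups, list(NULL)))),
                    pair_key, character(1))
  in_sc <- pce_keys %in% sc_keys
  structure(list(edges = pce_pairs[!in_sc],
                 matched = pce_pairs[in_sc],
                 dummyRoot = "dummy-root"),
            class = "sct_delta")
}

#' @export
print.sct_delta <- function(x, ...) {
  if (length(x$edges) == 0) {
    cat("<sct_delta> empty (fully covered by the Superconcept)\n")
  } else {
    cat("<sct_delta>\n")
    for (p in x$edges) cat("  ", pair_key(p), "\n", sep = "")
  }
  invisible(x)
}
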