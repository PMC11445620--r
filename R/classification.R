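# Structural EL subsumption with role groups: the desk-scale replacement for
# a description logic reasoner. Sound but incomplete with respect to full
# SNOMED CT OWL semantics (no property chains or transitive attributes other
# than is-a), which the fixtures deliberately avoid.

# Does the subsumer template `nd` (a normalized expression or concept normal
# form) hold for the normalized subsumee `ne`?
#  - every proximal primitive of nd must be an ancestor of some proximal
#    primitive of ne;
#  - every ungrouped pair of nd must be matched by some pair of ne
#    (ungrouped requirements may be satisfied by grouped pairs);
#  - every group of nd must be matched wholly within a single group of ne
#    (strict grouping: an ungrouped expression pair never satisfies a
#    grouped requirement).
subsumer_matches <- function(term, ne, nd) {
  for (p in nd$proximalPrimitives) {
    hit <- any(vapply(ne$proximalPrimitives, function(q) p %in% ancestors(term, q), logical(1)))
    if (!hit) return(FALSE)
  }
  all_pairs <- c(ne$ungrouped, do.call(c, c(ne$groups, list(NULL))))
  for (pd in nd$ungrouped) {
    hit <- any(vapply(all_pairs, function(pe) pair_refines(term, pe, pd), logical(1)))
    if (!hit) return(FALSE)
  }
  for (gd in nd$groups) {
    hit <- any(vapply(ne$groups, function(ge) {
      all(vapply(gd, function(pd) {
        any(vapply(ge, function(pe) pair_refines(term, pe, pd), logical(1)))
      }, logical(1)))
    }, logical(1)))
    if (!hit) return(FALSE)
  }
  TRUE
}

# Normalized-expression-vs-concept subsumption.
norm_subsumed_by <- function(term, ne, c) {
  assert_concept(term, c)
  if (!is_fully_defined(term, c)) {
    return(any(vapply(ne$proximalPrimitives, function(q) c %in% ancestors(term, q), logical(1))))
  }
  subsumer_matches(term, ne, normalize_concept(term, c))
}

#' Is a normalized expression subsumed by a precoordinated concept?
#'
#' A primitive concept subsumes the expression iff it is an ancestor of one
#' of the expression's proximal primitives. A fully defined concept subsumes
#' it iff the expression satisfies every requirement of the concept's normal
#' form: proximal primitive ancestry, every ungrouped definitional pair
#' matched by some expression pair (attribute and value each subsumed), and
#' every definitional role group matched wholly within a single expression
#' group.
#'
#' @param term An `sct_terminology`.
#' @param e An `sct_normexpr` from [normalize_expression()].
#' @param c An active concept id.
#' @return Logical flag.
#' @export
expr_subsumed_by <- function(term, e, c) {
  stopifnot(inherits(e, "sct_normexpr"))
  norm_subsumed_by(term, e, c)
}

#' Superconcept candidates of a postcoordinated expression
#'
#' Enumerates the active precoordinated concepts that subsume the expression
#' under structural EL subsumption and keeps the minimal (most specific,
#' pairwise is-a incomparable) ones. When the expression is structurally
#' equivalent to a precoordinated concept, that concept is returned as sole
#' candidate in `equivalentTo` and downstream similarity scoring becomes
#' degenerate.
#'
#' @param term An `sct_terminology`.
#' @param e An `sct_expression`.
#' @return An `sct_candidates` object with fields `candidates` (character)
#'   and `equivalentTo` (id or `NULL`).
#' @export
superconcept_candidates <- function(term, e) {
  ne <- normalize_expression(term, e)
  ids <- term$concepts$id
  subsumes <- vapply(ids, function(c) norm_subsumed_by(term, ne, c), logical(1))
  S <- ids[subsumes]
  if (length(S) == 0) S <- term$rootId  # unreachable: the root subsumes everything
  minimal <- S[vapply(S, function(c) {
    !any(vapply(setdiff(S, c), function(s) c %in% setdiff(ancestors(term, s), s), logical(1)))
  }, logical(1))]
  equivalent_to <- NULL
  for (c in minimal) {
    if (subsumer_matches(term, normalize_concept(term, c), ne)) {
      equivalent_to <- c
      break
    }
  }
  if (!is.null(equivalent_to)) {
    minimal <- equivalent_to
  }
  structure(list(candidates = sort_ids(minimal), equivalentTo = equivalent_to),
            class = "sct_candidates")
}

#' @export
print.sct_candidates <- function(x, ...) {
  cat(sprintf("<sct_candidates> {%s}%s\n", paste(x$candidates, collapse = ", "),
              if (!is.null(x$equivalentTo)) paste0(" (equivalent to ", x$equivalentTo, ")") else ""))
  invisible(x)
}

#' Structural equivalence of two expressions
#'
#' `TRUE` iff each expression is structurally subsumed by the other, with the
#' counterpart's normalized form treated as the subsumer template. Grouping
#' is significant: a pair inside a role group and the same pair ungrouped
#' are not equivalent.
#'
#' @param term An `sct_terminology`.
#' @param e1,e2 `sct_expression` objects.
#' @return Logical flag.
#' @export
expr_equivalent <- function(term, e1, e2) {
  n1 <- normalize_expression(term, e1)
  n2 <- normalize_expression(term, e2)
  subsumer_matches(term, n1, n2) && subsumer_matches(term, n2, n1)
}

#' Subsumption relation between two expressions
#'
#' @param term An `sct_terminology`.
#' @param e1,e2 `sct_expression` objects.
#' @return One of `"equivalent"`, `"e1-subsumes-e2"`, `"e2-subsumes-e1"`,
#'   `"incomparable"`.
#' @export
expr_subsumption <- function(term, e1, e2) {
  n1 <- normalize_expression(term, e1)
  n2 <- normalize_expression(term, e2)
  a <- subsumer_matches(term, n2, n1)  # e1 subsumes e2
  b <- subsumer_matches(term, n1, n2)  # e2 subsumes e1
  if (a && b) "equivalent"
  else if (a) "e1-subsumes-e2"
  else if (b) "e2-subsumes-e1"
  else "incomparable"
}
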