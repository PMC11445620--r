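# Expression normalization: rewrite to proximal primitive supertypes plus
# merged definitional refinements. This is the form the structural
# subsumption engine works on.

new_normexpr <- function(pp, ungrouped, groups) {
  structure(list(proximalPrimitives = sort_ids(unique(pp)),
                 ungrouped = ungrouped, groups = groups),
            class = "sct_normexpr")
}

#' @export
print.sct_normexpr <- function(x, ...) {
  cat(sprintf("<sct_normexpr> proximal primitives {%s}, %d ungrouped pair(s), %d group(s)\n",
              paste(x$proximalPrimitives, collapse = ", "),
              length(x$ungrouped), length(x$groups)))
  invisible(x)
}

# Normal form of a precoordinated concept: proximal primitives are reached by
# expanding fully defined concepts through their parents; definitional
# attribute pairs accumulate while the expansion passes through fully
# defined concepts (a primitive supertype's own differentia are necessary
# conditions already captured by the ancestor test, so expansion stops
# there). Memoized per terminology.
normalize_concept <- function(term, c) {
  assert_concept(term, c)
  key <- paste0("nrm_", c)
  cached <- term$cache[[key]]
  if (!is.null(cached)) return(cached)
  if (!is_fully_defined(term, c)) {
    out <- new_normexpr(c, list(), list())
  } else {
    def <- term$definitions[[c]] %||% list(ungrouped = list(), groups = list())
    pp <- character(0); ungrouped <- def$ungrouped; groups <- def$groups
    for (p in term$parents[[c]]) {
      pn <- normalize_concept(term, p)
      pp <- c(pp, pn$proximalPrimitives)
      ungrouped <- c(ungrouped, pn$ungrouped)
      groups <- c(groups, pn$groups)
    }
    if (length(pp) == 0) pp <- term$rootId  # fully defined child of the root
    out <- tidy_normexpr(term, new_normexpr(pp, ungrouped, groups))
  }
  term$cache[[key]] <- out
  out
}

#' Normalize a postcoordinated expression
#'
#' Every fully defined focus concept is replaced by its definition,
#' recursively, down to proximal primitive supertypes; its definitional role
#' groups and ungrouped pairs are merged into the expression's refinement.
#' Nested expression values are themselves normalized. Redundant pairs (a
#' pair implied by a more specific pair in the same scope, judged by
#' attribute and value subsumption) are removed, and a definitional group is
#' merged into a refinement group only when the refinement group refines one
#' of its pairs; otherwise the groups are kept side by side.
#'
#' @param term An `sct_terminology`.
#' @param e An `sct_expression` whose concept ids all exist in `term`.
#' @param max_depth Recursion guard for nested expression values.
#' @return An `sct_normexpr` with fields `proximalPrimitives`, `ungrouped`,
#'   `groups`.
#' @export
normalize_expression <- function(term, e, max_depth = 10) {
  stopifnot(inherits(e, "sct_expression"))
  if (max_depth < 0) {
    sct_error("sctfhir_normalization_error", "expression nesting exceeds the normalization depth limit")
  }
  pp <- character(0)
  def_ungrouped <- list(); def_groups <- list()
  for (f in e$focus) {
    fn <- normalize_concept(term, f)
    pp <- c(pp, fn$proximalPrimitives)
    def_ungrouped <- c(def_ungrouped, fn$ungrouped)
    def_groups <- c(def_groups, fn$groups)
  }
  norm_value <- function(v) {
    if (is.character(v)) { assert_concept(term, v); v }
    else normalize_expression(term, v, max_depth - 1)
  }
  norm_pairs <- function(pairs) lapply(pairs, function(p) {
    assert_concept(term, p$attribute)
    attribute_pair(p$attribute, norm_value(p$value))
  })
  ref_ungrouped <- norm_pairs(e$ungrouped)
  ref_groups <- lapply(e$groups, norm_pairs)

  groups <- merge_definition_groups(term, ref_groups, def_groups)
  tidy_normexpr(term, new_normexpr(pp, c(ref_ungrouped, def_ungrouped), groups))
}

# A definitional group is folded into the first refinement group containing a
# pair that refines (attribute- and value-subsumes) one of its pairs.
merge_definition_groups <- function(term, ref_groups, def_groups) {
  groups <- ref_groups
  for (dg in def_groups) {
    target <- 0L
    for (i in seq_along(ref_groups)) {
      hit <- any(vapply(ref_groups[[i]], function(pr) {
        any(vapply(dg, function(pd) pair_refines(term, pr, pd), logical(1)))
      }, logical(1)))
      if (hit) { target <- i; break }
    }
    if (target > 0L) {
      groups[[target]] <- c(groups[[target]], dg)
    } else {
      groups[[length(groups) + 1L]] <- dg
    }
  }
  groups
}

# pr refines pd: pr's attribute is a subtype of pd's and pr's value is
# subsumed by pd's value.
pair_refines <- function(term, pr, pd) {
  is_subtype(term, pr$attribute, pd$attribute) &&
    value_subsumed(term, pr$value, pd$value)
}

# Value subsumption across the two value representations (concept id or
# normalized nested expression).
value_subsumed <- function(term, v_sub, v_gen) {
  sub_is_id <- is.character(v_sub)
  gen_is_id <- is.character(v_gen)
  if (sub_is_id && gen_is_id) return(is_subtype(term, v_sub, v_gen))
  ne_sub <- if (sub_is_id) normalize_concept(term, v_sub) else v_sub
  if (gen_is_id) return(norm_subsumed_by(term, ne_sub, v_gen))
  subsumer_matches(term, ne_sub, v_gen)
}

value_key <- function(v) {
  if (is.character(v)) v else paste0("(", normexpr_key(v), ")")
}

normexpr_key <- function(ne) {
  items <- c(
    sort_pair_texts(vapply(ne$ungrouped, function(p) paste0(p$attribute, "=", value_key(p$value)), character(1))),
    sort(vapply(ne$groups, function(g) {
      paste0("{", paste(sort_pair_texts(vapply(g, function(p)
        paste0(p$attribute, "=", value_key(p$value)), character(1))), collapse = ","), "}")
    }, character(1)), method = "radix")
  )
  paste(c(paste(ne$proximalPrimitives, collapse = "+"), items), collapse = ":")
}

# Remove pairs implied by a more specific sibling, deduplicate, minimize the
# proximal primitive set, and drop subset-duplicate groups.
tidy_normexpr <- function(term, ne) {
  pp <- ne$proximalPrimitives
  keep_pp <- vapply(pp, function(a) {
    !any(vapply(setdiff(pp, a), function(b) is_subtype(term, b, a), logical(1)))
  }, logical(1))
  pp <- pp[keep_pp]

  clean <- function(pairs) {
    keys <- vapply(pairs, function(p) paste0(p$attribute, "=", value_key(p$value)), character(1))
    ord <- order(keys, method = "radix")
    pairs <- pairs[ord]; keys <- keys[ord]
    keep <- !duplicated(keys)
    pairs <- pairs[keep]
    n <- length(pairs)
    if (n <= 1) return(pairs)
    redundant <- logical(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || redundant[j]) next
        if (pair_refines(term, pairs[[j]], pairs[[i]]) &&
            !(pair_refines(term, pairs[[i]], pairs[[j]]) && j > i)) {
          redundant[i] <- TRUE
          break
        }
      }
    }
    pairs[!redundant]
  }

  ungrouped <- clean(ne$ungrouped)
  groups <- lapply(ne$groups, clean)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  # drop groups whose pair keys are a subset of another group's
  gkeys <- lapply(groups, function(g)
    sort(vapply(g, function(p) paste0(p$attribute, "=", value_key(p$value)), character(1))))
  n <- length(groups)
  if (n > 1) {
    drop <- logical(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || drop[j]) next
        if (all(gkeys[[i]] %in% gkeys[[j]]) &&
            !(all(gkeys[[j]] %in% gkeys[[i]]) && j > i)) {
          drop[i] <- TRUE
          break
        }
      }
    }
    groups <- groups[!drop]
  }
  gtext <- vapply(groups, function(g)
    paste(sort(vapply(g, function(p) paste0(p$attribute, "=", value_key(p$value)), character(1))), collapse = ","),
    character(1))
  groups <- groups[order(gtext, method = "radix")]
  new_normexpr(pp, ungrouped, groups)
}

# Rebuild an expression from a normalized form (possible when no nested
# expression values are present); used for idempotence checking and for the
# converse direction of equivalence testing.
normexpr_as_expression <- function(ne) {
  to_value <- function(v) if (is.character(v)) v else normexpr_as_expression(v)
  expression_ast(
    focus = ne$proximalPrimitives,
    ungrouped = lapply(ne$ungrouped, function(p) attribute_pair(p$attribute, to_value(p$value))),
    groups = lapply(ne$groups, function(g)
      lapply(g, function(p) attribute_pair(p$attribute, to_value(p$value))))
  )
}
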