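# Reverse direction: map FHIR element paths back to SNOMED CT attributes and
# recompose a postcoordinated expression from stored resources.

#' Determine the SNOMED attribute behind an extracted binding
#'
#' Most mapping rules are unidirectional, so a FHIR element path may map
#' back to several possible attributes. The case-distinction rules are
#' applied successively until one attribute remains:
#' 1. by attribute value range: keep the candidates whose concept-model
#'    range constraint admits the extracted code; if exactly one matches it
#'    is the answer;
#' 2. by attribute hierarchy: if the remaining candidates all lie in one
#'    is-a chain, the most general of them is selected;
#' 3. by occurrence heuristic: the attribute most frequently used with the
#'    extracted value across precoordinated definitions
#'    ([attribute_usage_counts()]) is selected.
#' Remaining ties fall to the lowest numeric id.
#'
#' @param b One binding (a row of [extract_bindings()] output, or a list
#'   with `path` and `code`).
#' @param map The governing `sct_structuremap`.
#' @param term An `sct_terminology`.
#' @param rules Named list of `sct_mrcm_rule`s.
#' @return The attribute concept id.
#' @export
reverse_attribute <- function(b, map, term, rules) {
  cand <- map$rules$source[map$rules$targetPath == b$path & map$rules$source != "Superconcept"]
  if (length(cand) == 0) {
    sct_error("sctfhir_reverse_error", sprintf(
      "no attribute rule maps to path %s", b$path))
  }
  if (length(cand) == 1) return(cand)

  # rule 1: value range
  code_is_concept <- is_concept_id(b$code) && has_concept(term, b$code)
  if (code_is_concept) {
    admits <- vapply(cand, function(a) {
      r <- rules[[a]]
      is.null(r) || eval_ecl_lite(term, r$rangeConstraint, b$code)
    }, logical(1))
    if (sum(admits) == 1) return(cand[admits])
    if (sum(admits) > 1) cand <- cand[admits]
  }

  # rule 2: one hierarchy chain -> most general candidate
  comparable <- all(vapply(cand, function(a) {
    all(vapply(cand, function(b2) {
      is_subtype(term, a, b2) || is_subtype(term, b2, a)
    }, logical(1)))
  }, logical(1)))
  if (comparable) {
    top <- cand[vapply(cand, function(a) {
      all(vapply(cand, function(b2) is_subtype(term, b2, a), logical(1)))
    }, logical(1))]
    if (length(top) >= 1) return(top[1])
  }

  # rule 3: occurrence heuristic
  if (code_is_concept) {
    counts <- attribute_usage_counts(term, b$code)
    n <- vapply(cand, function(a) if (is.na(counts[a])) 0L else counts[[a]], integer(1))
    cand <- cand[n == max(n)]
  }
  sort_ids(cand)[1]
}

#' Recompose a postcoordinated expression from extracted bindings
#'
#' The Superconcept (the coding found at the map's Superconcept path)
#' becomes the focus concept; every other binding becomes an ungrouped
#' attribute pair whose attribute is determined by [reverse_attribute()].
#'
#' @param bindings Data frame from [extract_bindings()].
#' @param map The governing `sct_structuremap`.
#' @param term An `sct_terminology`.
#' @param rules Named list of `sct_mrcm_rule`s.
#' @return A canonical `sct_expression`.
#' @export
recompose <- function(bindings, map, term, rules) {
  super_path <- map$rules$targetPath[map$rules$source == "Superconcept"]
  is_super <- bindings$path == super_path
  if (!any(is_super)) {
    sct_error("sctfhir_recomposition_error",
              "no Superconcept binding found (missing coding at the Superconcept path)")
  }
  focus <- bindings$code[is_super][1]
  rest <- bindings[!is_super, , drop = FALSE]
  pairs <- list()
  seen <- character(0)
  for (i in seq_len(nrow(rest))) {
    b <- rest[i, ]
    attr_id <- reverse_attribute(b, map, term, rules)
    value <- if (is_concept_id(b$code)) b$code
             else parse_expression(sub("\\)$", "", sub("^\\(", "", b$code)))
    key <- paste0(attr_id, "=", b$code)
    if (key %in% seen) next
    seen <- c(seen, key)
    pairs[[length(pairs) + 1L]] <- attribute_pair(attr_id, value)
  }
  canonical_expression(expression_ast(focus = focus, ungrouped = pairs))
}
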