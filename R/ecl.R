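# ECL-lite: the expression-constraint subset used for MRCM domains/ranges
# and content-category definitions: "<< id" (descendant-or-self), "< id"
# (strict descendant), AND, MINUS, parentheses.

ecl_tokenize <- function(constraint) {
  text <- gsub("([()])", " \\1 ", constraint)
  text <- gsub("(<<|<)", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(toks) == 0 || identical(toks, "")) {
    sct_error("sctfhir_ecl_error", "empty expression constraint")
  }
  toks
}

ecl_parse <- function(constraint) {
  toks <- ecl_tokenize(constraint)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { tk <- peek(); pos <<- pos + 1L; tk }
  err <- function(found, expected) {
    sct_error("sctfhir_ecl_error", sprintf(
      "constraint parse error in %s: found '%s', expected %s",
      dQuote(constraint, q = FALSE), found, expected))
  }
  parse_primary <- function() {
    tk <- take()
    if (tk == "(") {
      node <- parse_expr()
      if (take() != ")") err(peek(), "')'")
      return(node)
    }
    if (tk %in% c("<<", "<")) {
      id <- take()
      if (!is_concept_id(id)) err(id, "a concept id")
      return(list(op = tk, id = id))
    }
    err(tk, "'<<', '<' or '('")
  }
  parse_expr <- function() {
    node <- parse_primary()
    while (peek() %in% c("AND", "MINUS")) {
      op <- take()
      rhs <- parse_primary()
      node <- list(op = op, lhs = node, rhs = rhs)
    }
    node
  }
  node <- parse_expr()
  if (peek() != "") err(peek(), "end of constraint")
  node
}

ecl_eval_node <- function(term, node, c) {
  switch(node$op,
    "<<" = is_subtype(term, c, node$id),
    "<" = c != node$id && is_subtype(term, c, node$id),
    "AND" = ecl_eval_node(term, node$lhs, c) && ecl_eval_node(term, node$rhs, c),
    "MINUS" = ecl_eval_node(term, node$lhs, c) && !ecl_eval_node(term, node$rhs, c))
}

#' Evaluate an ECL-lite constraint for a concept
#'
#' @param term An `sct_terminology`.
#' @param constraint Constraint text, e.g. `"<< 100002 MINUS << 400001"`.
#' @param c A concept id.
#' @return Logical flag: does `c` belong to the constrained set?
#' @export
eval_ecl_lite <- function(term, constraint, c) {
  assert_concept(term, c)
  ecl_eval_node(term, ecl_parse(constraint), c)
}

#' Check that an ECL-lite constraint parses
#' @param constraint Constraint text.
#' @return `TRUE`, invisibly; signals a parse error otherwise.
#' @keywords internal
ecl_check <- function(constraint) {
  ecl_parse(constraint)
  invisible(TRUE)
}
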