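# SNOMED Compositional Grammar: parsing, canonical serialization, and the
# expression AST.

#' Construct an attribute-value pair
#'
#' @param attribute Attribute concept id.
#' @param value Concept id, or a nested `sct_expression` for expression
#'   values.
#' @return An `sct_pair`.
#' @export
attribute_pair <- function(attribute, value) {
  structure(list(attribute = as.character(attribute), value = value),
            class = "sct_pair")
}

#' Construct a postcoordinated expression AST
#'
#' @param focus Character vector of focus concept ids (at least one, no
#'   duplicates; duplicates are rejected to surface authoring errors).
#' @param ungrouped List of `sct_pair` refinements outside any role group.
#' @param groups List of role groups, each a non-empty list of `sct_pair`s.
#' @param definitionStatus `"equivalentTo"` (the default, no prefix) or
#'   `"subtypeOf"` (the `<<<` prefix).
#' @return An `sct_expression`.
#' @export
expression_ast <- function(focus, ungrouped = list(), groups = list(),
                           definitionStatus = c("equivalentTo", "subtypeOf")) {
  definitionStatus <- match.arg(definitionStatus)
  focus <- as.character(focus)
  if (length(focus) == 0) {
    sct_error("sctfhir_syntax_error", "an expression needs at least one focus concept")
  }
  if (anyDuplicated(focus)) {
    sct_error("sctfhir_syntax_error", sprintf(
      "duplicate focus concept: %s", focus[duplicated(focus)][1]))
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    sct_error("sctfhir_syntax_error", "role groups must be non-empty")
  }
  structure(list(definitionStatus = definitionStatus, focus = focus,
                 ungrouped = ungrouped, groups = groups),
            class = "sct_expression")
}

# ---- tokenizer -------------------------------------------------------------

cg_tokenize <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  tokens <- list()
  i <- 1L; line <- 1L; col <- 1L
  push <- function(type, value, l, c) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, line = l, col = c)
  }
  err <- function(msg, l = line, c = col) {
    sct_error("sctfhir_syntax_error",
              sprintf("syntax error at line %d, column %d: %s", l, c, msg),
              line = l, col = c)
  }
  advance <- function() {
    if (chars[i] == "\n") { line <<- line + 1L; col <<- 1L } else col <<- col + 1L
    i <<- i + 1L
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\r", "\n")) { advance(); next }
    l0 <- line; c0 <- col
    if (grepl("[0-9]", ch)) {
      j <- i
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      id <- paste(chars[i:(j - 1L)], collapse = "")
      while (i < j) advance()
      if (!is_concept_id(id)) err(sprintf("'%s' is not a valid concept id", id), l0, c0)
      push("ID", id, l0, c0)
    } else if (ch == "|") {
      # pipe-delimited term: accepted and discarded
      advance()
      start <- i
      while (i <= n && chars[i] != "|") advance()
      if (i > n) err("unterminated term (missing closing '|')", l0, c0)
      advance()
    } else if (ch == "=") {
      if (i + 2L <= n && chars[i + 1L] == "=" && chars[i + 2L] == "=") {
        advance(); advance(); advance()
        push("EQUIVALENT_TO", "===", l0, c0)
      } else {
        advance()
        push("EQ", "=", l0, c0)
      }
    } else if (ch == "<") {
      if (i + 2L <= n && chars[i + 1L] == "<" && chars[i + 2L] == "<") {
        advance(); advance(); advance()
        push("SUBTYPE_OF", "<<<", l0, c0)
      } else {
        err("unexpected '<' (only the '<<<' prefix is allowed here)", l0, c0)
      }
    } else if (ch %in% c(":", ",", "{", "}", "(", ")", "+")) {
      advance()
      push(ch, ch, l0, c0)
    } else {
      err(sprintf("unexpected character '%s'", ch), l0, c0)
    }
  }
  push("EOF", "", line, col)
  tokens
}

# ---- recursive-descent parser ---------------------------------------------

#' Parse a SNOMED Compositional Grammar expression
#'
#' Whitespace-insensitive; pipe-delimited display terms (`|...|`) are
#' accepted and discarded. The definition status prefix `===` (equivalent
#' to) or `<<<` (subtype of) is optional and defaults to equivalent-to.
#' Nested sub-expressions in value position are written in parentheses and
#' limited to `max_depth` levels.
#'
#' @param text Expression text.
#' @param max_depth Maximum nesting depth for expression values (default 2).
#' @return An `sct_expression`.
#' @examples
#' e <- parse_expression("71620000 |Fracture of femur| : {363698007=722738000}")
#' serialize_expression(e)
#' @export
parse_expression <- function(text, max_depth = 2) {
  tokens <- cg_tokenize(text)
  pos <- 1L
  peek <- function() tokens[[pos]]
  err <- function(expected) {
    tk <- peek()
    shown <- if (tk$type == "EOF") "end of input" else sprintf("'%s'", tk$value)
    sct_error("sctfhir_syntax_error", sprintf(
      "syntax error at line %d, column %d: found %s, expected %s",
      tk$line, tk$col, shown, expected), line = tk$line, col = tk$col)
  }
  take <- function(type, expected = NULL) {
    tk <- peek()
    if (tk$type != type) err(expected %||% sprintf("'%s'", type))
    pos <<- pos + 1L
    tk
  }

  parse_sub <- function(depth) {
    focus <- c(take("ID", "a concept id")$value)
    while (peek()$type == "+") {
      take("+")
      focus <- c(focus, take("ID", "a concept id")$value)
    }
    ungrouped <- list(); groups <- list()
    if (peek()$type == ":") {
      take(":")
      repeat {
        if (peek()$type == "{") {
          take("{")
          grp <- list(parse_pair(depth))
          while (peek()$type == ",") {
            take(",")
            grp[[length(grp) + 1L]] <- parse_pair(depth)
          }
          take("}", "',' or '}'")
          groups[[length(groups) + 1L]] <- grp
        } else {
          ungrouped[[length(ungrouped) + 1L]] <- parse_pair(depth)
        }
        if (peek()$type != ",") break
        take(",")
      }
    }
    expression_ast(focus, ungrouped, groups)
  }

  parse_pair <- function(depth) {
    attribute <- take("ID", "an attribute concept id")$value
    take("EQ", "'='")
    if (peek()$type == "(") {
      if (depth >= max_depth) {
        tk <- peek()
        sct_error("sctfhir_syntax_error", sprintf(
          "syntax error at line %d, column %d: expression nesting deeper than %d",
          tk$line, tk$col, max_depth))
      }
      take("(")
      value <- parse_sub(depth + 1L)
      take(")", "')'")
    } else {
      value <- take("ID", "a concept id or '('")$value
    }
    attribute_pair(attribute, value)
  }

  status <- "equivalentTo"
  if (peek()$type == "EQUIVALENT_TO") { take("EQUIVALENT_TO") }
  else if (peek()$type == "SUBTYPE_OF") { take("SUBTYPE_OF"); status <- "subtypeOf" }
  e <- parse_sub(0L)
  take("EOF", "end of input")
  e$definitionStatus <- status
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- canonical serialization ----------------------------------------------

serialize_value <- function(v) {
  if (is.character(v)) v else paste0("(", serialize_expression(v), ")")
}

serialize_pair <- function(p) {
  paste0(p$attribute, "=", serialize_value(p$value))
}

serialize_group <- function(g) {
  paste0("{", paste(sort_pair_texts(vapply(g, serialize_pair, character(1))), collapse = ","), "}")
}

# Pairs sort numerically by attribute id, then by value text.
sort_pair_texts <- function(texts) {
  attrs <- sub("=.*$", "", texts)
  texts[order(nchar(attrs), attrs, texts, method = "radix")]
}

#' Serialize an expression to canonical Compositional Grammar text
#'
#' Canonical form: no whitespace or display terms; focus concepts sorted
#' numerically; ungrouped pairs first (sorted by attribute id then value),
#' followed by role groups sorted by their own canonical text; the
#' equivalent-to status carries no prefix and subtype-of is written `<<<`.
#' `parse_expression(serialize_expression(e))` reproduces the canonical AST.
#'
#' @param e An `sct_expression`.
#' @return A single string.
#' @export
serialize_expression <- function(e) {
  stopifnot(inherits(e, "sct_expression"))
  prefix <- if (e$definitionStatus == "subtypeOf") "<<<" else ""
  focus <- paste(sort_ids(e$focus), collapse = "+")
  items <- c(
    sort_pair_texts(vapply(e$ungrouped, serialize_pair, character(1))),
    sort(vapply(e$groups, serialize_group, character(1)), method = "radix")
  )
  if (length(items) == 0) return(paste0(prefix, focus))
  paste0(prefix, focus, ":", paste(items, collapse = ","))
}

#' Put an expression into canonical order
#'
#' @param e An `sct_expression`.
#' @return The canonical-order `sct_expression` (round-trips through text).
#' @export
canonical_expression <- function(e) {
  parse_expression(serialize_expression(e), max_depth = Inf)
}

#' @export
print.sct_expression <- function(x, ...) {
  cat("<sct_expression> ", serialize_expression(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.sct_expression <- function(x, ...) serialize_expression(x)

# All attribute pairs of an expression, role groups flattened.
flatten_pairs <- function(e) {
  c(e$ungrouped, do.call(c, c(e$groups, list(NULL))))
}

pair_key <- function(p) {
  paste0(p$attribute, "=", serialize_value(p$value))
}
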