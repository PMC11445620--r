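# OWL functional-syntax export: class expressions for postcoordinated
# expressions and axioms for terminology definitions. Only the EL constructs
# SNOMED CT uses are emitted: Class, ObjectSomeValuesFrom,
# ObjectIntersectionOf, with role groups as an ObjectSomeValuesFrom over the
# role-group property.

DEFAULT_NAMESPACE <- "http://snomed.info/id/"
ROLE_GROUP_ID <- "609096000"

owl_class <- function(id) structure(list(kind = "Class", id = id), class = "owl_node")
owl_some <- function(property, filler)
  structure(list(kind = "ObjectSomeValuesFrom", property = property, filler = filler),
            class = "owl_node")
owl_and <- function(children) {
  stopifnot(length(children) >= 2)
  structure(list(kind = "ObjectIntersectionOf", children = children), class = "owl_node")
}

# Leading concept id of a node, used for numeric child ordering.
owl_leading_id <- function(node) {
  switch(node$kind,
    Class = node$id,
    ObjectSomeValuesFrom = node$property,
    ObjectIntersectionOf = owl_leading_id(node$children[[1]]))
}

owl_sort_children <- function(children) {
  keys <- vapply(children, owl_leading_id, character(1))
  texts <- vapply(children, owl_render, character(1))
  children[order(nchar(keys), keys, texts, method = "radix")]
}

owl_render <- function(node) {
  switch(node$kind,
    Class = paste0(":", node$id),
    ObjectSomeValuesFrom = sprintf("ObjectSomeValuesFrom(:%s %s)",
                                   node$property, owl_render(node$filler)),
    ObjectIntersectionOf = sprintf("ObjectIntersectionOf(%s)",
                                   paste(vapply(node$children, owl_render, character(1)),
                                         collapse = " ")))
}

new_owl_expression <- function(ast, namespace) {
  structure(list(ast = ast, text = owl_render(ast), namespace = namespace),
            class = "sct_owl_expression")
}

#' @export
print.sct_owl_expression <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' Translate an expression to an OWL class expression
#'
#' A single focus concept without refinement becomes a bare `Class`.
#' Otherwise an `ObjectIntersectionOf` is built from the focus classes, one
#' `ObjectSomeValuesFrom(attribute, value)` per ungrouped pair, and per role
#' group one `ObjectSomeValuesFrom(roleGroup, inner)` where `inner` is the
#' single pair's restriction or the intersection of the group's
#' restrictions. Children are ordered numerically by leading concept id for
#' byte-stable output.
#'
#' @param e An `sct_expression`.
#' @param namespace IRI prefix for concept ids (default
#'   `"http://snomed.info/id/"`).
#' @param role_group Concept id used as the role-group property.
#' @return An `sct_owl_expression` with fields `ast` and `text`.
#' @examples
#' to_owl(parse_expression("71620000:{363698007=722738000}"))$text
#' @export
to_owl <- function(e, namespace = DEFAULT_NAMESPACE, role_group = ROLE_GROUP_ID) {
  stopifnot(inherits(e, "sct_expression"))
  value_node <- function(v) {
    if (is.character(v)) owl_class(v) else to_owl(v, namespace, role_group)$ast
  }
  pair_node <- function(p) owl_some(p$attribute, value_node(p$value))
  group_node <- function(g) {
    inner <- if (length(g) == 1) pair_node(g[[1]])
             else owl_and(owl_sort_children(lapply(g, pair_node)))
    owl_some(role_group, inner)
  }
  children <- c(lapply(sort_ids(e$focus), owl_class),
                lapply(e$ungrouped, pair_node),
                lapply(e$groups, group_node))
  ast <- if (length(children) == 1) children[[1]] else owl_and(owl_sort_children(children))
  new_owl_expression(ast, namespace)
}

#' Build OWL axioms for every concept of a terminology
#'
#' One axiom per active non-root concept: `EquivalentClasses` for fully
#' defined concepts, `SubClassOf` for primitive ones. The right-hand side is
#' built from the concept's parents and definitional attribute pairs with
#' the same construction rules as [to_owl()].
#'
#' @param term An `sct_terminology`.
#' @param namespace IRI prefix.
#' @param role_group Role-group property id.
#' @return List of `sct_owl_axiom` objects (fields `kind`, `subject`,
#'   `expression`).
#' @export
ontology_axioms <- function(term, namespace = DEFAULT_NAMESPACE, role_group = ROLE_GROUP_ID) {
  ids <- setdiff(term$concepts$id, term$rootId)
  lapply(sort_ids(ids), function(id) {
    def <- term$definitions[[id]] %||% list(ungrouped = list(), groups = list())
    e <- expression_ast(focus = term$parents[[id]],
                        ungrouped = def$ungrouped, groups = def$groups)
    rhs <- to_owl(e, namespace, role_group)
    kind <- if (is_fully_defined(term, id)) "EquivalentClasses" else "SubClassOf"
    structure(list(kind = kind, subject = id, expression = rhs),
              class = "sct_owl_axiom")
  })
}

owl_axiom_text <- function(ax) {
  sprintf("%s(:%s %s)", ax$kind, ax$subject, ax$expression$text)
}

#' Write axioms as an OWL 2 functional-syntax document
#'
#' @param axioms List of `sct_owl_axiom`s (as from [ontology_axioms()]).
#' @param out Output file path.
#' @param namespace IRI bound to the default prefix.
#' @return `out`, invisibly.
#' @export
write_functional_syntax <- function(axioms, out, namespace = DEFAULT_NAMESPACE) {
  lines <- c(
    sprintf("Prefix(:=<%s>)", namespace),
    "Ontology(<http://example.org/sctfhir/ontology>",
    vapply(axioms, owl_axiom_text, character(1)),
    ")")
  writeLines(lines, out)
  invisible(out)
}

#' Read a functional-syntax document written by this package
#'
#' A minimal parser for the construct subset the exporter emits (`Class`
#' references, `ObjectSomeValuesFrom`, `ObjectIntersectionOf`,
#' `SubClassOf`, `EquivalentClasses`); used for structural round-trip
#' checking.
#'
#' @param path File path.
#' @return List with `namespace` and `axioms`.
#' @export
read_functional_syntax <- function(path) {
  lines <- readLines(path)
  ns <- sub("^Prefix\\(:=<(.*)>\\)$", "\\1", lines[grepl("^Prefix\\(:=<", lines)][1])
  body <- lines[grepl("^(SubClassOf|EquivalentClasses)\\(", lines)]
  axioms <- lapply(body, function(line) {
    kind <- sub("\\(.*$", "", line)
    inner <- sub("^[A-Za-z]+\\((.*)\\)$", "\\1", line)
    toks <- owl_tokenize(inner)
    subject <- sub("^:", "", toks$tokens[1])
    parsed <- owl_parse_node(toks$tokens, 2L)
    structure(list(kind = kind, subject = subject,
                   expression = new_owl_expression(parsed$node, ns)),
              class = "sct_owl_axiom")
  })
  list(namespace = ns, axioms = axioms)
}

owl_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  list(tokens = tokens)
}

owl_parse_node <- function(tokens, i) {
  tk <- tokens[i]
  if (startsWith(tk, ":")) {
    return(list(node = owl_class(sub("^:", "", tk)), i = i + 1L))
  }
  if (tk == "ObjectSomeValuesFrom") {
    stopifnot(tokens[i + 1L] == "(")
    property <- sub("^:", "", tokens[i + 2L])
    filler <- owl_parse_node(tokens, i + 3L)
    stopifnot(tokens[filler$i] == ")")
    return(list(node = owl_some(property, filler$node), i = filler$i + 1L))
  }
  if (tk == "ObjectIntersectionOf") {
    stopifnot(tokens[i + 1L] == "(")
    i <- i + 2L
    children <- list()
    while (tokens[i] != ")") {
      child <- owl_parse_node(tokens, i)
      children[[length(children) + 1L]] <- child$node
      i <- child$i
    }
    return(list(node = owl_and(children), i = i + 1L))
  }
  sct_error("sctfhir_load_error", sprintf("unexpected token in functional syntax: %s", tk))
}
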