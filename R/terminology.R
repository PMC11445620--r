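# Terminology container: RF2-dialect loading, the is-a DAG, ancestor sets,
# concept definitions and concept-model (MRCM) validation.

#' Construct a terminology from in-memory record tables
#'
#' The workhorse behind [load_rf2()]. Takes the three RF2-dialect tables as
#' data frames, runs the integrity checks (dangling references, cyclic is-a,
#' orphan concepts) and builds the package's terminology object: active
#' concepts, a child-to-parent is-a adjacency, and per-concept definitions
#' (ungrouped attribute pairs plus role groups) taken from the non-is-a
#' relationship rows.
#'
#' @param concepts Data frame with columns `id`, `effectiveTime`, `active`,
#'   `moduleId`, `definitionStatusId`.
#' @param relationships Data frame with columns `id`, `effectiveTime`,
#'   `active`, `moduleId`, `sourceId`, `destinationId`, `relationshipGroup`,
#'   `typeId`.
#' @param descriptions Optional data frame with columns `id`, `active`,
#'   `conceptId`, `typeId`, `term`; used to fill fully specified names.
#' @param isa_id Concept id that marks hierarchy (is-a) relationships.
#'   Defaults to the SNOMED CT is-a concept; synthetic fixtures may override.
#' @param check_digits If `TRUE`, every concept id must carry a valid
#'   Verhoeff check digit (real releases); off by default for fixtures.
#' @return An object of class `sct_terminology`.
#' @export
terminology <- function(concepts, relationships, descriptions = NULL,
                        isa_id = "116680003", check_digits = FALSE) {
  concepts$id <- as.character(concepts$id)
  concepts$active <- as_flag(concepts$active)
  concepts$definitionStatusId <- normalize_defstatus(concepts$definitionStatusId)
  for (col in c("sourceId", "destinationId", "typeId")) {
    relationships[[col]] <- as.character(relationships[[col]])
  }
  relationships$active <- as_flag(relationships$active)
  relationships$relationshipGroup <- as.integer(relationships$relationshipGroup)

  bad <- !is_concept_id(concepts$id, check_digit = check_digits)
  if (any(bad)) {
    sct_error("sctfhir_integrity_error", sprintf(
      "invalid concept id(s): %s", paste(utils::head(concepts$id[bad], 5), collapse = ", ")))
  }
  if (anyDuplicated(concepts$id)) {
    sct_error("sctfhir_integrity_error", sprintf(
      "duplicate concept id(s): %s",
      paste(unique(concepts$id[duplicated(concepts$id)]), collapse = ", ")))
  }

  act <- concepts[concepts$active, , drop = FALSE]
  rel_act <- relationships[relationships$active, , drop = FALSE]

  # Dangling references are checked against the active concept inventory.
  refs <- unique(c(rel_act$sourceId, rel_act$destinationId, rel_act$typeId))
  refs <- setdiff(refs, isa_id)
  missing_refs <- setdiff(refs, act$id)
  if (length(missing_refs) > 0) {
    sct_error("sctfhir_integrity_error", sprintf(
      "relationship references unknown or inactive concept(s): %s",
      paste(utils::head(missing_refs, 5), collapse = ", ")))
  }

  isa <- rel_act[rel_act$typeId == isa_id, , drop = FALSE]
  if (any(isa$relationshipGroup != 0L)) {
    sct_error("sctfhir_integrity_error", "is-a relationships must have relationshipGroup 0")
  }
  attr_rel <- rel_act[rel_act$typeId != isa_id, , drop = FALSE]

  parents <- split(isa$destinationId, factor(isa$sourceId, levels = act$id))
  parents <- lapply(parents, function(p) sort_ids(unique(p)))
  names(parents) <- act$id

  # Acyclicity via igraph; report one cycle on failure.
  if (nrow(isa) > 0) {
    g <- igraph::graph_from_data_frame(
      isa[, c("sourceId", "destinationId")], directed = TRUE,
      vertices = data.frame(name = act$id))
    if (!igraph::is_dag(g)) {
      cyc <- find_cycle(parents)
      sct_error("sctfhir_integrity_error", sprintf(
        "is-a hierarchy is cyclic: %s", paste(cyc, collapse = " -> ")))
    }
  }

  roots <- act$id[vapply(parents[act$id], length, integer(1)) == 0L]
  if (length(roots) != 1L) {
    sct_error("sctfhir_integrity_error", sprintf(
      "expected exactly one root concept, found %d (%s)",
      length(roots), paste(utils::head(roots, 5), collapse = ", ")))
  }

  definitions <- build_definitions(attr_rel, act$id)

  fsn <- stats::setNames(rep(NA_character_, nrow(act)), act$id)
  if (!is.null(descriptions) && nrow(descriptions) > 0) {
    descriptions$conceptId <- as.character(descriptions$conceptId)
    descriptions$active <- as_flag(descriptions$active)
    d <- descriptions[descriptions$active & descriptions$conceptId %in% act$id, , drop = FALSE]
    fsn[d$conceptId] <- d$term
  }

  structure(list(
    concepts = data.frame(
      id = act$id,
      fsn = unname(fsn[act$id]),
      active = TRUE,
      definitionStatus = act$definitionStatusId,
      stringsAsFactors = FALSE),
    parents = parents,
    definitions = definitions,
    rootId = roots,
    isaId = isa_id,
    attributeIds = sort_ids(unique(attr_rel$typeId)),
    inactive = list(
      concepts = concepts[!concepts$active, , drop = FALSE],
      relationships = relationships[!relationships$active, , drop = FALSE]),
    cache = new.env(parent = emptyenv())
  ), class = "sct_terminology")
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  as.character(x) %in% c("1", "true", "TRUE")
}

normalize_defstatus <- function(x) {
  x <- as.character(x)
  out <- ifelse(x %in% c("900000000000073002", "fullyDefined"), "fullyDefined",
         ifelse(x %in% c("900000000000074008", "primitive"), "primitive", NA))
  if (anyNA(out)) {
    sct_error("sctfhir_load_error", sprintf(
      "unknown definitionStatusId value(s): %s",
      paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

build_definitions <- function(attr_rel, ids) {
  defs <- stats::setNames(vector("list", length(ids)), ids)
  if (nrow(attr_rel) == 0) return(defs)
  ord <- order(attr_rel$sourceId, attr_rel$relationshipGroup,
               nchar(attr_rel$typeId), attr_rel$typeId,
               nchar(attr_rel$destinationId), attr_rel$destinationId,
               method = "radix")
  attr_rel <- attr_rel[ord, , drop = FALSE]
  for (src in unique(attr_rel$sourceId)) {
    rows <- attr_rel[attr_rel$sourceId == src, , drop = FALSE]
    ungrouped <- rows[rows$relationshipGroup == 0L, , drop = FALSE]
    grouped <- rows[rows$relationshipGroup != 0L, , drop = FALSE]
    groups <- lapply(split(grouped, grouped$relationshipGroup), function(gr) {
      lapply(seq_len(nrow(gr)), function(i)
        attribute_pair(gr$typeId[i], gr$destinationId[i]))
    })
    defs[[src]] <- list(
      ungrouped = lapply(seq_len(nrow(ungrouped)), function(i)
        attribute_pair(ungrouped$typeId[i], ungrouped$destinationId[i])),
      groups = unname(groups))
  }
  defs
}

# Depth-first search for one directed cycle in a child->parents adjacency.
find_cycle <- function(parents) {
  state <- new.env(parent = emptyenv())
  path <- character(0)
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return()
    s <- state[[v]]
    if (identical(s, "done")) return()
    if (identical(s, "open")) {
      i <- match(v, path)
      result <<- c(path[i:length(path)], v)
      return()
    }
    state[[v]] <- "open"
    path <<- c(path, v)
    for (p in parents[[v]]) visit(p)
    path <<- path[-length(path)]
    state[[v]] <- "done"
  }
  for (v in names(parents)) visit(v)
  result
}

#' Load an RF2-snapshot-dialect terminology from a directory
#'
#' Reads the tab-separated concept, relationship, and (optionally)
#' description files of the RF2 snapshot dialect and builds the terminology
#' graph. Only active rows enter the is-a DAG and the concept definitions;
#' inactive rows are retained in an inactive index.
#'
#' The directory must contain `concepts.tsv` and `relationships.tsv`
#' (`descriptions.tsv` is optional); files whose names merely contain
#' "concept"/"relationship"/"description" are also recognised, so real RF2
#' snapshot file names work unchanged.
#'
#' @inheritParams terminology
#' @param directory Path to the fixture or release directory.
#' @return An `sct_terminology` object.
#' @seealso [build_allergy_mini()] for the bundled fixture.
#' @examples
#' dir <- system.file("extdata", "allergy-mini", package = "sctfhir")
#' term <- load_rf2(dir, isa_id = "116680003")
#' nrow(term$concepts)
#' @export
load_rf2 <- function(directory, isa_id = "116680003", check_digits = FALSE) {
  if (!dir.exists(directory)) {
    sct_error("sctfhir_load_error", sprintf("terminology directory not found: %s", directory))
  }
  concept_file <- find_rf2_file(directory, "concept")
  rel_file <- find_rf2_file(directory, "relationship")
  desc_file <- find_rf2_file(directory, "description", required = FALSE)

  concepts <- utils::read.delim(concept_file, colClasses = "character", quote = "")
  relationships <- utils::read.delim(rel_file, colClasses = "character", quote = "")
  descriptions <- if (!is.null(desc_file)) {
    utils::read.delim(desc_file, colClasses = "character", quote = "")
  }
  terminology(concepts, relationships, descriptions,
              isa_id = isa_id, check_digits = check_digits)
}

find_rf2_file <- function(directory, kind, required = TRUE) {
  files <- list.files(directory, full.names = TRUE)
  exact <- files[basename(files) == paste0(kind, "s.tsv")]
  if (length(exact) == 1) return(exact)
  hit <- files[grepl(kind, basename(files), ignore.case = TRUE)]
  if (length(hit) >= 1) return(hit[[1]])
  if (required) {
    sct_error("sctfhir_load_error", sprintf(
      "missing %s file in %s (expected %ss.tsv)", kind, directory, kind))
  }
  NULL
}

#' @export
print.sct_terminology <- function(x, ...) {
  cat(sprintf("<sct_terminology> %d active concepts, root %s, %d attribute types\n",
              nrow(x$concepts), x$rootId, length(x$attributeIds)))
  invisible(x)
}

has_concept <- function(term, id) id %in% term$concepts$id

assert_concept <- function(term, id) {
  if (!has_concept(term, id)) {
    sct_error("sctfhir_lookup_error", sprintf("unknown or inactive concept id: %s", id))
  }
  invisible(id)
}

concept_fsn <- function(term, id) {
  i <- match(id, term$concepts$id)
  out <- term$concepts$fsn[i]
  ifelse(is.na(out), id, out)
}

is_fully_defined <- function(term, id) {
  term$concepts$definitionStatus[match(id, term$concepts$id)] == "fullyDefined"
}

#' Self-inclusive ancestor set of a concept
#'
#' Computed over is-a edges only and memoized per terminology. The set always
#' contains the concept itself; for any parent `p`, `ancestors(p)` is a
#' subset of the result.
#'
#' @param term An `sct_terminology`.
#' @param c A concept id present and active in `term`.
#' @return Character vector of ancestor ids (including `c`), in stable order.
#' @examples
#' term <- build_allergy_mini()$terminology
#' ancestors(term, term$rootId)
#' @export
ancestors <- function(term, c) {
  assert_concept(term, c)
  key <- paste0("anc_", c)
  cached <- term$cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- c
  for (p in term$parents[[c]]) {
    out <- c(out, ancestors(term, p))
  }
  out <- sort_ids(unique(out))
  term$cache[[key]] <- out
  out
}

#' Reflexive is-a subtype test
#'
#' `TRUE` iff `b` is in the self-inclusive ancestor set of `a`.
#'
#' @param term An `sct_terminology`.
#' @param a,b Concept ids.
#' @return Logical flag.
#' @export
is_subtype <- function(term, a, b) {
  assert_concept(term, b)
  b %in% ancestors(term, a)
}

#' Count defining uses of attributes for values under a concept
#'
#' For every attribute type, counts the active defining attribute pairs
#' (across all concept definitions, ungrouped and grouped alike) whose value
#' is a subtype of `value`. Used as the occurrence heuristic when a FHIR
#' element path maps back to several possible SNOMED CT attributes.
#'
#' @param term An `sct_terminology`.
#' @param value A concept id.
#' @return Named integer vector, attribute id to count; empty if the value
#'   never occurs.
#' @export
attribute_usage_counts <- function(term, value) {
  assert_concept(term, value)
  counts <- integer(0)
  for (def in term$definitions) {
    if (is.null(def)) next
    pairs <- c(def$ungrouped, do.call(c, c(def$groups, list(NULL))))
    for (p in pairs) {
      if (is.character(p$value) && is_subtype(term, p$value, value)) {
        counts[p$attribute] <- (if (is.na(counts[p$attribute])) 0L else counts[p$attribute]) + 1L
      }
    }
  }
  counts[sort_ids(names(counts))]
}
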