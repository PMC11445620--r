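# Content categories, the FHIRPath subset, FHIR R4 StructureMap loading,
# and the forward application of mapping rules to Superconcept and Delta.

SNOMED_SYSTEM <- "http://snomed.info/sct"

#' Load content-category definitions
#'
#' Categories partition the terminology into pairwise disjoint subsets, each
#' defined by an ECL-lite constraint and associated with one StructureMap
#' per profile set.
#'
#' @param path YAML (or JSON) file: a list of entries with `id`, `name`,
#'   `constraint`, `profileSets`.
#' @param term Optional `sct_terminology`; when given, pairwise disjointness
#'   of the constraints is verified over all active concepts.
#' @return List of `sct_category` objects.
#' @export
load_categories <- function(path, term = NULL) {
  if (!file.exists(path)) {
    sct_error("sctfhir_load_error", sprintf("category configuration not found: %s", path))
  }
  entries <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
             else yaml::read_yaml(path)
  categories <- lapply(entries, function(x) {
    ecl_check(x$constraint)
    structure(list(id = x$id, name = x$name %||% x$id, constraint = x$constraint,
                   profileSets = as.character(unlist(x$profileSets))),
              class = "sct_category")
  })
  if (!is.null(term)) check_category_disjointness(term, categories)
  categories
}

#' Verify that category constraints are pairwise disjoint
#'
#' @param term An `sct_terminology`.
#' @param categories List of `sct_category`s.
#' @return `TRUE` invisibly; signals a disjointness violation otherwise.
#' @export
check_category_disjointness <- function(term, categories) {
  for (c in term$concepts$id) {
    hits <- vapply(categories, function(cat) eval_ecl_lite(term, cat$constraint, c), logical(1))
    if (sum(hits) > 1) {
      sct_error("sctfhir_disjointness_error", sprintf(
        "categories %s overlap on concept %s",
        paste(vapply(categories[hits], function(x) x$id, character(1)), collapse = ", "), c))
    }
  }
  invisible(TRUE)
}

#' Assign an expression to its content category
#'
#' Membership is decided on the focus concepts first (a category matches
#' when every focus concept satisfies its constraint, so assignment can
#' precede classification); if no category matches and a Superconcept is
#' supplied, it is used as fallback.
#'
#' @param term An `sct_terminology`.
#' @param e An `sct_expression`.
#' @param categories List of `sct_category`s.
#' @param superconcept Optional chosen Superconcept id.
#' @return The matching `sct_category`.
#' @export
assign_category <- function(term, e, categories, superconcept = NULL) {
  match_on <- function(concepts) {
    vapply(categories, function(cat) {
      all(vapply(concepts, function(f) eval_ecl_lite(term, cat$constraint, f), logical(1)))
    }, logical(1))
  }
  hits <- match_on(e$focus)
  if (sum(hits) == 0 && !is.null(superconcept)) hits <- match_on(superconcept)
  if (sum(hits) == 0) {
    sct_error("sctfhir_uncategorized_error", sprintf(
      "expression %s matches no content category", serialize_expression(e)))
  }
  if (sum(hits) > 1) {
    sct_error("sctfhir_disjointness_error", sprintf(
      "expression %s matches %d categories; constraints are not disjoint",
      serialize_expression(e), sum(hits)))
  }
  categories[hits][[1]]
}

# ---- FHIRPath subset -------------------------------------------------------

# Dotted element names with optional ":slice" suffixes and "extension(<url>)"
# steps; the first segment names the resource type.
parse_fhirpath <- function(path) {
  if (!nzchar(path)) sct_error("sctfhir_schema_error", "empty FHIRPath")
  segments <- character(0)
  buf <- ""
  depth <- 0L
  for (ch in strsplit(path, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "." && depth == 0L) {
      segments <- c(segments, buf); buf <- ""
    } else buf <- paste0(buf, ch)
  }
  segments <- c(segments, buf)
  if (depth != 0L || length(segments) < 2) {
    sct_error("sctfhir_schema_error", sprintf("unparseable FHIRPath: %s", path))
  }
  resource <- segments[1]
  if (!grepl("^[A-Z][A-Za-z]*$", resource)) {
    sct_error("sctfhir_schema_error", sprintf("FHIRPath must start with a resource type: %s", path))
  }
  steps <- lapply(segments[-1], function(seg) {
    m <- regmatches(seg, regexec("^extension\\((.+)\\)$", seg))[[1]]
    if (length(m) == 2) {
      list(name = "extension", slice = NA_character_, url = m[2])
    } else {
      m2 <- regmatches(seg, regexec("^([A-Za-z]+)(?::([A-Za-z-]+))?$", seg))[[1]]
      if (length(m2) == 0) {
        sct_error("sctfhir_schema_error", sprintf("unparseable FHIRPath segment: %s", seg))
      }
      list(name = m2[2], slice = if (nzchar(m2[3])) m2[3] else NA_character_, url = NA_character_)
    }
  })
  list(resource = resource, steps = steps, path = path)
}

# ---- StructureMap loading --------------------------------------------------

#' Load a FHIR R4 StructureMap into the mapping model
#'
#' The JSON shape follows the StructureMap resource: a `mapping` group whose
#' rules carry `"Superconcept"` or an attribute id in `source[[1]]$value`
#' and a FHIRPath in `target[[1]]$value` (rule `documentation` equal to
#' `"extension"` marks mappings achievable only by introducing a standard
#' extension); a `references` group (source FHIRPath to target resource
#' type); and a `profiles` group (resource type to profile name). The map's
#' `name` is `<categoryId>--<profileSetId>`.
#'
#' @param doc Path to a JSON file, a JSON string, or an already-parsed list.
#' @return An `sct_structuremap` with fields `categoryId`, `profileSetId`,
#'   `rules` (data frame: `source`, `targetPath`, `viaExtension`),
#'   `references`, `profiles`.
#' @export
load_structuremap <- function(doc) {
  if (is.character(doc)) {
    doc <- if (file.exists(doc)) jsonlite::read_json(doc, simplifyVector = FALSE)
           else jsonlite::fromJSON(doc, simplifyVector = FALSE)
  }
  if (!identical(doc$resourceType, "StructureMap")) {
    sct_error("sctfhir_schema_error", "document is not a FHIR StructureMap")
  }
  name <- doc$name %||% ""
  parts <- strsplit(name, "--", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    sct_error("sctfhir_schema_error", sprintf(
      "StructureMap name must be '<category>--<profileSet>', got %s", dQuote(name, q = FALSE)))
  }
  groups <- stats::setNames(doc$group, vapply(doc$group, function(g) g$name, character(1)))
  g_map <- groups[["mapping"]]
  if (is.null(g_map)) sct_error("sctfhir_schema_error", "StructureMap has no 'mapping' group")
  rules <- do.call(rbind, lapply(g_map$rule, function(r) {
    data.frame(source = r$source[[1]]$value,
               targetPath = r$target[[1]]$value,
               viaExtension = identical(r$documentation, "extension"),
               stringsAsFactors = FALSE)
  }))
  if (sum(rules$source == "Superconcept") != 1) {
    sct_error("sctfhir_schema_error", "StructureMap must contain exactly one Superconcept rule")
  }
  if (anyDuplicated(rules$source)) {
    sct_error("sctfhir_schema_error", sprintf(
      "duplicate rule source(s): %s",
      paste(unique(rules$source[duplicated(rules$source)]), collapse = ", ")))
  }
  super_path <- rules$targetPath[rules$source == "Superconcept"]
  if (super_path %in% rules$targetPath[rules$source != "Superconcept"]) {
    sct_error("sctfhir_schema_error",
              "the Superconcept path may not be shared with an attribute rule")
  }
  for (p in rules$targetPath) parse_fhirpath(p)

  refs <- groups[["references"]]
  references <- if (!is.null(refs)) {
    do.call(rbind, lapply(refs$rule, function(r) {
      data.frame(fromPath = r$source[[1]]$value, toResourceType = r$target[[1]]$value,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(fromPath = character(0), toResourceType = character(0))

  profs <- groups[["profiles"]]
  profiles <- if (!is.null(profs)) {
    stats::setNames(
      vapply(profs$rule, function(r) r$target[[1]]$value, character(1)),
      vapply(profs$rule, function(r) r$source[[1]]$value, character(1)))
  } else stats::setNames(character(0), character(0))

  structure(list(categoryId = parts[1], profileSetId = parts[2],
                 rules = rules, references = references, profiles = profiles),
            class = "sct_structuremap")
}

#' Load every StructureMap in a directory
#'
#' @param dir Directory of `*.json` StructureMap documents.
#' @return Named list of `sct_structuremap`s keyed by
#'   `<categoryId>--<profileSetId>`.
#' @export
load_structuremap_bundle <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0) {
    sct_error("sctfhir_schema_error", sprintf("no StructureMap documents in %s", dir))
  }
  maps <- lapply(files, load_structuremap)
  stats::setNames(maps, vapply(maps, function(m)
    paste0(m$categoryId, "--", m$profileSetId), character(1)))
}

#' @export
print.sct_structuremap <- function(x, ...) {
  cat(sprintf("<sct_structuremap> %s--%s: %d rule(s), %d reference(s)\n",
              x$categoryId, x$profileSetId, nrow(x$rules), nrow(x$references)))
  invisible(x)
}

#' Apply a StructureMap to a Superconcept and Delta
#'
#' The Superconcept is bound to the Superconcept rule's path. Each Delta
#' edge is bound via the rule whose source equals its attribute id, or
#' failing that the nearest rule source that is an ancestor of the attribute
#' in the attribute hierarchy; edges with no applicable rule are reported in
#' `unmapped` rather than dropped. Displays are filled from fully specified
#' names.
#'
#' @param map An `sct_structuremap`.
#' @param superconcept Superconcept id.
#' @param delta An `sct_delta`.
#' @param term An `sct_terminology`.
#' @return An `sct_mapping_result` with fields `bindings` (data frame:
#'   `path`, `system`, `code`, `display`, `source`), `unmapped`,
#'   `referencesUsed`, `profiles`.
#' @export
apply_mapping <- function(map, superconcept, delta, term) {
  super_rule <- map$rules[map$rules$source == "Superconcept", , drop = FALSE]
  bindings <- data.frame(path = super_rule$targetPath, system = SNOMED_SYSTEM,
                         code = superconcept,
                         display = concept_fsn(term, superconcept),
                         source = "Superconcept", stringsAsFactors = FALSE)
  attr_rules <- map$rules[map$rules$source != "Superconcept", , drop = FALSE]
  unmapped <- list()
  for (edge in delta$edges) {
    rule_i <- match(edge$attribute, attr_rules$source)
    if (is.na(rule_i)) {
      # nearest rule source that is an ancestor of the attribute
      anc <- if (has_concept(term, edge$attribute)) ancestors(term, edge$attribute) else edge$attribute
      cand <- which(attr_rules$source %in% setdiff(anc, edge$attribute))
      if (length(cand) > 0) {
        depth <- vapply(attr_rules$source[cand], function(s) length(ancestors(term, s)), integer(1))
        cand <- cand[order(-depth, nchar(attr_rules$source[cand]),
                           attr_rules$source[cand], method = "radix")]
        rule_i <- cand[1]
      }
    }
    if (is.na(rule_i)) {
      unmapped[[length(unmapped) + 1L]] <- edge
      next
    }
    code <- serialize_value(edge$value)
    bindings <- rbind(bindings, data.frame(
      path = attr_rules$targetPath[rule_i], system = SNOMED_SYSTEM, code = code,
      display = if (is.character(edge$value)) concept_fsn(term, edge$value) else NA_character_,
      source = attr_rules$source[rule_i], stringsAsFactors = FALSE))
  }
  used_types <- unique(vapply(bindings$path, function(p) parse_fhirpath(p)$resource, character(1)))
  refs <- map$references
  refs_used <- refs[vapply(refs$fromPath, function(p) parse_fhirpath(p)$resource, character(1)) %in% used_types &
                      (refs$toResourceType %in% used_types | refs$toResourceType == "Patient"), , drop = FALSE]
  structure(list(bindings = bindings, unmapped = unmapped,
                 referencesUsed = refs_used,
                 profiles = map$profiles[names(map$profiles) %in% used_types]),
            class = "sct_mapping_result")
}

#' @export
print.sct_mapping_result <- function(x, ...) {
  print(x$bindings, row.names = FALSE)
  if (length(x$unmapped) > 0) {
    cat("unmapped delta edges:\n")
    for (p in x$unmapped) cat("  ", pair_key(p), "\n", sep = "")
  }
  invisible(x)
}

#' Coverage of SNOMED CT elements by a StructureMap bundle
#'
#' For every map, counts how many of its category's elements (the
#' Superconcept plus the category's attribute list) are mapped directly, how
#' many only via a standard extension, and how many not at all. Aggregates
#' are element-weighted (sums over all rows, not means of row percentages).
#'
#' @param maps List of `sct_structuremap`s.
#' @param elementCounts Named list: category id to character vector of
#'   elements (`"Superconcept"` plus attribute ids).
#' @return An `sct_coverage` with `rows` (per map) and `aggregates`
#'   (`directPct`, `withExtensionPct`, `minDirectPct`, `maxDirectPct`,
#'   `minWithExtensionPct`, `maxWithExtensionPct`).
#' @export
coverage_report <- function(maps, elementCounts) {
  rows <- do.call(rbind, lapply(maps, function(m) {
    elements <- elementCounts[[m$categoryId]]
    if (is.null(elements)) {
      sct_error("sctfhir_schema_error", sprintf(
        "no element list for category %s", m$categoryId))
    }
    known <- m$rules$source %in% elements
    if (!all(known)) {
      sct_error("sctfhir_schema_error", sprintf(
        "map %s--%s maps element(s) outside its category list: %s",
        m$categoryId, m$profileSetId,
        paste(m$rules$source[!known], collapse = ", ")))
    }
    mappable <- sum(!m$rules$viaExtension)
    via_ext <- sum(m$rules$viaExtension)
    total <- length(elements)
    if (mappable > total) {
      sct_error("sctfhir_schema_error", sprintf(
        "map %s--%s declares more mappable elements than the category has",
        m$categoryId, m$profileSetId))
    }
    data.frame(category = m$categoryId, profileSet = m$profileSetId,
               totalElements = total, mappable = mappable,
               unmappable = total - mappable, viaExtension = via_ext,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  direct <- 100 * sum(rows$mappable) / sum(rows$totalElements)
  with_ext <- 100 * sum(rows$mappable + rows$viaExtension) / sum(rows$totalElements)
  row_direct <- 100 * rows$mappable / rows$totalElements
  row_with_ext <- 100 * (rows$mappable + rows$viaExtension) / rows$totalElements
  structure(list(rows = rows, aggregates = list(
    directPct = direct, withExtensionPct = with_ext,
    minDirectPct = min(row_direct), maxDirectPct = max(row_direct),
    minWithExtensionPct = min(row_with_ext), maxWithExtensionPct = max(row_with_ext))),
    class = "sct_coverage")
}

#' @export
print.sct_coverage <- function(x, ...) {
  print(x$rows, row.names = FALSE)
  a <- x$aggregates
  cat(sprintf("direct coverage: %.1f%% (rows %.0f%%-%.0f%%)\n",
              a$directPct, a$minDirectPct, a$maxDirectPct))
  cat(sprintf("with extensions: %.1f%% (rows %.0f%%-%.0f%%)\n",
              a$withExtensionPct, a$minWithExtensionPct, a$maxWithExtensionPct))
  invisible(x)
}
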