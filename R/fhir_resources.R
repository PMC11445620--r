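# Emission of FHIR R4 resource JSON from a mapping result, and the reverse
# extraction of SNOMED codings.
#
# Element dialect: every mapped element holds an array. A path ending in a
# "coding" segment (optionally sliced, e.g. coding:snomed) appends Coding
# objects to that array; an extension(<url>) step appends an extension
# entry whose valueCodeableConcept carries the Coding; any other final
# element holds an array of CodeableConcepts. Intermediate segments are
# created as single objects. Extraction mirrors this and additionally
# traverses arrays wherever they occur, filtering codings to the SNOMED
# system.

as_node_list <- function(v) {
  if (is.null(v)) list()
  else if (is.list(v) && is.null(names(v))) v
  else list(v)
}

fhir_set_binding <- function(res, steps, coding) {
  if (length(steps) == 1) {
    step <- steps[[1]]
    if (identical(step$name, "extension")) {
      res$extension <- c(as_node_list(res$extension),
                         list(list(url = step$url,
                                   valueCodeableConcept = list(coding = list(coding)))))
    } else if (identical(step$name, "coding")) {
      res$coding <- c(as_node_list(res$coding), list(coding))
    } else {
      res[[step$name]] <- c(as_node_list(res[[step$name]]),
                            list(list(coding = list(coding))))
    }
    return(res)
  }
  step <- steps[[1]]
  if (identical(step$name, "extension")) {
    sct_error("sctfhir_emission_error",
              "extension steps are only supported as the final path segment")
  }
  child <- res[[step$name]]
  if (is.null(child)) child <- list()
  if (is.list(child) && is.null(names(child)) && length(child) > 0) {
    # existing array: descend into its first entry
    child[[1]] <- fhir_set_binding(child[[1]], steps[-1], coding)
    res[[step$name]] <- child
  } else {
    res[[step$name]] <- fhir_set_binding(child, steps[-1], coding)
  }
  res
}

fhir_set_reference <- function(res, steps, reference) {
  if (length(steps) == 1) {
    res[[steps[[1]]$name]] <- list(reference = reference)
    return(res)
  }
  step <- steps[[1]]
  child <- res[[step$name]]
  if (is.null(child)) child <- list()
  res[[step$name]] <- fhir_set_reference(child, steps[-1], reference)
  res
}

#' Emit FHIR R4 resources from a mapping result
#'
#' Builds one resource document per distinct resource type named in the
#' bindings, writing each binding's code as a SNOMED Coding at its FHIRPath
#' (intermediate elements are created on demand). References declared in the
#' governing StructureMap are materialised between the emitted resources
#' (and to the patient stub), profile names are recorded in `meta.profile`,
#' and the original expression, when supplied, is kept in `meta.tag` as a
#' safeguard against lossy mappings.
#'
#' @param result An `sct_mapping_result` from [apply_mapping()].
#' @param context List of prefill stubs: `patientRef` (default
#'   `"Patient/example"`), optional `originalExpression` (an
#'   `sct_expression` or string), optional `mapKey` recorded alongside it.
#' @return Named list of resource documents (lists ready for
#'   [jsonlite::toJSON()]), keyed by resource type.
#' @export
emit_resources <- function(result, context = list()) {
  stopifnot(inherits(result, "sct_mapping_result"))
  if (nrow(result$bindings) == 0) {
    sct_error("sctfhir_emission_error",
              "mapping result has no bindings; the Superconcept rule always yields one")
  }
  patient_ref <- context$patientRef %||% "Patient/example"
  types <- sort(unique(vapply(result$bindings$path, function(p) parse_fhirpath(p)$resource,
                              character(1))))
  resources <- stats::setNames(lapply(types, function(type) {
    res <- list(resourceType = type, id = paste0(tolower(type), "-1"))
    meta <- list()
    if (type %in% names(result$profiles)) meta$profile <- list(unname(result$profiles[[type]]))
    tags <- list()
    if (!is.null(context$originalExpression)) {
      orig <- context$originalExpression
      if (inherits(orig, "sct_expression")) orig <- serialize_expression(orig)
      tags <- c(tags, list(list(system = "urn:sctfhir:expression", code = orig)))
    }
    if (!is.null(context$mapKey)) {
      tags <- c(tags, list(list(system = "urn:sctfhir:structuremap", code = context$mapKey)))
    }
    if (length(tags) > 0) meta$tag <- tags
    if (length(meta) > 0) res$meta <- meta
    subject_el <- if (type == "AllergyIntolerance") "patient" else "subject"
    res[[subject_el]] <- list(reference = patient_ref)
    res
  }), types)

  for (i in seq_len(nrow(result$bindings))) {
    b <- result$bindings[i, ]
    parsed <- parse_fhirpath(b$path)
    coding <- list(system = b$system, code = b$code)
    if (!is.na(b$display)) coding$display <- b$display
    resources[[parsed$resource]] <-
      fhir_set_binding(resources[[parsed$resource]], parsed$steps, coding)
  }

  refs <- result$referencesUsed
  for (i in seq_len(nrow(refs))) {
    parsed <- parse_fhirpath(refs$fromPath[i])
    if (!parsed$resource %in% names(resources)) next
    target <- refs$toResourceType[i]
    reference <- if (target == "Patient") patient_ref
                 else if (target %in% names(resources)) paste0(target, "/", resources[[target]]$id)
                 else next
    resources[[parsed$resource]] <-
      fhir_set_reference(resources[[parsed$resource]], parsed$steps, reference)
  }
  resources
}

fhir_collect <- function(nodes, steps) {
  if (length(steps) == 0) return(nodes)
  step <- steps[[1]]
  out <- list()
  for (node in nodes) {
    if (!is.list(node)) next
    if (identical(step$name, "extension")) {
      for (ext in as_node_list(node$extension)) {
        if (identical(ext$url, step$url)) {
          out <- c(out, list(ext$valueCodeableConcept))
        }
      }
    } else {
      out <- c(out, as_node_list(node[[step$name]]))
    }
  }
  fhir_collect(out, steps[-1])
}

# All SNOMED codings reachable at a path inside one resource document.
fhir_codings_at <- function(res, parsed) {
  if (!identical(res$resourceType, parsed$resource)) return(list())
  last <- parsed$steps[[length(parsed$steps)]]
  nodes <- fhir_collect(list(res), parsed$steps)
  codings <- list()
  for (node in nodes) {
    if (!is.list(node)) next
    if (identical(last$name, "coding") && !is.null(node$code)) {
      codings <- c(codings, list(node))        # node is already a Coding
    } else {
      codings <- c(codings, as_node_list(node$coding))
    }
  }
  Filter(function(cd) identical(cd$system, SNOMED_SYSTEM) && !is.null(cd$code), codings)
}

#' Extract SNOMED bindings from FHIR resources
#'
#' Reads every SNOMED Coding found at any rule's target path in the given
#' resources; codings from other code systems are ignored. Duplicate
#' (path, code) hits from rules that share a path are collapsed.
#'
#' @param resources List of resource documents (parsed JSON lists, as
#'   emitted by [emit_resources()] or conforming to the same paths).
#' @param map The governing `sct_structuremap`.
#' @return Data frame of bindings: `path`, `system`, `code`, `display`.
#' @export
extract_bindings <- function(resources, map) {
  if (!is.null(resources$resourceType)) resources <- list(resources)
  rows <- list()
  for (path in unique(map$rules$targetPath)) {
    parsed <- parse_fhirpath(path)
    for (res in resources) {
      for (cd in fhir_codings_at(res, parsed)) {
        rows[[length(rows) + 1L]] <- data.frame(
          path = path, system = SNOMED_SYSTEM, code = cd$code,
          display = cd$display %||% NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(path = character(0), system = character(0),
               code = character(0), display = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  out[!duplicated(out[, c("path", "code")]), , drop = FALSE]
}

#' Write emitted resources to JSON files
#'
#' @param resources Named list from [emit_resources()].
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths.
#' @export
write_resources <- function(resources, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(names(resources), function(type) {
    path <- file.path(dir, paste0(tolower(type), ".json"))
    jsonlite::write_json(resources[[type]], path, auto_unbox = TRUE, pretty = TRUE)
    path
  }, character(1))
}
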