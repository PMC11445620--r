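# End-to-end orchestration: configuration, the decompose / recompose /
# coverage commands, and JSON report output. The thin command-line wrapper
# in inst/cli/sctfhir delegates to these functions.

#' Assemble and check a pipeline configuration
#'
#' @param terminologyDir Directory of RF2-dialect files.
#' @param mrcmPath MRCM rule table (YAML or TSV).
#' @param categoriesPath Category configuration (YAML).
#' @param mapsDir Directory of StructureMap JSON documents (with an optional
#'   `elements.yaml` holding per-category element lists for coverage).
#' @param profileSet Profile-set token selecting among each category's maps
#'   (e.g. `"nashp-like"` or `"mii-like"`).
#' @param namespace IRI namespace for OWL export.
#' @param outputFormat `"json"` or `"text"` report rendering.
#' @param isa_id Is-a marker concept id of the terminology dialect.
#' @return An `sct_pipeline_config`.
#' @export
pipeline_config <- function(terminologyDir, mrcmPath, categoriesPath, mapsDir,
                            profileSet = "nashp-like",
                            namespace = DEFAULT_NAMESPACE,
                            outputFormat = c("json", "text"),
                            isa_id = "116680003") {
  outputFormat <- match.arg(outputFormat)
  for (p in c(terminologyDir, mapsDir)) {
    if (!dir.exists(p)) sct_error("sctfhir_config_error", sprintf("directory not found: %s", p))
  }
  for (p in c(mrcmPath, categoriesPath)) {
    if (!file.exists(p)) sct_error("sctfhir_config_error", sprintf("file not found: %s", p))
  }
  structure(list(terminologyDir = terminologyDir, mrcmPath = mrcmPath,
                 categoriesPath = categoriesPath, mapsDir = mapsDir,
                 profileSet = profileSet, namespace = namespace,
                 outputFormat = outputFormat, isa_id = isa_id),
            class = "sct_pipeline_config")
}

#' Load every artefact a pipeline configuration points to
#'
#' @param cfg An `sct_pipeline_config`.
#' @return List with `term`, `mrcm`, `categories`, `maps`, `elements`.
#' @export
load_pipeline <- function(cfg) {
  term <- load_rf2(cfg$terminologyDir, isa_id = cfg$isa_id)
  elements_path <- file.path(cfg$mapsDir, "elements.yaml")
  list(term = term,
       mrcm = load_mrcm(cfg$mrcmPath),
       categories = load_categories(cfg$categoriesPath, term = term),
       maps = load_structuremap_bundle(cfg$mapsDir),
       elements = if (file.exists(elements_path)) {
         lapply(yaml::read_yaml(elements_path), as.character)
       })
}

select_map <- function(maps, category_id, profile_set) {
  key <- paste0(category_id, "--", profile_set)
  map <- maps[[key]]
  if (is.null(map)) {
    sct_error("sctfhir_schema_error", sprintf("no StructureMap named %s in the bundle", key))
  }
  map
}

#' Decompose a postcoordinated expression into FHIR resource elements
#'
#' Runs the full forward pipeline: syntactic and semantic validation,
#' Superconcept candidate classification, similarity scoring and
#' Superconcept choice, Delta computation, category assignment, StructureMap
#' application, and resource emission. A syntactically or semantically
#' invalid expression yields a report containing only the failed validation;
#' later-stage failures raise classed conditions carrying a `stage` field.
#'
#' @param expr Expression text (Compositional Grammar) or an
#'   `sct_expression`.
#' @param cfg An `sct_pipeline_config`, or a pre-loaded pipeline from
#'   [load_pipeline()] / [build_allergy_mini()].
#' @return An `sct_report` with the fields of each completed stage.
#' @export
cmd_decompose <- function(expr, cfg) {
  pl <- as_pipeline(cfg)
  report <- structure(list(inputExpression = if (is.character(expr)) expr
                                             else serialize_expression(expr)),
                      class = "sct_report")
  e <- tryCatch(
    if (is.character(expr)) parse_expression(expr) else expr,
    sctfhir_syntax_error = function(cnd) {
      report$validation <<- new_validation_report(
        validation_issue("error", "syntax", conditionMessage(cnd)))
      NULL
    })
  if (is.null(e)) return(report)
  report$inputExpression <- serialize_expression(e)

  report$validation <- validate_semantics(pl$term, pl$mrcm, e)
  if (!report$validation$ok) return(report)

  stage <- function(name, code) {
    withCallingHandlers(code, sctfhir_error = function(cnd) {
      cnd$stage <- name
      stop(cnd)
    })
  }
  report$candidates <- stage("classification", superconcept_candidates(pl$term, e))
  report$scores <- stage("superconcept", score_candidates(pl$term, e, report$candidates))
  superconcept <- report$scores$chosen
  report$delta <- stage("delta", compute_delta(pl$term, e, superconcept))
  report$category <- stage("category",
                           assign_category(pl$term, e, pl$categories, superconcept))
  map <- stage("mapping", select_map(pl$maps, report$category$id, pl$profileSet))
  report$mapping <- stage("mapping", apply_mapping(map, superconcept, report$delta, pl$term))
  report$resources <- stage("emission", emit_resources(report$mapping, context = list(
    originalExpression = e,
    mapKey = paste0(map$categoryId, "--", map$profileSetId))))
  report
}

as_pipeline <- function(cfg) {
  if (inherits(cfg, "sct_pipeline_config")) {
    pl <- load_pipeline(cfg)
    pl$profileSet <- cfg$profileSet
    pl
  } else {
    if (is.null(cfg$profileSet)) cfg$profileSet <- "nashp-like"
    if (is.null(cfg$term) && !is.null(cfg$terminology)) cfg$term <- cfg$terminology
    cfg
  }
}

#' Recompose an expression from stored FHIR resources
#'
#' Extracts SNOMED codings along the governing StructureMap's paths,
#' determines the attribute behind each path, and rebuilds the expression
#' with the Superconcept as focus concept. When the original expression is
#' supplied, the subsumption relationship between original and recomposed
#' expression is reported.
#'
#' @param resources Resource JSON file paths, or a list of parsed resource
#'   documents.
#' @param cfg Configuration or pre-loaded pipeline (see [cmd_decompose()]).
#' @param original Optional original expression (text or `sct_expression`).
#' @param map Optional `sct_structuremap`; by default it is recovered from
#'   the `urn:sctfhir:structuremap` meta tag the emitter writes.
#' @return List with `expression`, serialized `text`, and `comparison` (one
#'   of `"equivalent"`, `"original-subsumes-recomposed"`,
#'   `"recomposed-subsumes-original"`, `"incomparable"`, or `NA` when no
#'   original was given).
#' @export
cmd_recompose <- function(resources, cfg, original = NULL, map = NULL) {
  pl <- as_pipeline(cfg)
  if (is.character(resources)) {
    resources <- lapply(resources, jsonlite::read_json, simplifyVector = FALSE)
  }
  if (!is.null(resources$resourceType)) resources <- list(resources)
  if (is.null(map)) {
    for (res in resources) {
      for (tag in as_node_list(res$meta$tag)) {
        if (identical(tag$system, "urn:sctfhir:structuremap")) {
          map <- pl$maps[[tag$code]]
        }
      }
    }
    if (is.null(map)) {
      sct_error("sctfhir_reverse_error",
                "cannot determine the governing StructureMap (no structuremap meta tag)")
    }
  }
  bindings <- extract_bindings(resources, map)
  recomposed <- recompose(bindings, map, pl$term, pl$mrcm)
  comparison <- NA_character_
  if (!is.null(original)) {
    if (is.character(original)) original <- parse_expression(original)
    comparison <- switch(expr_subsumption(pl$term, original, recomposed),
      "equivalent" = "equivalent",
      "e1-subsumes-e2" = "original-subsumes-recomposed",
      "e2-subsumes-e1" = "recomposed-subsumes-original",
      "incomparable" = "incomparable")
  }
  list(expression = recomposed, text = serialize_expression(recomposed),
       comparison = comparison)
}

#' Coverage statistics of the configured StructureMap bundle
#'
#' @param cfg Configuration or pre-loaded pipeline; the bundle must come
#'   with per-category element lists.
#' @return An `sct_coverage`.
#' @export
cmd_coverage <- function(cfg) {
  pl <- as_pipeline(cfg)
  if (is.null(pl$elements)) {
    sct_error("sctfhir_schema_error",
              "no element lists (elements.yaml) available for coverage accounting")
  }
  coverage_report(pl$maps, pl$elements)
}

#' Serialize a decomposition report
#'
#' @param report An `sct_report` from [cmd_decompose()].
#' @param format `"json"` (default) or `"text"`.
#' @return A string (JSON document or human-readable rendering).
#' @export
render_report <- function(report, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "text") {
    lines <- c(sprintf("expression: %s", report$inputExpression))
    if (!is.null(report$validation)) {
      lines <- c(lines, sprintf("validation: %s",
                                if (report$validation$ok) "ok" else "failed"))
      if (nrow(report$validation$issues) > 0) {
        lines <- c(lines, paste0("  - ", report$validation$issues$message))
      }
    }
    if (!is.null(report$candidates)) {
      lines <- c(lines, sprintf("candidates: %s",
                                paste(report$candidates$candidates, collapse = ", ")))
    }
    if (!is.null(report$scores)) {
      s <- report$scores$scores
      lines <- c(lines, sprintf("superconcept: %s", report$scores$chosen),
                 sprintf("  %s: nonshared %d, union %d, similarity %.2f",
                         s$candidateId, s$nonshared, s$union, s$value))
    }
    if (!is.null(report$delta)) {
      lines <- c(lines, sprintf("delta: %s",
        if (length(report$delta$edges) == 0) "(empty)"
        else paste(vapply(report$delta$edges, pair_key, character(1)), collapse = ", ")))
    }
    if (!is.null(report$category)) {
      lines <- c(lines, sprintf("category: %s", report$category$id))
    }
    if (!is.null(report$mapping)) {
      b <- report$mapping$bindings
      lines <- c(lines, "bindings:",
                 sprintf("  %s <- %s (%s)", b$path, b$code, b$source))
      if (length(report$mapping$unmapped) > 0) {
        lines <- c(lines, "unmapped:",
                   paste0("  ", vapply(report$mapping$unmapped, pair_key, character(1))))
      }
    }
    return(paste(lines, collapse = "\n"))
  }
  out <- list(inputExpression = report$inputExpression)
  if (!is.null(report$validation)) {
    out$validation <- list(ok = report$validation$ok, issues = report$validation$issues)
  }
  if (!is.null(report$candidates)) {
    out$candidates <- list(candidates = report$candidates$candidates,
                           equivalentTo = report$candidates$equivalentTo)
  }
  if (!is.null(report$scores)) {
    scores <- report$scores$scores
    scores$value <- round(scores$value, 2)
    out$superconcept <- list(chosen = report$scores$chosen,
                             tieBreakUsed = report$scores$tieBreakUsed,
                             scores = scores)
  }
  if (!is.null(report$delta)) {
    out$delta <- vapply(report$delta$edges, pair_key, character(1))
  }
  if (!is.null(report$category)) out$category <- report$category$id
  if (!is.null(report$mapping)) {
    out$mapping <- list(bindings = report$mapping$bindings,
                        unmapped = vapply(report$mapping$unmapped, pair_key, character(1)))
  }
  if (!is.null(report$resources)) out$resources <- report$resources
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, na = "null"))
}

#' @export
print.sct_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
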