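# Concept-model (MRCM-lite) rules and semantic validation of expressions.

#' Construct a concept-model rule
#'
#' @param attributeId Attribute concept id the rule governs.
#' @param domainConstraint ECL-lite constraint the focus concepts must
#'   satisfy for the attribute to be applicable.
#' @param rangeConstraint ECL-lite constraint admissible values must satisfy.
#' @param maxPerGroup Maximum occurrences of the attribute inside one role
#'   group (or the ungrouped refinement); `Inf` for unbounded.
#' @param groupedAllowed May the attribute appear inside a role group?
#' @return An `sct_mrcm_rule`.
#' @export
mrcm_rule <- function(attributeId, domainConstraint, rangeConstraint,
                      maxPerGroup = 1, groupedAllowed = TRUE) {
  ecl_check(domainConstraint)
  ecl_check(rangeConstraint)
  if (!(is.numeric(maxPerGroup) && (is.infinite(maxPerGroup) || maxPerGroup >= 1))) {
    sct_error("sctfhir_argument_error", "maxPerGroup must be a positive count or Inf")
  }
  structure(list(attributeId = as.character(attributeId),
                 domainConstraint = domainConstraint,
                 rangeConstraint = rangeConstraint,
                 maxPerGroup = maxPerGroup,
                 groupedAllowed = isTRUE(groupedAllowed)),
            class = "sct_mrcm_rule")
}

#' Load concept-model rules from a YAML or TSV table
#'
#' One row/entry per attribute with fields `attributeId`,
#' `domainConstraint`, `rangeConstraint`, `maxPerGroup` (a count,
#' `"unbounded"` or `"*"`), `groupedAllowed`.
#'
#' @param path File path (`.yaml`/`.yml` or tab-separated text).
#' @return Named list of `sct_mrcm_rule`s keyed by attribute id.
#' @export
load_mrcm <- function(path) {
  if (!file.exists(path)) {
    sct_error("sctfhir_load_error", sprintf("MRCM rule table not found: %s", path))
  }
  if (grepl("\\.ya?ml$", path)) {
    entries <- yaml::read_yaml(path)
  } else {
    tab <- utils::read.delim(path, colClasses = "character", quote = "")
    entries <- lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ]))
  }
  rules <- lapply(entries, function(row) {
    mx <- row$maxPerGroup
    mx <- if (is.null(mx) || mx %in% c("unbounded", "*")) Inf else as.numeric(mx)
    mrcm_rule(row$attributeId, row$domainConstraint, row$rangeConstraint,
              maxPerGroup = mx,
              groupedAllowed = as_flag(row$groupedAllowed %||% TRUE))
  })
  stats::setNames(rules, vapply(rules, function(r) r$attributeId, character(1)))
}

validation_issue <- function(severity, code, message, element = NA_character_) {
  data.frame(severity = severity, code = code, message = message,
             element = element, stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(severity = character(0), code = character(0),
             message = character(0), element = character(0),
             stringsAsFactors = FALSE)
}

new_validation_report <- function(issues) {
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "sct_validation_report")
}

#' @export
print.sct_validation_report <- function(x, ...) {
  cat(sprintf("<sct_validation_report> ok = %s\n", x$ok))
  if (nrow(x$issues) > 0) print(x$issues, row.names = FALSE)
  invisible(x)
}

#' Validate an expression against the concept model
#'
#' Reports (as issues, never errors) unknown or inactive concept ids,
#' attributes without a concept-model rule, focus-concept sets outside an
#' attribute's domain constraint, values outside the range constraint,
#' cardinality violations (more occurrences of an attribute in one scope
#' than `maxPerGroup` allows), and grouped use of attributes whose rule
#' forbids grouping. Nested expression values are validated recursively.
#'
#' @param term An `sct_terminology`.
#' @param rules Named list of `sct_mrcm_rule`s (see [load_mrcm()]).
#' @param e A parsed `sct_expression`.
#' @return An `sct_validation_report`; `ok` is `TRUE` iff no issue has
#'   severity `"error"`.
#' @export
validate_semantics <- function(term, rules, e) {
  issues <- no_issues()
  add <- function(...) issues <<- rbind(issues, validation_issue(...))

  known <- function(id) {
    if (!has_concept(term, id)) {
      inactive <- id %in% term$inactive$concepts$id
      add("error", if (inactive) "inactive-concept" else "unknown-concept",
          sprintf("concept %s is %s in the terminology", id,
                  if (inactive) "inactive" else "unknown"), id)
      return(FALSE)
    }
    TRUE
  }

  focus_known <- vapply(e$focus, known, logical(1))
  focus <- e$focus[focus_known]

  check_pairs <- function(pairs, grouped, scope_label) {
    attrs <- vapply(pairs, function(p) p$attribute, character(1))
    for (a in unique(attrs)) {
      rule <- rules[[a]]
      if (!known(a)) next
      if (is.null(rule)) {
        add("error", "no-mrcm-rule",
            sprintf("attribute %s has no concept-model rule", a), a)
        next
      }
      if (grouped && !rule$groupedAllowed) {
        add("error", "grouping",
            sprintf("attribute %s may not be used inside a role group", a), a)
      }
      if (sum(attrs == a) > rule$maxPerGroup) {
        add("error", "cardinality",
            sprintf("attribute %s occurs %d times in %s, violating cardinality restrictions of the concept model (max %s)",
                    a, sum(attrs == a), scope_label, format(rule$maxPerGroup)), a)
      }
      if (length(focus) > 0 &&
          !any(vapply(focus, function(f) eval_ecl_lite(term, rule$domainConstraint, f), logical(1)))) {
        add("error", "domain-constraint",
            sprintf("focus concepts are outside the domain constraint %s of attribute %s",
                    dQuote(rule$domainConstraint, q = FALSE), a), a)
      }
    }
    for (p in pairs) {
      rule <- rules[[p$attribute]]
      if (is.null(rule)) next
      if (is.character(p$value)) {
        if (!known(p$value)) next
        if (!eval_ecl_lite(term, rule$rangeConstraint, p$value)) {
          add("error", "range-constraint",
              sprintf("value %s is outside the range constraint %s of attribute %s",
                      p$value, dQuote(rule$rangeConstraint, q = FALSE), p$attribute),
              p$value)
        }
      } else {
        nested <- validate_semantics(term, rules, p$value)
        issues <<- rbind(issues, nested$issues)
        nested_focus <- p$value$focus[vapply(p$value$focus, function(f) has_concept(term, f), logical(1))]
        if (length(nested_focus) > 0 &&
            !any(vapply(nested_focus, function(f) eval_ecl_lite(term, rule$rangeConstraint, f), logical(1)))) {
          add("error", "range-constraint",
              sprintf("nested expression value is outside the range constraint %s of attribute %s",
                      dQuote(rule$rangeConstraint, q = FALSE), p$attribute),
              serialize_expression(p$value))
        }
      }
    }
  }

  check_pairs(e$ungrouped, grouped = FALSE, scope_label = "the ungrouped refinement")
  for (i in seq_along(e$groups)) {
    check_pairs(e$groups[[i]], grouped = TRUE, scope_label = sprintf("role group %d", i))
  }
  new_validation_report(issues)
}
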