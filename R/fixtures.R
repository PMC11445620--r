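# Synthetic fixture generation: randomized mini-terminologies with
# concept-model rules and category configs, plus random PCE corpora. Every
# stage of the pipeline is testable without licensed terminology content.

#' Describe a synthetic terminology fixture
#'
#' @param seed Integer seed; equal specs produce byte-identical output.
#' @param conceptCount Number of content concepts (on top of the skeleton of
#'   root, attribute/value subtrees and category roots).
#' @param maxParents Maximum is-a parents per content concept.
#' @param attributeCount Number of attribute concepts; with three or more,
#'   the first three form a three-level chain (the shape of the
#'   device-attribute hierarchy used by the reverse-mapping case
#'   distinctions).
#' @param definedFraction Fraction of content concepts that are fully
#'   defined with attribute pairs.
#' @param groupProbability Probability that a defined concept's pairs are
#'   placed in a role group rather than ungrouped.
#' @param categoryLayout Named integer vector of per-category content
#'   subtree sizes; defaults to an even split over five categories.
#' @return An `sct_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, conceptCount = 60, maxParents = 2,
                         attributeCount = 4, definedFraction = 0.3,
                         groupProbability = 0.15, categoryLayout = NULL) {
  if (conceptCount > 1 && maxParents < 1) {
    sct_error("sctfhir_spec_error", "maxParents must be >= 1 when conceptCount > 1")
  }
  if (attributeCount < 1) {
    sct_error("sctfhir_spec_error", "attributeCount must be >= 1")
  }
  if (definedFraction < 0 || definedFraction > 1 ||
      groupProbability < 0 || groupProbability > 1) {
    sct_error("sctfhir_spec_error", "fractions must lie in [0, 1]")
  }
  if (is.null(categoryLayout)) {
    k <- 5L
    base <- conceptCount %/% k
    categoryLayout <- stats::setNames(rep(base, k), paste0("cat", seq_len(k)))
    categoryLayout[1] <- categoryLayout[1] + conceptCount - sum(categoryLayout)
  }
  structure(list(seed = as.integer(seed), conceptCount = as.integer(conceptCount),
                 maxParents = as.integer(maxParents),
                 attributeCount = as.integer(attributeCount),
                 definedFraction = definedFraction,
                 groupProbability = groupProbability,
                 categoryLayout = categoryLayout),
            class = "sct_fixture_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic mini-terminology
#'
#' Builds an acyclic polyhierarchy: a root, an attribute subtree (first
#' three attributes in a chain when present), one value subtree per
#' attribute, one disjoint content subtree per category, and randomly
#' parented content concepts, a fraction of which are fully defined with
#' attribute pairs (optionally role-grouped). A consistent MRCM table (one
#' rule per attribute, range bound to the attribute's value subtree) and
#' category config are produced alongside.
#'
#' @param spec An `sct_fixture_spec`.
#' @param out Optional directory; when given, RF2-dialect files,
#'   `mrcm.yaml` and `categories.yaml` are written there (byte-identical
#'   for equal specs).
#' @return List with `terminology`, `mrcm`, `categories`, `contentIds`,
#'   and `spec`.
#' @export
generate_terminology <- function(spec, out = NULL) {
  stopifnot(inherits(spec, "sct_fixture_spec"))
  with_seed(spec$seed, {
    root <- "900001"; attr_root <- "900002"
    rows <- list()
    add_concept <- function(id, fsn, status, parents, pairs = list(), group = FALSE) {
      rows[[length(rows) + 1L]] <<- list(id = id, fsn = fsn, status = status,
                                         parents = parents, pairs = pairs,
                                         group = group)
    }
    add_concept(root, "Synthetic root concept", "primitive", character(0))
    add_concept(attr_root, "Synthetic attribute (attribute)", "primitive", root)

    attrs <- sprintf("91%04d", seq_len(spec$attributeCount))
    for (i in seq_along(attrs)) {
      parent <- if (i %in% c(2L, 3L)) attrs[i - 1L] else attr_root
      add_concept(attrs[i], sprintf("Attribute %d (attribute)", i), "primitive", parent)
    }
    value_roots <- sprintf("92%04d", seq_len(spec$attributeCount))
    values <- list()
    for (i in seq_along(attrs)) {
      add_concept(value_roots[i], sprintf("Value root %d (qualifier value)", i),
                  "primitive", root)
      vs <- sprintf("93%04d", (i - 1L) * 3L + 1:3)
      add_concept(vs[1], sprintf("Value %d.1", i), "primitive", value_roots[i])
      add_concept(vs[2], sprintf("Value %d.2", i), "primitive", vs[1])
      add_concept(vs[3], sprintf("Value %d.3", i), "primitive", value_roots[i])
      values[[attrs[i]]] <- vs
    }

    layout <- spec$categoryLayout
    cat_roots <- sprintf("94%04d", seq_along(layout))
    for (i in seq_along(layout)) {
      add_concept(cat_roots[i], sprintf("Category root %d", i), "primitive", root)
    }

    content <- character(0)
    counter <- 0L
    for (i in seq_along(layout)) {
      members <- cat_roots[i]
      for (j in seq_len(layout[[i]])) {
        counter <- counter + 1L
        id <- sprintf("95%04d", counter)
        n_par <- sample.int(min(spec$maxParents, length(members)), 1L)
        parents <- sample(members, n_par)
        defined <- stats::runif(1) < spec$definedFraction
        pairs <- list()
        grouped <- FALSE
        if (defined) {
          n_pairs <- sample.int(min(2L, length(attrs)), 1L)
          use_attrs <- sample(attrs, n_pairs)
          pairs <- lapply(use_attrs, function(a) {
            attribute_pair(a, sample(values[[a]], 1L))
          })
          grouped <- stats::runif(1) < spec$groupProbability
        }
        add_concept(id, sprintf("Content concept %d", counter),
                    if (defined && length(pairs) > 0) "fullyDefined" else "primitive",
                    parents, pairs, grouped)
        members <- c(members, id)
        content <- c(content, id)
      }
    }

    concepts <- data.frame(
      id = vapply(rows, `[[`, character(1), "id"),
      effectiveTime = "20230430",
      active = "1",
      moduleId = "900000000000207008",
      definitionStatusId = vapply(rows, `[[`, character(1), "status"),
      stringsAsFactors = FALSE)
    rel <- list()
    add_rel <- function(src, dst, type, group) {
      rel[[length(rel) + 1L]] <<- data.frame(
        id = sprintf("%d", 7000000L + length(rel)), effectiveTime = "20230430",
        active = "1", moduleId = "900000000000207008",
        sourceId = src, destinationId = dst,
        relationshipGroup = as.character(group), typeId = type,
        stringsAsFactors = FALSE)
    }
    for (r in rows) {
      for (p in r$parents) add_rel(r$id, p, "116680003", 0L)
      for (k in seq_along(r$pairs)) {
        add_rel(r$id, r$pairs[[k]]$value, r$pairs[[k]]$attribute,
                if (r$group) 1L else 0L)
      }
    }
    relationships <- do.call(rbind, rel)
    descriptions <- data.frame(
      id = sprintf("%d", 8000000L + seq_len(nrow(concepts))),
      active = "1", conceptId = concepts$id,
      typeId = "900000000000003001",
      term = vapply(rows, `[[`, character(1), "fsn"),
      stringsAsFactors = FALSE)

    term <- terminology(concepts, relationships, descriptions, isa_id = "116680003")
    mrcm <- lapply(attrs, function(a) {
      mrcm_rule(a, paste0("<< ", root),
                paste0("<< ", value_roots[match(a, attrs)]),
                maxPerGroup = 1, groupedAllowed = TRUE)
    })
    names(mrcm) <- attrs
    categories <- lapply(seq_along(layout), function(i) {
      structure(list(id = names(layout)[i], name = names(layout)[i],
                     constraint = paste0("<< ", cat_roots[i]),
                     profileSets = "generic"), class = "sct_category")
    })

    if (!is.null(out)) {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_tsv <- function(df, name) {
        utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                           row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
      }
      write_tsv(concepts, "concepts.tsv")
      write_tsv(relationships, "relationships.tsv")
      write_tsv(descriptions, "descriptions.tsv")
      yaml::write_yaml(lapply(mrcm, function(r) list(
        attributeId = r$attributeId, domainConstraint = r$domainConstraint,
        rangeConstraint = r$rangeConstraint, maxPerGroup = r$maxPerGroup,
        groupedAllowed = r$groupedAllowed)), file.path(out, "mrcm.yaml"))
      yaml::write_yaml(lapply(categories, function(x) list(
        id = x$id, name = x$name, constraint = x$constraint,
        profileSets = as.list(x$profileSets))), file.path(out, "categories.yaml"))
    }
    list(terminology = term, mrcm = mrcm, categories = categories,
         contentIds = content, spec = spec)
  })
}

#' Generate a corpus of semantically valid random expressions
#'
#' Each expression refines a randomly chosen content concept with one or two
#' attribute pairs drawn from its MRCM-admissible attributes and their
#' admissible value ranges; every generated expression passes
#' [validate_semantics()].
#'
#' @param term An `sct_terminology`.
#' @param n Number of expressions.
#' @param seed Integer seed for reproducibility.
#' @param mrcm Named list of `sct_mrcm_rule`s governing the terminology.
#' @param focus_pool Optional candidate focus concepts; defaults to every
#'   active concept with at least one admissible attribute.
#' @param group_probability Probability of placing a generated refinement in
#'   a role group (default 0: ungrouped, the shape of clinically authored
#'   expressions the round-trip study condition assumes).
#' @return List of `sct_expression`s of length `n`.
#' @export
generate_pce_corpus <- function(term, n, seed, mrcm, focus_pool = NULL,
                                group_probability = 0) {
  with_seed(seed, {
    admissible <- function(f) {
      names(mrcm)[vapply(mrcm, function(r)
        eval_ecl_lite(term, r$domainConstraint, f), logical(1))]
    }
    range_values <- lapply(mrcm, function(r) {
      term$concepts$id[vapply(term$concepts$id, function(c)
        eval_ecl_lite(term, r$rangeConstraint, c), logical(1))]
    })
    pool <- focus_pool %||% setdiff(term$concepts$id, term$rootId)
    pool <- pool[vapply(pool, function(f) {
      a <- admissible(f)
      length(a) > 0 && any(vapply(range_values[a], length, integer(1)) > 0)
    }, logical(1))]
    if (length(pool) == 0) {
      sct_error("sctfhir_corpus_error", "no concept has an admissible attribute")
    }
    lapply(seq_len(n), function(i) {
      focus <- sample(pool, 1L)
      a <- admissible(focus)
      a <- a[vapply(range_values[a], length, integer(1)) > 0]
      use <- sample(a, min(sample.int(2L, 1L), length(a)))
      pairs <- lapply(use, function(at) attribute_pair(at, sample(range_values[[at]], 1L)))
      grouped <- stats::runif(1) < group_probability
      e <- if (grouped) expression_ast(focus, groups = list(pairs))
           else expression_ast(focus, ungrouped = pairs)
      canonical_expression(e)
    })
  })
}
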