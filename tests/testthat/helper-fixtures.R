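# Shared fixtures and independent oracles.

# The bundled fixture, built once per test run.
mini <- build_allergy_mini()
mini_pipeline <- list(term = mini$terminology, mrcm = mini$mrcm,
                      categories = mini$categories, maps = mini$maps,
                      elements = mini$elements, profileSet = "nashp-like")

concept_table <- function(ids, status = "primitive") {
  data.frame(id = ids, effectiveTime = "20230430", active = "1",
             moduleId = "m", definitionStatusId = status,
             stringsAsFactors = FALSE)
}

relationship_table <- function(source, destination, type = "116680003",
                               group = 0, active = "1") {
  n <- length(source)
  data.frame(id = as.character(seq_len(n)), effectiveTime = "20230430",
             active = active, moduleId = "m",
             sourceId = source, destinationId = destination,
             relationshipGroup = as.character(group), typeId = type,
             stringsAsFactors = FALSE)
}

# root <- A <- B linear chain
chain_term <- function() {
  terminology(concept_table(c("100001", "100002", "100003")),
              relationship_table(c("100002", "100003"), c("100001", "100002")))
}

# diamond: B below A1 and A2, both below root
diamond_term <- function() {
  terminology(concept_table(c("100001", "100011", "100012", "100013")),
              relationship_table(c("100011", "100012", "100013", "100013"),
                                 c("100001", "100001", "100011", "100012")))
}

# Independent ancestor oracle: reachability over the is-a edges via igraph.
igraph_ancestors <- function(term, c) {
  edges <- do.call(rbind, lapply(names(term$parents), function(ch) {
    if (length(term$parents[[ch]]) == 0) return(NULL)
    data.frame(from = ch, to = term$parents[[ch]], stringsAsFactors = FALSE)
  }))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = term$concepts$id))
  sort(names(igraph::subcomponent(g, c, mode = "out")))
}

# Brute-force Superconcept-candidate oracle: enumerate every concept through
# the subsumption test, then keep the minimal elements using igraph
# reachability for the descendant check.
oracle_candidates <- function(term, e) {
  ne <- normalize_expression(term, e)
  S <- term$concepts$id[vapply(term$concepts$id, function(c)
    expr_subsumed_by(term, ne, c), logical(1))]
  keep <- vapply(S, function(c) {
    !any(vapply(setdiff(S, c), function(s) c %in% setdiff(igraph_ancestors(term, s), s),
                logical(1)))
  }, logical(1))
  sort(S[keep])
}

expect_expression_equal <- function(a, b) {
  expect_identical(serialize_expression(a), serialize_expression(b))
}
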