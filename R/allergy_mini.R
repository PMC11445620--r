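# The bundled "allergy-mini" fixture: a synthetic polyhierarchy shaped like
# the allergy/procedure corner of a clinical terminology, with concept-model
# rules, five pairwise-disjoint content categories, and the bundle of
# 10 StructureMaps (5 categories x 2 profile sets). Non-attribute concept
# ids are synthetic six-digit numbers; the attribute concepts carry the real
# SNOMED CT attribute ids so the shipped mapping rule tables read naturally.

# id | fsn | definitionStatus | parents (space-sep) | definition pairs
# ("attr=value" space-sep, all ungrouped)
ALLERGY_MINI_CONCEPTS <- c(
  "100001|SNOMED CT concept (synthetic root)|primitive||",
  "100002|Clinical finding (finding)|primitive|100001|",
  "100003|Procedure (procedure)|primitive|100001|",
  "100004|Body structure (body structure)|primitive|100001|",
  "100005|Substance (substance)|primitive|100001|",
  "100006|Morphologic abnormality (morphologic abnormality)|primitive|100004|",
  "100007|Attribute (attribute)|primitive|100001|",
  "100008|Device (physical object)|primitive|100001|",
  "100009|Qualifier value (qualifier value)|primitive|100001|",
  "100010|Action (qualifier value)|primitive|100009|",
  # attributes (real SNOMED CT attribute ids)
  "246075003|Causative agent (attribute)|primitive|100007|",
  "363698007|Finding site (attribute)|primitive|100007|",
  "116676008|Associated morphology (attribute)|primitive|100007|",
  "370135005|Pathological process (attribute)|primitive|100007|",
  "263502005|Clinical course (attribute)|primitive|100007|",
  "719722006|Has realization (attribute)|primitive|100007|",
  "246454002|Occurrence (attribute)|primitive|100007|",
  "42752001|Due to (attribute)|primitive|100007|",
  "260686004|Method (attribute)|primitive|100007|",
  "363704007|Procedure site (attribute)|primitive|100007|",
  "405813007|Procedure site - Direct (attribute)|primitive|363704007|",
  "405814001|Procedure site - Indirect (attribute)|primitive|363704007|",
  "363701004|Direct substance (attribute)|primitive|100007|",
  "363700003|Direct morphology (attribute)|primitive|100007|",
  "424361007|Using substance (attribute)|primitive|100007|",
  "405815000|Procedure device (attribute)|primitive|100007|",
  "424226004|Using device (attribute)|primitive|405815000|",
  "425391005|Using access device (attribute)|primitive|424226004|",
  "363703001|Has intent (attribute)|primitive|100007|",
  "260507000|Access (attribute)|primitive|100007|",
  "424876005|Surgical approach (attribute)|primitive|100007|",
  "363702006|Has focus (attribute)|primitive|100007|",
  # substances
  "300001|Nut substance (substance)|primitive|100005|",
  "300002|Tree nut substance (substance)|primitive|300001|",
  "300003|Drug substance (substance)|primitive|100005|",
  "300004|Contrast medium (substance)|primitive|100005|",
  # body structures
  "310001|Skin structure (body structure)|primitive|100004|",
  "310002|Lip structure (body structure)|primitive|310001|",
  "310003|Vascular structure (body structure)|primitive|100004|",
  # morphologies
  "320001|Swelling morphology (morphologic abnormality)|primitive|100006|",
  "320002|Inflammation morphology (morphologic abnormality)|primitive|100006|",
  "320003|Fracture morphology (morphologic abnormality)|primitive|100006|",
  # devices
  "330002|Access device (physical object)|primitive|100008|",
  "330001|Catheter device (physical object)|primitive|330002|",
  "330003|Imaging scanner (physical object)|primitive|100008|",
  # qualifier values
  "340003|Course qualifier (qualifier value)|primitive|100009|",
  "340001|Acute course (qualifier value)|primitive|340003|",
  "340002|Chronic course (qualifier value)|primitive|340003|",
  "360001|Process qualifier (qualifier value)|primitive|100009|",
  "360002|Allergic process (qualifier value)|primitive|360001|",
  "360003|Autoimmune process (qualifier value)|primitive|360001|",
  "370001|Life period qualifier (qualifier value)|primitive|100009|",
  "370002|Childhood period (qualifier value)|primitive|370001|",
  "380001|Intent qualifier (qualifier value)|primitive|100009|",
  "380002|Diagnostic intent (qualifier value)|primitive|380001|",
  "390001|Access qualifier (qualifier value)|primitive|100009|",
  "390002|Percutaneous access (qualifier value)|primitive|390001|",
  "395001|Approach qualifier (qualifier value)|primitive|100009|",
  "395002|Lateral approach (qualifier value)|primitive|395001|",
  # actions
  "350001|Excision action (qualifier value)|primitive|100010|",
  "350002|Imaging action (qualifier value)|primitive|100010|",
  "350003|Insertion action (qualifier value)|primitive|100010|",
  # findings: three category subtree roots plus general findings
  "400001|Allergic reaction (finding)|primitive|100002|",
  "400010|Allergy to substance (finding)|primitive|100002|",
  "400020|Allergic disease (finding)|primitive|100002|",
  "400002|Swelling (finding)|fullyDefined|100002|116676008=320001",
  "400004|Allergic reaction caused by nut (finding)|fullyDefined|400001|246075003=300001",
  "400003|Allergic reaction caused by tree nut (finding)|fullyDefined|400004|246075003=300002",
  "400005|Swelling of skin (finding)|fullyDefined|400002|116676008=320001 363698007=310001",
  "400006|Allergic reaction caused by drug (finding)|fullyDefined|400001|246075003=300003",
  "400007|Fracture finding (finding)|fullyDefined|100002|116676008=320003",
  "400011|Allergy to nut (finding)|fullyDefined|400010|246075003=300001",
  "400021|Allergic inflammatory disease (finding)|fullyDefined|400020|370135005=360002 116676008=320002",
  "400022|Autoimmune disease (finding)|fullyDefined|400020|370135005=360003",
  # procedures
  "500001|Allergy testing procedure (procedure)|primitive|100003|",
  "500002|Catheterization procedure (procedure)|fullyDefined|100003|260686004=350003 425391005=330001",
  "500003|Imaging procedure (procedure)|fullyDefined|100003|260686004=350002",
  "500004|Excision procedure (procedure)|fullyDefined|100003|260686004=350001",
  "500005|Excision of skin (procedure)|fullyDefined|500004|260686004=350001 405813007=310001"
)

# One retired concept (and its retired is-a row) exercises the inactive index.
ALLERGY_MINI_INACTIVE <- list(
  concept = c(id = "999999", fsn = "Retired finding (finding)"),
  parent = "100002")

# attributeId|domain|range|maxPerGroup|groupedAllowed
ALLERGY_MINI_MRCM <- c(
  "246075003|<< 100002|<< 100005|1|true",
  "363698007|<< 100002|<< 100004|1|true",
  "116676008|<< 100002|<< 100006|1|true",
  "370135005|<< 100002|<< 360001|1|true",
  "263502005|<< 100002|<< 340003|1|false",
  "719722006|<< 100002|<< 360001|1|true",
  "246454002|<< 100002|<< 370001|1|true",
  "42752001|<< 100002|<< 100002|1|true",
  "260686004|<< 100003|<< 100010|1|true",
  "363704007|<< 100003|<< 100004|1|true",
  "405813007|<< 100003|<< 100004|1|true",
  "405814001|<< 100003|<< 100004|1|true",
  "363701004|<< 100003|<< 100005|1|true",
  "363700003|<< 100003|<< 100006|1|true",
  "424361007|<< 100003|<< 100005|1|true",
  "405815000|<< 100003|<< 100008|1|true",
  "424226004|<< 100003|<< 100008|1|true",
  "425391005|<< 100003|<< 330002|1|true",
  "363703001|<< 100003|<< 380001|1|true",
  "260507000|<< 100003|<< 390001|1|true",
  "424876005|<< 100003|<< 395001|1|true",
  "363702006|<< 100003|<< 100002|1|true"
)

ALLERGY_MINI_CATEGORIES <- list(
  list(id = "allergic-reaction", name = "Allergic reaction",
       constraint = "<< 400001", profileSets = c("nashp-like", "mii-like")),
  list(id = "allergy", name = "Allergies",
       constraint = "<< 400010", profileSets = c("nashp-like", "mii-like")),
  list(id = "disease-due-to-allergy", name = "Disease due to allergy",
       constraint = "<< 400020", profileSets = c("nashp-like", "mii-like")),
  list(id = "clinical-finding", name = "Clinical finding (general)",
       constraint = "<< 100002 MINUS << 400001 MINUS << 400010 MINUS << 400020",
       profileSets = c("nashp-like", "mii-like")),
  list(id = "procedure", name = "Procedure",
       constraint = "<< 100003", profileSets = c("nashp-like", "mii-like"))
)

# Category element lists: the Superconcept plus the attributes considered
# for the category (finding categories share a core of five attributes, the
# allergy-flavoured ones add three, procedures have twelve).
ALLERGY_MINI_ELEMENTS <- list(
  "allergic-reaction" = c("Superconcept", "246075003", "363698007", "116676008",
                          "370135005", "263502005", "719722006", "246454002", "42752001"),
  "allergy" = c("Superconcept", "246075003", "363698007", "116676008",
                "370135005", "263502005", "719722006", "246454002", "42752001"),
  "disease-due-to-allergy" = c("Superconcept", "246075003", "363698007", "116676008",
                               "370135005", "263502005", "719722006", "246454002", "42752001"),
  "clinical-finding" = c("Superconcept", "246075003", "363698007", "116676008",
                         "370135005", "263502005"),
  "procedure" = c("Superconcept", "260686004", "405813007", "405814001", "363701004",
                  "363700003", "424361007", "424226004", "425391005", "363703001",
                  "260507000", "424876005", "363702006")
)

EXT_DISEASE_COURSE <- "http://hl7.org/fhir/StructureDefinition/condition-diseaseCourse"
EXT_DUE_TO <- "http://hl7.org/fhir/StructureDefinition/condition-dueTo"
EXT_RELATED <- "http://hl7.org/fhir/StructureDefinition/condition-related"
EXT_LIFE_PHASE <- "https://fhir.kbv.de/StructureDefinition/KBV_EX_Base_Abatement_Lebensphase_Von"
EXT_HAS_FOCUS <- "http://hl7.org/fhir/StructureDefinition/procedure-hasFocus"
MANIFESTATION_PATH <- "AllergyIntolerance.reaction.manifestation.coding:snomed"

# rules: list of c(source, path) or c(source, path, "extension")
allergy_mini_maps <- function() {
  rule <- function(source, path, ext = FALSE) list(source = source, path = path, ext = ext)
  maps <- list(
    list(category = "allergic-reaction", profileSet = "nashp-like",
      rules = list(
        rule("Superconcept", "Condition.code"),
        rule("246075003", "AllergyIntolerance.code"),
        rule("363698007", "Condition.bodySite"),
        rule("116676008", MANIFESTATION_PATH),
        rule("370135005", MANIFESTATION_PATH),
        rule("719722006", MANIFESTATION_PATH),
        rule("246454002", paste0("AllergyIntolerance.extension(", EXT_LIFE_PHASE, ")")),
        rule("263502005", paste0("Condition.extension(", EXT_DISEASE_COURSE, ")"), TRUE),
        rule("42752001", paste0("Condition.extension(", EXT_DUE_TO, ")"), TRUE)),
      references = list(c("Condition.subject", "Patient"),
                        c("AllergyIntolerance.patient", "Patient")),
      profiles = c(Condition = "KBV_PR_Base_Condition",
                   AllergyIntolerance = "KBV_PR_Base_AllergyIntolerance")),
    list(category = "allergic-reaction", profileSet = "mii-like",
      rules = list(
        rule("Superconcept", "Condition.code"),
        rule("246075003", "Observation.valueCodeableConcept"),
        rule("363698007", "Condition.bodySite"),
        rule("116676008", "Condition.evidence.code"),
        rule("370135005", "Condition.evidence.code"),
        rule("719722006", "Condition.evidence.code"),
        rule("246454002", "Condition.onset"),
        rule("263502005", paste0("Condition.extension(", EXT_DISEASE_COURSE, ")"), TRUE)),
      references = list(c("Observation.focus", "Condition"),
                        c("Condition.subject", "Patient"),
                        c("Observation.subject", "Patient")),
      profiles = c(Condition = "MII_PR_Diagnose_Condition",
                   Observation = "MII_PR_Befund_Observation")),
    list(category = "allergy", profileSet = "nashp-like",
      rules = list(
        rule("Superconcept", "AllergyIntolerance.code"),
        rule("246075003", "AllergyIntolerance.reaction.substance"),
        rule("116676008", MANIFESTATION_PATH),
        rule("370135005", MANIFESTATION_PATH),
        rule("246454002", paste0("AllergyIntolerance.extension(", EXT_LIFE_PHASE, ")")),
        rule("263502005", paste0("AllergyIntolerance.extension(", EXT_DISEASE_COURSE, ")"), TRUE)),
      references = list(c("AllergyIntolerance.patient", "Patient")),
      profiles = c(AllergyIntolerance = "KBV_PR_Base_AllergyIntolerance")),
    list(category = "allergy", profileSet = "mii-like",
      rules = list(
        rule("Superconcept", "Condition.code"),
        rule("246075003", "Observation.valueCodeableConcept"),
        rule("363698007", "Condition.bodySite"),
        rule("116676008", "Condition.evidence.code"),
        rule("370135005", "Condition.evidence.code"),
        rule("263502005", paste0("Condition.extension(", EXT_DISEASE_COURSE, ")"), TRUE),
        rule("42752001", paste0("Condition.extension(", EXT_DUE_TO, ")"), TRUE)),
      references = list(c("Observation.focus", "Condition"),
                        c("Condition.subject", "Patient"),
                        c("Observation.subject", "Patient")),
      profiles = c(Condition = "MII_PR_Diagnose_Condition",
                   Observation = "MII_PR_Befund_Observation")),
    list(category = "disease-due-to-allergy", profileSet = "nashp-like",
      rules = list(
        rule("Superconcept", "Condition.code"),
        rule("246075003", "AllergyIntolerance.code"),
        rule("363698007", "Condition.bodySite"),
        rule("116676008", "Condition.evidence.code"),
        rule("370135005", "Condition.evidence.code"),
        rule("719722006", "Condition.evidence.code"),
        rule("246454002", paste0("AllergyIntolerance.extension(", EXT_LIFE_PHASE, ")")),
        rule("263502005", paste0("Condition.extension(", EXT_DISEASE_COURSE, ")"), TRUE),
        rule("42752001", paste0("Condition.extension(", EXT_DUE_TO, ")"), TRUE)),
      references = list(c("Condition.subject", "Patient"),
                        c("AllergyIntolerance.patient", "Patient")),
      profiles = c(Condition = "KBV_PR_Base_Condition",
                   AllergyIntolerance = "KBV_PR_Base_AllergyIntolerance")),
    list(category = "disease-due-to-allergy", profileSet = "mii-like",
      rules = list(
        rule("Superconcept", "Condition.code"),
        rule("246075003", "Observation.valueCodeableConcept"),
        rule("363698007", "Condition.bodySite"),
        rule("116676008", "Condition.evidence.code"),
        rule("370135005", "Condition.evidence.code"),
        rule("719722006", "Condition.evidence.code"),
        rule("246454002", "Condition.onset"),
        rule("263502005", paste0("Condition.extension(", EXT_DISEASE_COURSE, ")"), TRUE),
        rule("42752001", paste0("Condition.extension(", EXT_DUE_TO, ")"), TRUE)),
      references = list(c("Observation.focus", "Condition"),
                        c("Condition.subject", "Patient"),
                        c("Observation.subject", "Patient")),
      profiles = c(Condition = "MII_PR_Diagnose_Condition",
                   Observation = "MII_PR_Befund_Observation")),
    list(category = "clinical-finding", profileSet = "nashp-like",
      rules = list(
        rule("Superconcept", "Condition.code"),
        rule("246075003", "AllergyIntolerance.code"),
        rule("363698007", "Condition.bodySite"),
        rule("116676008", "Condition.evidence.code"),
        rule("370135005", paste0("Condition.extension(", EXT_RELATED, ")"), TRUE),
        rule("263502005", paste0("Condition.extension(", EXT_DISEASE_COURSE, ")"), TRUE)),
      references = list(c("Condition.subject", "Patient"),
                        c("AllergyIntolerance.patient", "Patient")),
      profiles = c(Condition = "KBV_PR_Base_Condition",
                   AllergyIntolerance = "KBV_PR_Base_AllergyIntolerance")),
    list(category = "clinical-finding", profileSet = "mii-like",
      rules = list(
        rule("Superconcept", "Condition.code"),
        rule("246075003", "Observation.valueCodeableConcept"),
        rule("363698007", "Condition.bodySite"),
        rule("116676008", "Condition.evidence.code"),
        rule("370135005", paste0("Condition.extension(", EXT_RELATED, ")"), TRUE),
        rule("263502005", paste0("Condition.extension(", EXT_DISEASE_COURSE, ")"), TRUE)),
      references = list(c("Observation.focus", "Condition"),
                        c("Condition.subject", "Patient"),
                        c("Observation.subject", "Patient")),
      profiles = c(Condition = "MII_PR_Diagnose_Condition",
                   Observation = "MII_PR_Befund_Observation")),
    list(category = "procedure", profileSet = "nashp-like",
      rules = list(
        rule("Superconcept", "Procedure.code"),
        rule("260686004", "Procedure.method"),
        rule("405813007", "Procedure.bodySite"),
        rule("405814001", "Procedure.bodySite"),
        rule("363701004", "Procedure.usedCode"),
        rule("424361007", "Procedure.usedCode"),
        rule("363700003", "Procedure.outcome"),
        rule("424226004", "Device.type"),
        rule("425391005", "Device.type"),
        rule("363703001", "Procedure.category"),
        rule("260507000", "Procedure.access"),
        rule("424876005", "Procedure.approach"),
        rule("363702006", paste0("Procedure.extension(", EXT_HAS_FOCUS, ")"), TRUE)),
      references = list(c("Procedure.usedReference", "Device"),
                        c("Procedure.subject", "Patient")),
      profiles = c(Procedure = "KBV_PR_Base_Procedure",
                   Device = "KBV_PR_Base_Device")),
    list(category = "procedure", profileSet = "mii-like",
      rules = list(
        rule("Superconcept", "Procedure.code"),
        rule("260686004", "Procedure.method"),
        rule("405813007", "Procedure.bodySite"),
        rule("405814001", "Procedure.bodySite"),
        rule("363701004", "Procedure.usedCode"),
        rule("424361007", "Procedure.usedCode"),
        rule("363700003", "Procedure.outcome"),
        rule("424226004", "Device.type"),
        rule("425391005", "Device.type"),
        rule("363703001", "Procedure.category"),
        rule("260507000", "Procedure.access"),
        rule("424876005", "Procedure.approach"),
        rule("363702006", paste0("Procedure.extension(", EXT_HAS_FOCUS, ")"), TRUE)),
      references = list(c("Procedure.usedReference", "Device"),
                        c("Procedure.subject", "Patient")),
      profiles = c(Procedure = "MII_PR_Prozedur_Procedure",
                   Device = "MII_PR_Geraet_Device"))
  )
  maps
}

structuremap_document <- function(m) {
  mapping_rules <- lapply(seq_along(m$rules), function(i) {
    r <- m$rules[[i]]
    doc <- list(
      name = sprintf("rule-%02d", i),
      source = list(list(context = "source", value = r$source)),
      target = list(list(context = "target", value = r$path)))
    if (isTRUE(r$ext)) doc$documentation <- "extension"
    doc
  })
  ref_rules <- lapply(seq_along(m$references), function(i) {
    r <- m$references[[i]]
    list(name = sprintf("ref-%02d", i),
         source = list(list(context = "source", value = r[[1]])),
         target = list(list(context = "target", value = r[[2]])))
  })
  prof_rules <- lapply(seq_along(m$profiles), function(i) {
    list(name = sprintf("profile-%02d", i),
         source = list(list(context = "source", value = names(m$profiles)[i])),
         target = list(list(context = "target", value = unname(m$profiles[i]))))
  })
  list(
    resourceType = "StructureMap",
    id = paste0(m$category, "--", m$profileSet),
    url = paste0("urn:sctfhir:structuremap:", m$category, "--", m$profileSet),
    name = paste0(m$category, "--", m$profileSet),
    status = "active",
    group = list(
      list(name = "mapping", rule = mapping_rules),
      list(name = "references", rule = ref_rules),
      list(name = "profiles", rule = prof_rules)))
}

allergy_mini_tables <- function() {
  parts <- strsplit(ALLERGY_MINI_CONCEPTS, "|", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  fsns <- vapply(parts, `[`, character(1), 2)
  status <- vapply(parts, `[`, character(1), 3)
  parents <- lapply(parts, function(p) {
    if (length(p) < 4 || !nzchar(p[4])) character(0)
    else strsplit(p[4], " ", fixed = TRUE)[[1]]
  })
  defs <- lapply(parts, function(p) {
    if (length(p) < 5 || !nzchar(p[5])) character(0)
    else strsplit(p[5], " ", fixed = TRUE)[[1]]
  })

  concepts <- data.frame(
    id = c(ids, ALLERGY_MINI_INACTIVE$concept[["id"]]),
    effectiveTime = "20230430",
    active = c(rep("1", length(ids)), "0"),
    moduleId = "900000000000207008",
    definitionStatusId = c(status, "primitive"),
    stringsAsFactors = FALSE)

  rel_rows <- list()
  add_rel <- function(src, dst, type, group, active = "1") {
    rel_rows[[length(rel_rows) + 1L]] <<- data.frame(
      id = sprintf("%d", 7000000L + length(rel_rows)),
      effectiveTime = "20230430", active = active,
      moduleId = "900000000000207008",
      sourceId = src, destinationId = dst,
      relationshipGroup = as.character(group), typeId = type,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(ids)) {
    for (p in parents[[i]]) add_rel(ids[i], p, "116680003", 0)
    for (d in defs[[i]]) {
      kv <- strsplit(d, "=", fixed = TRUE)[[1]]
      add_rel(ids[i], kv[2], kv[1], 0)
    }
  }
  add_rel(ALLERGY_MINI_INACTIVE$concept[["id"]], ALLERGY_MINI_INACTIVE$parent,
          "116680003", 0, active = "0")
  relationships <- do.call(rbind, rel_rows)

  descriptions <- data.frame(
    id = sprintf("%d", 8000000L + seq_along(ids)),
    active = "1",
    conceptId = ids,
    typeId = "900000000000003001",
    term = fsns,
    stringsAsFactors = FALSE)

  list(concepts = concepts, relationships = relationships,
       descriptions = descriptions)
}

#' Build the bundled allergy-mini fixture
#'
#' Constructs the static synthetic terminology (polyhierarchy of findings,
#' procedures, substances, body structures, morphologies, devices and
#' qualifier values, with an attribute subtree containing the three-level
#' device-attribute chain), its concept-model rules, the five disjoint
#' content categories, the per-category element lists, and the bundle of 10
#' StructureMaps. The fixture's flagship scenario is the expression
#' `400001:116676008=320001,246075003=300002` (an allergic reaction caused
#' by a tree nut, with swelling): classification yields exactly the two
#' incomparable candidates `400003` (allergic reaction caused by tree nut)
#' and `400002` (swelling).
#'
#' @param dir Optional directory; when given, the RF2 files (`concepts.tsv`,
#'   `relationships.tsv`, `descriptions.tsv`), `mrcm.yaml`,
#'   `categories.yaml`, and `maps/` (10 StructureMap JSON documents plus
#'   `elements.yaml`) are written there, byte-identically on every call.
#' @return List with `terminology`, `mrcm`, `categories`, `elements`,
#'   `maps`, `flagship` (the flagship expression), and `manifest` (declared
#'   counts).
#' @export
build_allergy_mini <- function(dir = NULL) {
  tabs <- allergy_mini_tables()
  term <- terminology(tabs$concepts, tabs$relationships, tabs$descriptions,
                      isa_id = "116680003")
  mrcm_parts <- strsplit(ALLERGY_MINI_MRCM, "|", fixed = TRUE)
  mrcm <- lapply(mrcm_parts, function(p) {
    mrcm_rule(p[1], p[2], p[3], maxPerGroup = as.numeric(p[4]),
              groupedAllowed = identical(p[5], "true"))
  })
  names(mrcm) <- vapply(mrcm, function(r) r$attributeId, character(1))
  categories <- lapply(ALLERGY_MINI_CATEGORIES, function(x) {
    structure(list(id = x$id, name = x$name, constraint = x$constraint,
                   profileSets = x$profileSets), class = "sct_category")
  })
  map_docs <- lapply(allergy_mini_maps(), structuremap_document)
  maps <- lapply(map_docs, load_structuremap)
  names(maps) <- vapply(maps, function(m) paste0(m$categoryId, "--", m$profileSetId),
                        character(1))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv <- function(df, name) {
      utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
    }
    write_tsv(tabs$concepts, "concepts.tsv")
    write_tsv(tabs$relationships, "relationships.tsv")
    write_tsv(tabs$descriptions, "descriptions.tsv")
    yaml::write_yaml(lapply(mrcm, function(r) list(
      attributeId = r$attributeId, domainConstraint = r$domainConstraint,
      rangeConstraint = r$rangeConstraint,
      maxPerGroup = if (is.infinite(r$maxPerGroup)) "unbounded" else r$maxPerGroup,
      groupedAllowed = r$groupedAllowed)), file.path(dir, "mrcm.yaml"))
    yaml::write_yaml(lapply(ALLERGY_MINI_CATEGORIES, function(x) {
      x$profileSets <- as.list(x$profileSets); x
    }), file.path(dir, "categories.yaml"))
    maps_dir <- file.path(dir, "maps")
    dir.create(maps_dir, showWarnings = FALSE)
    for (doc in map_docs) {
      jsonlite::write_json(doc, file.path(maps_dir, paste0(doc$id, ".json")),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    yaml::write_yaml(lapply(ALLERGY_MINI_ELEMENTS, as.list),
                     file.path(maps_dir, "elements.yaml"))
  }
  list(terminology = term, mrcm = mrcm, categories = categories,
       elements = ALLERGY_MINI_ELEMENTS, maps = maps,
       flagship = parse_expression("400001:116676008=320001,246075003=300002"),
       manifest = list(
         activeConceptCount = sum(as_flag(tabs$concepts$active)),
         totalConceptCount = nrow(tabs$concepts),
         mapCount = length(maps),
         categoryCount = length(categories)))
}
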