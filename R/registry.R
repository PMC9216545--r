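# The SSSOM schema registry: metadata slots, controlled vocabularies and the
# recommended mapping predicates. The registry is fixed at build time; all
# other modules interrogate it rather than hard-coding slot lists.

# -- slot registry ------------------------------------------------------------

# One definition per distinct slot. `level` is "mapping", "mapping_set" or
# "both"; declaration order within each level follows the schema.
.slot_def <- function(name, level, datatype = "string", required = FALSE,
                      multivalued = FALSE, external_property = NA_character_) {
  list(name = name, level = level, datatype = datatype, required = required,
       multivalued = multivalued, external_property = external_property)
}

.SLOT_DEFS <- list(
  # mapping-only slots
  .slot_def("subject_id", "mapping", "entity_reference", required = TRUE),
  .slot_def("subject_label", "mapping"),
  .slot_def("subject_category", "mapping"),
  .slot_def("predicate_id", "mapping", "entity_reference", required = TRUE),
  .slot_def("predicate_label", "mapping"),
  .slot_def("predicate_modifier", "mapping", "predicate_modifier"),
  .slot_def("object_id", "mapping", "entity_reference", required = TRUE),
  .slot_def("object_label", "mapping"),
  .slot_def("object_category", "mapping"),
  .slot_def("match_type", "mapping", "match_type", required = TRUE),
  .slot_def("mapping_cardinality", "mapping"),
  .slot_def("author_id", "mapping", "entity_reference", multivalued = TRUE,
            external_property = "pav:authoredBy"),
  .slot_def("author_label", "mapping"),
  .slot_def("reviewer_id", "mapping", "entity_reference", multivalued = TRUE,
            external_property = "prov:wasAttributedTo"),
  .slot_def("reviewer_label", "mapping"),
  # shared slots (level "both")
  .slot_def("creator_id", "both", "entity_reference", multivalued = TRUE,
            external_property = "dcterms:creator"),
  .slot_def("creator_label", "both"),
  .slot_def("license", "both", external_property = "dcterms:license"),
  .slot_def("subject_source", "both", external_property = "dcterms:source"),
  .slot_def("subject_source_version", "both"),
  .slot_def("object_source", "both", external_property = "dcterms:source"),
  .slot_def("object_source_version", "both"),
  .slot_def("mapping_provider", "both", external_property = "dcterms:publisher"),
  .slot_def("mapping_tool", "both"),
  .slot_def("mapping_tool_version", "both"),
  .slot_def("mapping_date", "both", "date", external_property = "pav:authoredOn"),
  .slot_def("publication_date", "both", "date", external_property = "dcterms:issued"),
  .slot_def("confidence", "mapping", "double"),
  .slot_def("subject_match_field", "both", "entity_reference", multivalued = TRUE),
  .slot_def("object_match_field", "both", "entity_reference", multivalued = TRUE),
  .slot_def("match_string", "mapping", multivalued = TRUE),
  .slot_def("subject_preprocessing", "both", multivalued = TRUE),
  .slot_def("object_preprocessing", "both", multivalued = TRUE),
  .slot_def("semantic_similarity_score", "mapping", "double"),
  .slot_def("semantic_similarity_measure", "mapping"),
  .slot_def("see_also", "both", multivalued = TRUE,
            external_property = "rdfs:seeAlso"),
  .slot_def("other", "both"),
  .slot_def("comment", "both", external_property = "rdfs:comment"),
  # mapping-set-only slots
  .slot_def("mapping_set_id", "mapping_set", required = TRUE,
            external_property = "dcterms:identifier"),
  .slot_def("mapping_set_version", "mapping_set"),
  .slot_def("mapping_set_description", "mapping_set",
            external_property = "dcterms:description"),
  .slot_def("curie_map", "mapping_set", "prefix_map")
)

.slot_table <- function() {
  tibble::tibble(
    name = vapply(.SLOT_DEFS, `[[`, "", "name"),
    level = vapply(.SLOT_DEFS, `[[`, "", "level"),
    datatype = vapply(.SLOT_DEFS, `[[`, "", "datatype"),
    required = vapply(.SLOT_DEFS, `[[`, NA, "required"),
    multivalued = vapply(.SLOT_DEFS, `[[`, NA, "multivalued"),
    external_property = vapply(.SLOT_DEFS, `[[`, "", "external_property")
  )
}

.SLOT_TABLE <- .slot_table()

# Canonical per-level slot orders. The mapping-set order interleaves the
# set-only identification slots ahead of the shared provenance block.
.MAPPING_SET_ORDER <- c(
  "mapping_set_id", "mapping_set_version", "mapping_set_description",
  "curie_map", "creator_id", "creator_label", "license",
  "subject_source", "subject_source_version",
  "object_source", "object_source_version",
  "mapping_provider", "mapping_tool", "mapping_tool_version",
  "mapping_date", "publication_date",
  "subject_match_field", "object_match_field",
  "subject_preprocessing", "object_preprocessing",
  "see_also", "other", "comment"
)

#' SSSOM metadata slot registry
#'
#' Returns the schema registry of metadata slots for individual mappings or
#' for mapping sets. Each mapping can carry up to 38 slots, four of which
#' (`subject_id`, `predicate_id`, `object_id`, `match_type`) are required;
#' mapping sets carry 23 slots including `mapping_set_id` and the prefix map.
#'
#' @param level `"mapping"` or `"mapping_set"`.
#' @return A tibble with columns `name`, `level`, `datatype`, `required`,
#'   `multivalued` and `external_property` (`NA` for SSSOM-native slots),
#'   in canonical declaration order for the requested level.
#' @examples
#' nrow(sssom_slots("mapping"))      # 38
#' nrow(sssom_slots("mapping_set"))  # 23
#' @export
sssom_slots <- function(level = c("mapping", "mapping_set")) {
  if (length(level) != 1 || !level %in% c("mapping", "mapping_set")) {
    sssom_abort("level must be 'mapping' or 'mapping_set'", "sssom_usage_error")
  }
  tab <- .SLOT_TABLE
  if (level == "mapping") {
    out <- tab[tab$level %in% c("mapping", "both"), , drop = FALSE]
  } else {
    out <- tab[match(.MAPPING_SET_ORDER, tab$name), , drop = FALSE]
    # mapping_set_id is required at set level; mapping-level requiredness of
    # shared slots does not apply here
    out$required <- out$name == "mapping_set_id"
    # only creator_id and see_also are multivalued at set level
    out$multivalued <- out$name %in% c("creator_id", "see_also")
  }
  out$external_property[is.na(out$external_property)] <- NA_character_
  out
}

.MAPPING_SLOTS <- sssom_slots("mapping")$name
.SET_SLOTS <- .MAPPING_SET_ORDER
.REQUIRED_MAPPING_SLOTS <- c("subject_id", "predicate_id", "object_id", "match_type")
.MULTIVALUED_MAPPING_SLOTS <-
  .SLOT_TABLE$name[.SLOT_TABLE$multivalued & .SLOT_TABLE$level %in% c("mapping", "both")]
.MULTIVALUED_SET_SLOTS <- c("creator_id", "see_also")
.DOUBLE_SLOTS <- .SLOT_TABLE$name[.SLOT_TABLE$datatype == "double"]
.DATE_SLOTS <- .SLOT_TABLE$name[.SLOT_TABLE$datatype == "date"]
.ENTITY_REF_MAPPING_SLOTS <-
  .SLOT_TABLE$name[.SLOT_TABLE$datatype == "entity_reference" &
                     .SLOT_TABLE$level %in% c("mapping", "both")]

# -- controlled vocabularies --------------------------------------------------

.MATCH_TYPES <- c("Lexical", "Logical", "HumanCurated", "SemanticSimilarity",
                  "Complex")
.PREDICATE_MODIFIERS <- "Not"
.CARDINALITIES <- c("1:1", "1:n", "n:1", "n:n")

#' Controlled vocabulary of match types
#'
#' The five ways a match can be established: `Lexical` (lexical analysis),
#' `Logical` (automated reasoner), `HumanCurated` (domain expert),
#' `SemanticSimilarity` (similarity algorithm such as Resnik or Jaccard) and
#' `Complex` (a combination of strategies, typically an automated tool).
#'
#' @return Character vector of the five match types.
#' @export
sssom_match_types <- function() .MATCH_TYPES

# -- predicate registry -------------------------------------------------------

.PREDICATE_TABLE <- tibble::tibble(
  predicate_id = c("owl:sameAs", "owl:equivalentClass", "owl:equivalentProperty",
                   "rdfs:subClassOf", "rdfs:subPropertyOf",
                   "skos:relatedMatch", "skos:closeMatch", "skos:exactMatch",
                   "skos:narrowMatch", "skos:broadMatch"),
  strength = c("EXACT", "EXACT", "EXACT",
               "BROAD", "BROAD",
               "RELATED", "CLOSE", "EXACT",
               "NARROW", "BROAD"),
  entity_kind = c("individual", "class", "property",
                  "class", "property",
                  "class", "class", "class",
                  "class", "class")
)

.STRENGTHS <- c("EXACT", "CLOSE", "RELATED", "BROAD", "NARROW")

#' Recommended mapping predicates
#'
#' The ten recommended values of `predicate_id`, drawn from SKOS and OWL,
#' with the strength class each implies (`EXACT`, `CLOSE`, `RELATED`,
#' `BROAD`, `NARROW`) and the kind of entity it relates (`owl:sameAs` maps
#' individuals, `rdfs:subPropertyOf` maps properties, the rest map classes).
#' `BROAD` means the subject is narrower than the object (skos:broadMatch,
#' rdfs:subClassOf); `NARROW` is its inverse.
#'
#' @return A tibble with columns `predicate_id`, `strength`, `entity_kind`.
#' @export
sssom_predicates <- function() .PREDICATE_TABLE

#' Strength class of a mapping predicate
#'
#' @param predicate_id A CURIE such as `"skos:exactMatch"`.
#' @return One of `"EXACT"`, `"CLOSE"`, `"RELATED"`, `"BROAD"`, `"NARROW"`,
#'   or `"UNKNOWN"` for any predicate outside the recommended set
#'   (unregistered predicates are allowed but flagged downstream).
#' @examples
#' predicate_class("skos:exactMatch")  # "EXACT"
#' predicate_class("rdfs:subClassOf")  # "BROAD"
#' @export
predicate_class <- function(predicate_id) {
  assert_curie(predicate_id)
  i <- match(predicate_id, .PREDICATE_TABLE$predicate_id)
  if (is.na(i)) "UNKNOWN" else .PREDICATE_TABLE$strength[i]
}

#' Inverse of a strength class
#'
#' `EXACT`, `CLOSE` and `RELATED` are symmetric; `BROAD` and `NARROW`
#' exchange when a mapping is read from object to subject.
#'
#' @param strength One of the five strength classes.
#' @return The strength class of the reversed mapping.
#' @export
strength_inverse <- function(strength) {
  if (!strength %in% .STRENGTHS) {
    sssom_abort(paste0("unknown strength class: ", strength), "sssom_usage_error")
  }
  switch(strength, BROAD = "NARROW", NARROW = "BROAD", strength)
}

#' External vocabulary property for a slot
#'
#' Thirteen SSSOM slots are mapped to external vocabularies (two to PAV, one
#' to PROV-O, the rest to Dublin Core terms or RDFS); these properties are
#' used in the RDF serializations. All other slots are SSSOM-native.
#'
#' @param slot_name A registered slot name.
#' @return The external property CURIE, or `NA_character_` for native slots.
#' @examples
#' external_property_for("author_id")  # "pav:authoredBy"
#' external_property_for("match_type") # NA
#' @export
external_property_for <- function(slot_name) {
  i <- match(slot_name, .SLOT_TABLE$name)
  if (is.na(i)) {
    sssom_abort(paste0("unknown slot: ", slot_name), "sssom_lookup_error")
  }
  .SLOT_TABLE$external_property[i]
}
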