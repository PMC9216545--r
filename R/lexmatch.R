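# Lexical matcher over flat label tables, in the style of rdf-matcher:
# entities match when their preprocessed label/synonym strings are equal,
# and every (field, field) agreement is emitted as its own row ("one row per
# mapping rule") with full match metadata, so downstream consumers can see
# exactly which evidence produced each mapping.

.MATCH_FIELDS <- c("rdfs:label", "oboInOwl:hasExactSynonym", "skos:exactMatch")
.PREPROCESS_STEPS <- c("lowercase", "strip_nonalphanumeric", "strip_digits",
                       "collapse_whitespace")
# steps that can merge distinct strings beyond trivial case/spacing variation
.DESTRUCTIVE_STEPS <- c("strip_nonalphanumeric", "strip_digits")

.OBOINOWL_PREFIX <- c(oboInOwl = "http://www.geneontology.org/formats/oboInOwl#")

#' Preprocess a label
#'
#' Applies normalization steps left to right: `lowercase` (case fold),
#' `strip_nonalphanumeric` (drop everything but letters, digits and
#' spaces), `strip_digits` (drop digits — destructive: "Alzheimer 2" and
#' "Alzheimer 3" collapse), `collapse_whitespace` (trim and squeeze runs of
#' whitespace to single spaces).
#'
#' @param text Character vector of labels.
#' @param steps Ordered character vector of step names (possibly empty).
#' @return The normalized labels.
#' @examples
#' preprocess_label("Alzheimer 2", c("lowercase", "strip_nonalphanumeric",
#'                                   "collapse_whitespace"))  # "alzheimer 2"
#' @export
preprocess_label <- function(text, steps = character(0)) {
  bad <- setdiff(steps, .PREPROCESS_STEPS)
  if (length(bad) > 0) {
    sssom_abort(paste0("unknown preprocessing step(s): ",
                       paste(bad, collapse = ", ")), "sssom_usage_error")
  }
  for (step in steps) {
    text <- switch(step,
      lowercase = tolower(text),
      strip_nonalphanumeric = gsub("[^[:alnum:] ]+", "", text),
      strip_digits = gsub("[0-9]+", "", text),
      collapse_whitespace = gsub("[[:space:]]+", " ", trimws(text)))
  }
  text
}

#' Matcher configuration
#'
#' @param preprocessing Ordered preprocessing steps applied to both sides
#'   before comparison.
#' @param predicate Predicate asserted for each match.
#' @param weights Named numeric vector of base confidences per unordered
#'   field pair, keyed `"field1~field2"` with fields sorted; defaults:
#'   label/label 0.9, label/other 0.8, other/other 0.7. Each destructive
#'   preprocessing step deducts 0.05.
#' @return A list of class `sssom_match_config`.
#' @export
match_config <- function(preprocessing = c("lowercase", "collapse_whitespace"),
                         predicate = "skos:exactMatch",
                         weights = NULL) {
  bad <- setdiff(preprocessing, .PREPROCESS_STEPS)
  if (length(bad) > 0) {
    sssom_abort(paste0("unknown preprocessing step(s): ",
                       paste(bad, collapse = ", ")), "sssom_usage_error")
  }
  assert_curie(predicate)
  if (!is.null(weights) && (any(weights < 0) || any(weights > 1))) {
    sssom_abort("rule weights must lie in [0,1]", "sssom_range_error")
  }
  structure(list(preprocessing = preprocessing, predicate = predicate,
                 weights = weights),
            class = "sssom_match_config")
}

pair_key <- function(f1, f2) {
  paste(sort(c(f1, f2)), collapse = "~")
}

rule_weight <- function(f1, f2, config) {
  key <- pair_key(f1, f2)
  w <- config$weights[[key]]
  if (is.null(w)) {
    n_label <- sum(c(f1, f2) == "rdfs:label")
    w <- c(0.7, 0.8, 0.9)[n_label + 1]
  }
  penalty <- 0.05 * sum(config$preprocessing %in% .DESTRUCTIVE_STEPS)
  max(0, w - penalty)
}

check_label_table <- function(tab, which) {
  need <- c("entity_id", "field", "text")
  if (!all(need %in% names(tab))) {
    sssom_abort(paste0(which, " table needs columns entity_id, field, text"),
                "sssom_usage_error")
  }
  if (any(is.na(tab$text) | tab$text == "")) {
    sssom_abort(paste0(which, " table has empty label text"), "sssom_format_error")
  }
  bad <- setdiff(unique(tab$field), .MATCH_FIELDS)
  if (length(bad) > 0) {
    sssom_abort(paste0("unregistered match field(s): ", paste(bad, collapse = ", ")),
                "sssom_format_error")
  }
  invisible(tab)
}

#' Lexical matching between two label tables
#'
#' Emits one mapping per (subject record, object record) pair whose
#' preprocessed texts are equal — one row per mapping rule, so an entity
#' pair agreeing on both primary labels and exact synonyms yields two rows.
#' Every row carries `match_type = Lexical`, the two match fields, the
#' shared match string, the preprocessing steps applied and a
#' rule-dependent confidence. Self-matches (identical `entity_id`) are
#' suppressed.
#'
#' @param subjects,objects Label tables: data frames with columns
#'   `entity_id` (CURIE), `field` (one of `rdfs:label`,
#'   `oboInOwl:hasExactSynonym`, `skos:exactMatch`) and `text`.
#' @param config A [match_config()].
#' @param curie_map Prefix map declaring the entity prefixes used in the
#'   tables (the match-field prefixes are added automatically).
#' @param mapping_set_id Identifier for the emitted set.
#' @return A `sssom_mapping_set`, rows sorted by subject, object, then
#'   confidence descending.
#' @export
lexical_match <- function(subjects, objects, config = match_config(),
                          curie_map = prefix_map(),
                          mapping_set_id = "https://example.org/sssomr/lexmatch") {
  check_label_table(subjects, "subjects")
  check_label_table(objects, "objects")
  overlap <- intersect(unique(subjects$entity_id), unique(objects$entity_id))
  if (length(overlap) > 0) {
    sssom_warn(paste0("entity_id present in both tables: ",
                      paste(overlap, collapse = ", ")), "sssom_entity_overlap")
  }
  skey <- preprocess_label(subjects$text, config$preprocessing)
  okey <- preprocess_label(objects$text, config$preprocessing)

  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    if (skey[i] == "") next  # label fully consumed by preprocessing
    js <- which(okey == skey[i] & objects$entity_id != subjects$entity_id[i])
    for (j in js) {
      rows[[length(rows) + 1]] <- make_mapping(
        subject_id = subjects$entity_id[i],
        predicate_id = config$predicate,
        object_id = objects$entity_id[j],
        match_type = "Lexical",
        subject_match_field = subjects$field[i],
        object_match_field = objects$field[j],
        match_string = skey[i],
        subject_preprocessing = config$preprocessing,
        object_preprocessing = config$preprocessing,
        confidence = rule_weight(subjects$field[i], objects$field[j], config),
        mapping_tool = "sssomr-lexmatch")
    }
  }
  tab <- mappings_tibble(rows)
  if (nrow(tab) > 0) {
    tab <- tab[order(tab$subject_id, tab$object_id, -tab$confidence,
                     method = "radix"), , drop = FALSE]
  }
  pm <- merge_prefix_maps(curie_map, .OBOINOWL_PREFIX)
  new_mapping_set(
    list(mapping_set_id = as.character(mapping_set_id),
         mapping_tool = "sssomr-lexmatch"),
    pm, tab)
}
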