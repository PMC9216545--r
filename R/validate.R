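# Rule-based validator. Issues are data, not exceptions: each check appends
# rows (code, severity, locus, message) and the report is sorted by
# (code, locus). `locus` is the 1-based mapping row, or "set" for set-level
# findings.

.RULE_TABLE <- tibble::tibble(
  code = sprintf("R%02d", 1:13),
  severity = c("ERROR", "ERROR", "WARNING", "ERROR", "ERROR", "INFO", "ERROR",
               "WARNING", "WARNING", "ERROR", "ERROR", "WARNING", "INFO"),
  description = c(
    "required mapping slots present",
    "mapping_set_id present",
    "license present",
    "CURIEs well-formed and prefixes resolvable",
    "match_type drawn from the five-value vocabulary",
    "predicate outside the recommended set",
    "confidence / semantic_similarity_score within [0,1]",
    "SemanticSimilarity mapping lacks semantic_similarity_measure",
    "Lexical mapping lacks subject/object match_field",
    "dates are ISO-8601 (YYYY-MM-DD)",
    "predicate_modifier outside {Not}",
    "preprocessing recorded without the match_field it modifies",
    "duplicate identical mappings"
  )
)

#' The validation rule table
#' @return Tibble with columns `code`, `severity`, `description`.
#' @export
sssom_rules <- function() .RULE_TABLE

issue_row <- function(code, locus, message) {
  sev <- .RULE_TABLE$severity[.RULE_TABLE$code == code]
  tibble::tibble(code = code, severity = sev, locus = as.character(locus),
                 message = message)
}

row_values <- function(set, slot, i) {
  v <- set$mappings[[slot]][i]
  if (is.list(v)) v <- v[[1]]
  v[!is.na(v)]
}

#' Validate a mapping set
#'
#' Applies the full rule table (see [sssom_rules()]): presence of required
#' slots and the set identifier, license, CURIE well-formedness and prefix
#' resolvability, controlled vocabularies (match types, predicate
#' modifiers), numeric ranges, ISO dates, recommended-predicate usage,
#' match-type-specific metadata expectations, the preprocessing/match_field
#' idempotency hazard and duplicate rows.
#'
#' @param set A `sssom_mapping_set`.
#' @return A tibble of issues (`code`, `severity`, `locus`, `message`),
#'   ordered by code then locus; zero rows means a clean set.
#' @export
validate_sssom <- function(set) {
  issues <- list()
  add <- function(x) issues[[length(issues) + 1]] <<- x
  tab <- set$mappings
  n <- nrow(tab)
  resolvable <- resolvable_prefixes(set$curie_map)

  # R01 required mapping slots
  for (slot in .REQUIRED_MAPPING_SLOTS) {
    bad <- which(is.na(tab[[slot]]) | tab[[slot]] == "")
    for (i in bad) add(issue_row("R01", i, paste0("missing required slot ", slot)))
  }
  # R02 / R03 set-level presence
  if (blank(set$metadata$mapping_set_id)) {
    add(issue_row("R02", "set", "mapping_set_id is missing"))
  }
  if (blank(set$metadata$license)) {
    add(issue_row("R03", "set", "license is missing"))
  }
  # R04 CURIE well-formedness and prefix resolution
  for (slot in .ENTITY_REF_MAPPING_SLOTS) {
    for (i in seq_len(n)) {
      for (v in row_values(set, slot, i)) {
        if (!is_curie(v)) {
          add(issue_row("R04", i, paste0(slot, " is not a CURIE: ", v)))
        } else if (!curie_prefix(v) %in% resolvable) {
          add(issue_row("R04", i, paste0("undeclared prefix in ", slot, ": ",
                                         curie_prefix(v))))
        }
      }
    }
  }
  for (i in seq_len(n)) {
    mt <- row_values(set, "match_type", i)
    pid <- row_values(set, "predicate_id", i)
    # R05 match_type vocabulary
    if (length(mt) == 1 && !mt %in% .MATCH_TYPES) {
      add(issue_row("R05", i, paste0("unknown match_type: ", mt)))
    }
    # R06 unrecommended predicate
    if (length(pid) == 1 && is_curie(pid) &&
        !pid %in% .PREDICATE_TABLE$predicate_id) {
      add(issue_row("R06", i, paste0("unrecommended predicate: ", pid)))
    }
    # R07 numeric ranges
    for (slot in .DOUBLE_SLOTS) {
      v <- tab[[slot]][i]
      if (!is.na(v) && (v < 0 || v > 1)) {
        add(issue_row("R07", i, paste0(slot, " outside [0,1]: ", .num_format(v))))
      }
    }
    # R08 similarity measure expected
    if (identical(mt, "SemanticSimilarity") &&
        blank(row_values(set, "semantic_similarity_measure", i))) {
      add(issue_row("R08", i, "SemanticSimilarity mapping without semantic_similarity_measure"))
    }
    # R09 lexical match fields expected
    if (identical(mt, "Lexical") &&
        (length(row_values(set, "subject_match_field", i)) == 0 ||
         length(row_values(set, "object_match_field", i)) == 0)) {
      add(issue_row("R09", i, "Lexical mapping without subject/object match_field"))
    }
    # R10 dates
    for (slot in .DATE_SLOTS) {
      v <- row_values(set, slot, i)
      if (length(v) == 1 && !is_iso_date(v)) {
        add(issue_row("R10", i, paste0(slot, " is not ISO-8601: ", v)))
      }
    }
    # R11 predicate modifier vocabulary
    pmv <- row_values(set, "predicate_modifier", i)
    if (length(pmv) == 1 && !pmv %in% .PREDICATE_MODIFIERS) {
      add(issue_row("R11", i, paste0("unknown predicate_modifier: ", pmv)))
    }
    # R12 preprocessing recorded but no match_field to interpret it against
    if ((length(row_values(set, "subject_preprocessing", i)) > 0 &&
         length(row_values(set, "subject_match_field", i)) == 0) ||
        (length(row_values(set, "object_preprocessing", i)) > 0 &&
         length(row_values(set, "object_match_field", i)) == 0)) {
      add(issue_row("R12", i, "preprocessing populated while match_field absent"))
    }
  }
  # R10 set-level dates
  for (slot in .DATE_SLOTS) {
    v <- set$metadata[[slot]]
    if (!blank(v) && !is_iso_date(v)) {
      add(issue_row("R10", "set", paste0(slot, " is not ISO-8601: ", v)))
    }
  }
  # R13 duplicate identical rows
  if (n > 1) {
    keys <- vapply(seq_len(n), function(i) {
      rec <- mapping_record(set, i)
      paste(names(rec), vapply(rec, function(v) paste(v, collapse = "|"), ""),
            sep = "=", collapse = "\r")
    }, "")
    dup <- which(duplicated(keys))
    for (i in dup) {
      add(issue_row("R13", i, paste0("duplicate of row ", match(keys[i], keys))))
    }
  }

  out <- if (length(issues) == 0) {
    tibble::tibble(code = character(0), severity = character(0),
                   locus = character(0), message = character(0))
  } else {
    do.call(rbind, issues)
  }
  locus_key <- suppressWarnings(as.numeric(out$locus))
  locus_key[is.na(locus_key)] <- Inf  # "set" sorts after rows within a code
  out[order(out$code, locus_key), , drop = FALSE]
}
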