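# Core in-memory model: a mapping is a named list over the 38 mapping-level
# slots; a mapping set bundles set-level metadata, a prefix map and a tibble
# of mappings (one row per mapping, multivalued slots as list-columns).

.DATE_RE <- "^\\d{4}-\\d{2}-\\d{2}$"

is_iso_date <- function(x) {
  grepl(.DATE_RE, x) & !is.na(suppressWarnings(as.Date(x, format = "%Y-%m-%d")))
}

# Normalize a date value: ISO kept as-is; an unambiguous long form such as
# "1 January 2020" is converted; anything else is rejected.
normalize_date <- function(x, slot) {
  if (is_iso_date(x)) return(x)
  for (fmt in c("%d %B %Y", "%B %d, %Y")) {
    d <- suppressWarnings(as.Date(x, format = fmt))
    if (!is.na(d)) return(format(d, "%Y-%m-%d"))
  }
  sssom_abort(paste0(slot, " is not an ISO-8601 (YYYY-MM-DD) date: ", x),
              "sssom_format_error")
}

.num_format <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, digits = 15)
}

blank <- function(x) {
  is.null(x) || length(x) == 0 || all(is.na(x)) ||
    (is.character(x) && all(x == ""))
}

#' Construct a single mapping
#'
#' Builds a validated mapping record from a named list of slot values. The
#' four required slots are `subject_id`, `predicate_id`, `object_id` and
#' `match_type`; `subject_id`, `predicate_id` and `object_id` must be
#' CURIEs. Multivalued slots (e.g. `author_id`, `match_string`) accept
#' character vectors and preserve input order.
#'
#' @param record Named list (or one mapping's worth of named arguments via
#'   `...`) of slot values.
#' @param ... Slot values given directly, e.g.
#'   `make_mapping(subject_id = "A:1", ...)`.
#' @return A named list of class `sssom_mapping` covering all 38 slots
#'   (absent slots are `NA` / empty).
#' @examples
#' m <- make_mapping(subject_id = "UBERON:0002101",
#'                   predicate_id = "skos:exactMatch",
#'                   object_id = "FMA:24875",
#'                   match_type = "HumanCurated")
#' m$predicate_id
#' @export
make_mapping <- function(record = list(), ...) {
  record <- c(record, list(...))
  unknown <- setdiff(names(record), .MAPPING_SLOTS)
  if (length(unknown) > 0) {
    sssom_abort(paste0("unknown mapping slot(s): ", paste(unknown, collapse = ", ")),
                "sssom_lookup_error")
  }
  for (req in .REQUIRED_MAPPING_SLOTS) {
    if (blank(record[[req]])) {
      sssom_abort(paste0("missing required slot: ", req),
                  "sssom_missing_required_slot", slot = req)
    }
  }
  out <- stats::setNames(vector("list", length(.MAPPING_SLOTS)), .MAPPING_SLOTS)
  for (slot in .MAPPING_SLOTS) {
    v <- record[[slot]]
    if (blank(v)) {
      out[[slot]] <- if (slot %in% .MULTIVALUED_MAPPING_SLOTS) character(0)
                     else if (slot %in% .DOUBLE_SLOTS) NA_real_
                     else NA_character_
      next
    }
    if (slot %in% .DOUBLE_SLOTS) {
      vn <- suppressWarnings(as.numeric(v))
      if (length(vn) != 1 || is.na(vn)) {
        sssom_abort(paste0(slot, " must be a number"), "sssom_format_error")
      }
      if (vn < 0 || vn > 1) {
        sssom_abort(paste0(slot, " must lie in [0,1], got ", .num_format(vn)),
                    "sssom_range_error", slot = slot)
      }
      out[[slot]] <- vn
      next
    }
    v <- as.character(v)
    if (slot %in% .MULTIVALUED_MAPPING_SLOTS) {
      out[[slot]] <- v
      next
    }
    if (length(v) != 1) {
      sssom_abort(paste0(slot, " is single-valued"), "sssom_format_error")
    }
    if (slot %in% .DATE_SLOTS) v <- normalize_date(v, slot)
    if (slot %in% c("subject_id", "predicate_id", "object_id")) assert_curie(v)
    if (slot == "match_type" && !v %in% .MATCH_TYPES) {
      sssom_abort(paste0("match_type must be one of ",
                         paste(.MATCH_TYPES, collapse = ", "), "; got ", v),
                  "sssom_format_error")
    }
    if (slot == "predicate_modifier" && !v %in% .PREDICATE_MODIFIERS) {
      sssom_abort(paste0("predicate_modifier must be 'Not', got ", v),
                  "sssom_format_error")
    }
    if (slot == "mapping_cardinality" && !v %in% .CARDINALITIES) {
      sssom_abort(paste0("mapping_cardinality must be one of ",
                         paste(.CARDINALITIES, collapse = ", ")),
                  "sssom_format_error")
    }
    out[[slot]] <- v
  }
  structure(out, class = "sssom_mapping")
}

# 0-row canonical mappings tibble with all 38 columns correctly typed.
empty_mappings <- function() {
  cols <- lapply(.MAPPING_SLOTS, function(slot) {
    if (slot %in% .MULTIVALUED_MAPPING_SLOTS) list()
    else if (slot %in% .DOUBLE_SLOTS) numeric(0)
    else character(0)
  })
  names(cols) <- .MAPPING_SLOTS
  tibble::as_tibble(cols)
}

mappings_tibble <- function(mappings) {
  if (length(mappings) == 0) return(empty_mappings())
  cols <- lapply(.MAPPING_SLOTS, function(slot) {
    if (slot %in% .MULTIVALUED_MAPPING_SLOTS) {
      lapply(mappings, `[[`, slot)
    } else if (slot %in% .DOUBLE_SLOTS) {
      vapply(mappings, function(m) as.numeric(m[[slot]]), 0)
    } else {
      vapply(mappings, function(m) as.character(m[[slot]]), "")
    }
  })
  names(cols) <- .MAPPING_SLOTS
  tibble::as_tibble(cols)
}

#' Construct a mapping set
#'
#' @param mappings A list of `sssom_mapping` objects (see [make_mapping()])
#'   or a tibble in canonical column layout.
#' @param mapping_set_id Required set identifier (IRI or CURIE string).
#' @param curie_map A prefix map ([prefix_map()]) resolving every
#'   non-builtin prefix used in the set.
#' @param ... Further set-level slots (e.g. `license`, `creator_id`,
#'   `mapping_set_version`).
#' @return An object of class `sssom_mapping_set` with elements `metadata`
#'   (named list of set-level slots), `curie_map` and `mappings` (tibble).
#' @export
mapping_set <- function(mappings = list(), mapping_set_id, curie_map = prefix_map(),
                        ...) {
  if (missing(mapping_set_id) || blank(mapping_set_id)) {
    sssom_abort("mapping_set_id is required", "sssom_missing_required_slot",
                slot = "mapping_set_id")
  }
  meta <- list(...)
  unknown <- setdiff(names(meta), setdiff(.SET_SLOTS, c("mapping_set_id", "curie_map")))
  if (length(unknown) > 0) {
    sssom_abort(paste0("unknown mapping set slot(s): ",
                       paste(unknown, collapse = ", ")), "sssom_lookup_error")
  }
  meta <- c(list(mapping_set_id = as.character(mapping_set_id)), meta)
  for (slot in .DATE_SLOTS) {
    if (!blank(meta[[slot]])) meta[[slot]] <- normalize_date(meta[[slot]], slot)
  }
  tab <- if (is.data.frame(mappings)) mappings else mappings_tibble(mappings)
  set <- structure(
    list(metadata = meta,
         curie_map = if (inherits(curie_map, "sssom_prefix_map")) curie_map
                     else prefix_map(entries = curie_map),
         mappings = tab),
    class = "sssom_mapping_set")
  check_prefixes_resolvable(set)
  set
}

# Every prefix used by an entity-reference slot must be declared or builtin.
check_prefixes_resolvable <- function(set) {
  used <- used_prefixes(set)
  missing <- setdiff(used, resolvable_prefixes(set$curie_map))
  if (length(missing) > 0) {
    sssom_abort(paste0("undeclared prefix(es): ", paste(missing, collapse = ", ")),
                "sssom_undeclared_prefix", prefix = missing)
  }
  invisible(set)
}

used_prefixes <- function(set) {
  vals <- character(0)
  for (slot in .ENTITY_REF_MAPPING_SLOTS) {
    col <- set$mappings[[slot]]
    v <- if (is.list(col)) unlist(col) else col
    vals <- c(vals, v[!is.na(v)])
  }
  unique(curie_prefix(vals[is_curie(vals)]))
}

#' Number of mappings in a set
#' @param set A `sssom_mapping_set`.
#' @return Integer row count.
#' @export
n_mappings <- function(set) nrow(set$mappings)

# Extract row i of the mappings tibble as a plain named list with absent
# slots dropped (the "populated slots" view used by converters and equality).
mapping_record <- function(set, i) {
  row <- set$mappings[i, ]
  out <- list()
  for (slot in .MAPPING_SLOTS) {
    v <- row[[slot]]
    if (is.list(v)) v <- v[[1]]
    if (!blank(v)) out[[slot]] <- v
  }
  out
}

populated_mapping_slots <- function(set) {
  .MAPPING_SLOTS[vapply(.MAPPING_SLOTS, function(slot) {
    col <- set$mappings[[slot]]
    if (is.list(col)) any(lengths(col) > 0) else any(!is.na(col))
  }, NA)]
}

populated_set_slots <- function(set) {
  names(set$metadata)[!vapply(set$metadata, blank, NA)]
}

# Canonical comparable form: metadata with blanks dropped, sorted curie_map,
# list of per-row populated-slot records.
normalize_set <- function(set) {
  meta <- set$metadata[populated_set_slots(set)]
  meta <- meta[order(names(meta))]
  pm <- unclass(set$curie_map)
  pm <- pm[order(names(pm))]
  rows <- lapply(seq_len(n_mappings(set)), function(i) mapping_record(set, i))
  list(metadata = meta, curie_map = as.list(pm), mappings = rows)
}

#' Field-level equality of two mapping sets
#'
#' Compares set metadata, prefix maps and every mapping slot value,
#' ignoring unpopulated slots and prefix-map ordering.
#'
#' @param a,b Mapping sets.
#' @return `TRUE` or `FALSE`.
#' @export
sssom_equal <- function(a, b) {
  isTRUE(all.equal(normalize_set(a), normalize_set(b), tolerance = 1e-12))
}

#' @export
print.sssom_mapping_set <- function(x, ...) {
  cat("<sssom_mapping_set> ", x$metadata$mapping_set_id, "\n", sep = "")
  cat("  mappings: ", n_mappings(x),
      " | prefixes declared: ", length(x$curie_map), "\n", sep = "")
  pop <- setdiff(populated_mapping_slots(x), .REQUIRED_MAPPING_SLOTS)
  if (length(pop) > 0) {
    cat("  optional slots populated: ", paste(pop, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
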