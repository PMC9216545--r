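# Reader/writer for the SSSOM TSV format. A document has two parts: set-level
# metadata as commented YAML (every line prefixed '#') and the mapping table
# as plain TSV whose first row names the mapping-level slots. Both the
# "embedded" mode (one file) and the "external" mode (YAML metadata in a
# separate file) are supported. There is no quoting dialect: tabs and
# newlines are illegal inside cells, which keeps the format consumable by
# completely generic TSV toolchains.

# split a line on tabs without dropping trailing empty fields
split_tsv_line <- function(line) {
  n <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))) + 1L
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  c(fields, rep("", n - length(fields)))
}

# internal constructor that, unlike mapping_set(), tolerates a missing
# mapping_set_id so the validator can report it as an issue
new_mapping_set <- function(metadata, curie_map, mappings_tab,
                            check_prefixes = TRUE) {
  set <- structure(
    list(metadata = metadata, curie_map = curie_map, mappings = mappings_tab),
    class = "sssom_mapping_set")
  if (check_prefixes) check_prefixes_resolvable(set)
  set
}

parse_header_yaml <- function(header_lines) {
  yaml_text <- paste(sub("^# ?", "", header_lines), collapse = "\n")
  meta <- tryCatch(
    yaml::yaml.load(yaml_text),
    error = function(e) sssom_abort(paste0("metadata header is not valid YAML: ",
                                           conditionMessage(e)),
                                    "sssom_header_error"))
  if (is.null(meta)) meta <- list()
  if (!is.list(meta)) {
    sssom_abort("metadata header must be a YAML mapping", "sssom_header_error")
  }
  meta
}

#' Parse SSSOM TSV text into a mapping set
#'
#' @param text Document text: embedded mode (commented-YAML header followed
#'   by the table) or just the table when `metadata` is supplied.
#' @param metadata Optional YAML text with the set-level metadata
#'   (external mode).
#' @param strict If `TRUE` (default), unknown columns and header keys are
#'   errors; if `FALSE` they are warned about, and unknown column values are
#'   preserved concatenated into the `other` slot.
#' @return A `sssom_mapping_set`.
#' @export
parse_sssom <- function(text, metadata = NULL, strict = TRUE) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  is_header <- startsWith(lines, "#")
  # '#' only marks metadata before the column header row
  n_header <- if (all(is_header)) length(lines) else which(!is_header)[1] - 1L
  header_lines <- lines[seq_len(n_header)]
  body_lines <- lines[setdiff(seq_along(lines), seq_len(n_header))]
  body_lines <- body_lines[body_lines != ""]

  if (!is.null(metadata)) {
    if (n_header > 0) {
      sssom_abort("external mode: document must not also carry an embedded header",
                  "sssom_header_error")
    }
    meta_raw <- parse_header_yaml(strsplit(metadata, "\n", fixed = TRUE)[[1]])
  } else {
    meta_raw <- parse_header_yaml(header_lines)
  }

  cm <- meta_raw[["curie_map"]]
  meta_raw[["curie_map"]] <- NULL
  pm <- if (is.null(cm)) prefix_map() else prefix_map(entries = cm)

  unknown_keys <- setdiff(names(meta_raw), .SET_SLOTS)
  if (length(unknown_keys) > 0) {
    msg <- paste0("unknown metadata key(s): ", paste(unknown_keys, collapse = ", "))
    if (strict) sssom_abort(msg, "sssom_unknown_column")
    sssom_warn(msg, "sssom_unknown_column")
    meta_raw <- meta_raw[setdiff(names(meta_raw), unknown_keys)]
  }
  meta <- lapply(meta_raw, function(v) {
    if (length(v) > 1 || is.list(v)) as.character(unlist(v)) else as.character(v)
  })

  if (length(body_lines) == 0) {
    sssom_abort("document has no column header row", "sssom_missing_required_column")
  }
  cols <- split_tsv_line(body_lines[1])
  unknown_cols <- setdiff(cols, .MAPPING_SLOTS)
  if (length(unknown_cols) > 0) {
    msg <- paste0("unknown column(s): ", paste(unknown_cols, collapse = ", "))
    if (strict) sssom_abort(msg, "sssom_unknown_column")
    sssom_warn(msg, "sssom_unknown_column")
  }
  missing_req <- setdiff(.REQUIRED_MAPPING_SLOTS, cols)
  if (length(missing_req) > 0) {
    sssom_abort(paste0("missing required column(s): ",
                       paste(missing_req, collapse = ", ")),
                "sssom_missing_required_column", column = missing_req)
  }

  rows <- lapply(seq_along(body_lines)[-1], function(i) {
    fields <- split_tsv_line(body_lines[i])
    if (length(fields) != length(cols)) {
      sssom_abort(paste0("row on line ", n_header + i, " has ", length(fields),
                         " fields, expected ", length(cols)),
                  "sssom_ragged_row", line = n_header + i)
    }
    rec <- list()
    extras <- character(0)
    for (j in seq_along(cols)) {
      val <- fields[j]
      if (val == "") next
      slot <- cols[j]
      if (slot %in% unknown_cols) {
        extras <- c(extras, paste0(slot, "=", val))
        next
      }
      rec[[slot]] <- if (slot %in% .MULTIVALUED_MAPPING_SLOTS) {
        strsplit(val, "|", fixed = TRUE)[[1]]
      } else val
    }
    if (length(extras) > 0) {
      rec$other <- paste(c(rec$other, extras), collapse = ";")
    }
    make_mapping(rec)
  })

  new_mapping_set(meta, pm, mappings_tibble(rows), check_prefixes = strict)
}

#' Read a SSSOM TSV file
#'
#' @param path Path to the TSV file.
#' @param metadata Optional path to an external YAML metadata file.
#' @param strict Passed to [parse_sssom()].
#' @return A `sssom_mapping_set`.
#' @export
read_sssom <- function(path, metadata = NULL, strict = TRUE) {
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  meta_text <- if (!is.null(metadata)) {
    paste(readLines(metadata, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  parse_sssom(text, metadata = meta_text, strict = strict)
}

serialize_cell <- function(v, multivalued) {
  if (is.numeric(v)) {
    if (is.na(v)) return("")
    return(.num_format(v))
  }
  v <- v[!is.na(v)]
  if (length(v) == 0) return("")
  if (any(grepl("[\t\n]", v)) || any(startsWith(v, "#"))) {
    sssom_abort("cell values may not contain tabs or newlines or start with '#'",
                "sssom_serialization_error")
  }
  if (multivalued) {
    if (any(grepl("|", v, fixed = TRUE))) {
      sssom_abort("multivalued cell values may not contain the '|' delimiter",
                  "sssom_serialization_error")
    }
    paste(v, collapse = "|")
  } else {
    v
  }
}

header_yaml_text <- function(set) {
  meta <- set$metadata[populated_set_slots(set)]
  if (length(set$curie_map) > 0) {
    pm <- unclass(set$curie_map)
    meta$curie_map <- as.list(pm[order(names(pm))])
  }
  meta <- meta[order(names(meta))]
  if (length(meta) == 0) return("")
  meta <- lapply(meta, function(v) if (length(v) > 1) as.list(v) else v)
  yaml::as.yaml(meta, indent = 2, line.sep = "\n")
}

table_tsv_text <- function(set) {
  cols <- union(.REQUIRED_MAPPING_SLOTS, populated_mapping_slots(set))
  cols <- .MAPPING_SLOTS[.MAPPING_SLOTS %in% cols]  # registry order
  lines <- paste(cols, collapse = "\t")
  for (i in seq_len(n_mappings(set))) {
    cells <- vapply(cols, function(slot) {
      v <- set$mappings[[slot]][i]
      if (is.list(v)) v <- v[[1]]
      serialize_cell(v, slot %in% .MULTIVALUED_MAPPING_SLOTS)
    }, "")
    lines <- c(lines, paste(cells, collapse = "\t"))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Serialize a mapping set to SSSOM TSV text
#'
#' Output is canonical and deterministic: header keys sorted alphabetically,
#' columns in registry declaration order restricted to populated slots plus
#' the four required ones, multivalues joined with `|`. The same set always
#' yields identical bytes.
#'
#' @param set A `sssom_mapping_set`.
#' @return A single string, the embedded-mode document.
#' @export
format_sssom <- function(set) {
  hdr <- header_yaml_text(set)
  hdr_lines <- if (hdr == "") character(0) else
    paste0("#", strsplit(hdr, "\n", fixed = TRUE)[[1]])
  body <- table_tsv_text(set)
  if (length(hdr_lines) == 0) body
  else paste0(paste(hdr_lines, collapse = "\n"), "\n", body)
}

#' Write a mapping set to disk
#'
#' @param set A `sssom_mapping_set`.
#' @param path Output TSV path.
#' @param mode `"embedded"` (default; one self-contained file) or
#'   `"external"` (metadata written separately to `metadata_path`).
#' @param metadata_path YAML path for external mode.
#' @return `path`, invisibly.
#' @export
write_sssom <- function(set, path, mode = c("embedded", "external"),
                        metadata_path = NULL) {
  mode <- match.arg(mode)
  if (mode == "embedded") {
    cat(format_sssom(set), file = path)
  } else {
    if (is.null(metadata_path)) {
      sssom_abort("external mode requires metadata_path", "sssom_usage_error")
    }
    parts <- externalize_sssom(set)
    cat(parts$metadata, file = metadata_path)
    cat(parts$table, file = path)
  }
  invisible(path)
}

#' Split a mapping set into external-mode parts
#'
#' @param set A `sssom_mapping_set`.
#' @return List with `metadata` (YAML text, uncommented) and `table`
#'   (TSV text). `embed_sssom()` reassembles an embedded document from the
#'   two parts; the round trip is lossless.
#' @export
externalize_sssom <- function(set) {
  list(metadata = header_yaml_text(set), table = table_tsv_text(set))
}

#' Reassemble an embedded document from external-mode parts
#'
#' @param metadata YAML metadata text (uncommented).
#' @param table TSV table text.
#' @return Embedded-mode document text.
#' @export
embed_sssom <- function(metadata, table) {
  if (metadata == "") return(table)
  hdr_lines <- paste0("#", strsplit(metadata, "\n", fixed = TRUE)[[1]])
  paste0(paste(hdr_lines, collapse = "\n"), "\n", table)
}
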