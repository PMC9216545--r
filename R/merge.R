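# Set algebra over mapping sets: merging, deduplication, rule collapsing,
# cardinality annotation, unique-object reconciliation (the harmonization
# discipline in which no external term may map to more than one target term)
# and conflict detection.

row_key_full <- function(set, i) {
  rec <- mapping_record(set, i)
  paste(names(rec),
        vapply(rec, function(v) paste(v, collapse = "\x1f"), ""),
        sep = "=", collapse = "\x1e")
}

row_key_spmo <- function(set, i = seq_len(n_mappings(set))) {
  mod <- set$mappings$predicate_modifier[i]
  mod[is.na(mod)] <- ""
  paste(set$mappings$subject_id[i], set$mappings$predicate_id[i], mod,
        set$mappings$object_id[i], sep = "\x1e")
}

#' Merge mapping sets
#'
#' Concatenates mappings in input order, merges the prefix maps (clashing
#' declarations are an error), assigns a new set identifier and records the
#' source set identifiers in `see_also`.
#'
#' @param sets A list of `sssom_mapping_set` objects (at least one).
#' @param new_id Identifier for the merged set.
#' @return The merged `sssom_mapping_set`.
#' @export
sssom_merge <- function(sets, new_id) {
  if (length(sets) < 1) sssom_abort("need at least one set", "sssom_usage_error")
  pm <- do.call(merge_prefix_maps, lapply(sets, `[[`, "curie_map"))
  tab <- do.call(rbind, lapply(sets, `[[`, "mappings"))
  src <- unlist(lapply(sets, function(s) s$metadata$mapping_set_id))
  meta <- list(mapping_set_id = as.character(new_id),
               see_also = unique(src[!is.na(src)]))
  new_mapping_set(meta, pm, tab)
}

#' Remove exact duplicate mappings
#'
#' Rows identical on every populated slot collapse to one (the first
#' occurrence). Rows sharing subject, predicate and object but differing in
#' match metadata are distinct mapping rules and are all retained.
#'
#' @param set A `sssom_mapping_set`.
#' @return The deduplicated set.
#' @export
sssom_dedup <- function(set) {
  n <- n_mappings(set)
  if (n == 0) return(set)
  keys <- vapply(seq_len(n), function(i) row_key_full(set, i), "")
  set$mappings <- set$mappings[!duplicated(keys), , drop = FALSE]
  set
}

union_preserve <- function(values) {
  out <- unlist(values)
  out[!duplicated(out)]
}

#' Collapse mapping rules into single mappings
#'
#' The inverse of the one-row-per-mapping-rule convention: rows sharing
#' (subject, predicate, modifier, object) merge into one row whose
#' confidence is the maximum over the rules, whose match_type is kept when
#' unanimous and set to `Complex` otherwise, and whose match_field,
#' match_string and preprocessing values are unioned (first-seen order).
#'
#' @param set A `sssom_mapping_set`.
#' @return The collapsed set, one row per (s, p, modifier, o).
#' @export
collapse_rules <- function(set) {
  n <- n_mappings(set)
  if (n == 0) return(set)
  keys <- row_key_spmo(set)
  groups <- split(seq_len(n), factor(keys, levels = unique(keys)))
  union_slots <- c("subject_match_field", "object_match_field", "match_string",
                   "subject_preprocessing", "object_preprocessing")
  rows <- lapply(groups, function(idx) {
    rec <- mapping_record(set, idx[1])
    if (length(idx) > 1) {
      conf <- set$mappings$confidence[idx]
      rec$confidence <- if (all(is.na(conf))) NULL else max(conf, na.rm = TRUE)
      mts <- unique(set$mappings$match_type[idx])
      rec$match_type <- if (length(mts) == 1) mts else "Complex"
      for (slot in union_slots) {
        vals <- union_preserve(set$mappings[[slot]][idx])
        if (length(vals) > 0) rec[[slot]] <- vals else rec[[slot]] <- NULL
      }
    }
    make_mapping(rec)
  })
  set$mappings <- mappings_tibble(unname(rows))
  set
}

#' Annotate mapping cardinality
#'
#' Over the non-negated rows, counts for each subject the distinct objects
#' it maps to and for each object the distinct subjects mapping to it, and
#' stamps every such row with `1:1`, `1:n`, `n:1` or `n:n`. Negated rows do
#' not assert a correspondence: they get no cardinality and do not enter
#' the counts.
#'
#' @param set A `sssom_mapping_set`.
#' @param by_strength If `TRUE`, counts are computed separately within each
#'   predicate strength class instead of across all predicates.
#' @return The set with `mapping_cardinality` populated.
#' @export
compute_cardinality <- function(set, by_strength = FALSE) {
  tab <- set$mappings
  active <- which(is.na(tab$predicate_modifier))
  card <- rep(NA_character_, nrow(tab))
  if (length(active) > 0) {
    strata <- if (by_strength) {
      vapply(tab$predicate_id[active], predicate_class, "")
    } else rep("all", length(active))
    for (g in unique(strata)) {
      idx <- active[strata == g]
      s <- tab$subject_id[idx]
      o <- tab$object_id[idx]
      o_per_s <- tapply(o, s, function(x) length(unique(x)))
      s_per_o <- tapply(s, o, function(x) length(unique(x)))
      many_o <- o_per_s[s] > 1
      many_s <- s_per_o[o] > 1
      card[idx] <- ifelse(many_o,
                          ifelse(many_s, "n:n", "1:n"),
                          ifelse(many_s, "n:1", "1:1"))
    }
  }
  set$mappings$mapping_cardinality <- card
  set
}

.MATCH_TYPE_RANK <- c(HumanCurated = 5, Logical = 4, Lexical = 3,
                      SemanticSimilarity = 2, Complex = 1)

#' Reconcile a set under the unique-object constraint
#'
#' Enforces the harmonization rule that no single external term maps to more
#' than one target term: among non-negated EXACT-class rows, each
#' `object_id` is retained in at most one row. When several subjects compete
#' for the same object, the winner is chosen by (1) higher confidence
#' (absent confidence ranks below any value), (2) match-type rank
#' (HumanCurated > Logical > Lexical > SemanticSimilarity > Complex),
#' (3) lexicographically smallest `subject_id`. Losing rows are not
#' silently dropped: they are emitted in the rejected set with
#' `predicate_modifier` set to `Not` and a comment recording the reason, so
#' that rejection is explicit. Non-EXACT and negated rows pass through the
#' accepted set untouched.
#'
#' @param set A `sssom_mapping_set`, ideally already passed through
#'   [collapse_rules()] so there is one row per (s, p, modifier, o).
#' @return A list with elements `accepted` and `rejected` (both mapping
#'   sets).
#' @export
reconcile_unique_object <- function(set) {
  tab <- set$mappings
  n <- nrow(tab)
  strength <- vapply(tab$predicate_id, predicate_class, "")
  exact <- which(strength == "EXACT" & is.na(tab$predicate_modifier))
  reject <- integer(0)
  if (length(exact) > 1) {
    for (obj in unique(tab$object_id[exact])) {
      cand <- exact[tab$object_id[exact] == obj]
      if (length(cand) < 2) next
      conf <- tab$confidence[cand]
      conf[is.na(conf)] <- -Inf
      rank <- .MATCH_TYPE_RANK[tab$match_type[cand]]
      ord <- order(-conf, -rank, tab$subject_id[cand], method = "radix")
      reject <- c(reject, cand[ord[-1]])
    }
  }
  accepted <- set
  accepted$mappings <- tab[setdiff(seq_len(n), reject), , drop = FALSE]
  rejected <- set
  rej_tab <- tab[sort(reject), , drop = FALSE]
  if (nrow(rej_tab) > 0) {
    rej_tab$predicate_modifier <- "Not"
    rej_tab$comment <- ifelse(
      is.na(rej_tab$comment) | rej_tab$comment == "",
      "rejected by unique-object reconciliation: object retained under another subject",
      paste0(rej_tab$comment,
             "; rejected by unique-object reconciliation"))
  }
  rejected$mappings <- rej_tab
  list(accepted = accepted, rejected = rejected)
}

#' Detect negation and strength conflicts
#'
#' Scans for subject/object pairs that are asserted both positively and
#' negatively under the same predicate strength (`NEGATION_CLASH`), and
#' pairs mapped under EXACT as well as under a weaker class (BROAD, NARROW
#' or RELATED; `STRENGTH_CLASH`).
#'
#' @param set A `sssom_mapping_set`.
#' @return A tibble (`kind`, `subject_id`, `object_id`, `rows`) sorted by
#'   pair; `rows` is a list-column of the involved row indices.
#' @export
detect_conflicts <- function(set) {
  tab <- set$mappings
  n <- nrow(tab)
  strength <- if (n > 0) vapply(tab$predicate_id, predicate_class, "") else character(0)
  pair <- paste(tab$subject_id, tab$object_id, sep = "\x1e")
  out <- list()
  for (p in sort(unique(pair), method = "radix")) {
    idx <- which(pair == p)
    neg <- !is.na(tab$predicate_modifier[idx])
    # same strength class asserted and negated
    for (g in unique(strength[idx])) {
      gi <- idx[strength[idx] == g]
      if (any(!is.na(tab$predicate_modifier[gi])) &&
          any(is.na(tab$predicate_modifier[gi]))) {
        out[[length(out) + 1]] <- tibble::tibble(
          kind = "NEGATION_CLASH",
          subject_id = tab$subject_id[gi[1]], object_id = tab$object_id[gi[1]],
          rows = list(gi))
        break
      }
    }
    pos <- idx[!neg]
    if (any(strength[pos] == "EXACT") &&
        any(strength[pos] %in% c("BROAD", "NARROW", "RELATED"))) {
      out[[length(out) + 1]] <- tibble::tibble(
        kind = "STRENGTH_CLASH",
        subject_id = tab$subject_id[pos[1]], object_id = tab$object_id[pos[1]],
        rows = list(pos))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(kind = character(0), subject_id = character(0),
                          object_id = character(0), rows = list()))
  }
  do.call(rbind, out)
}
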