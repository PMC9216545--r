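# Deterministic exports: JSON, and RDF as a triple set serialized to sorted
# N-Triples. Three RDF profiles are provided: "direct" (one plain triple per
# asserted mapping), "reified" (one owl:Axiom annotation node per row,
# carrying all metadata) and "owl" (reified plus the entity declarations
# required for OWL conformance).

new_triple_set <- function(subject = character(0), predicate = character(0),
                           object = character(0), object_kind = character(0)) {
  ts <- tibble::tibble(subject = subject, predicate = predicate,
                       object = object, object_kind = object_kind)
  ts <- unique(ts)
  structure(ts[order(ts$subject, ts$predicate, ts$object, ts$object_kind,
                     method = "radix"), , drop = FALSE],
            class = c("sssom_triple_set", class(ts)))
}

n_triples <- function(ts) nrow(ts)

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

render_node <- function(x, kind) {
  if (kind == "literal") paste0("\"", escape_literal(x), "\"")
  else if (startsWith(x, "_:")) x
  else paste0("<", x, ">")
}

#' Serialize a triple set to N-Triples text
#'
#' Lines are unique and byte-sorted, so identical triple sets always produce
#' identical output.
#'
#' @param ts A triple set as returned by the `sssom_to_rdf_*` converters.
#' @return A single string of N-Triples (one statement per line).
#' @export
format_ntriples <- function(ts) {
  if (nrow(ts) == 0) return("")
  lines <- vapply(seq_len(nrow(ts)), function(i) {
    paste(render_node(ts$subject[i], "iri"),
          render_node(ts$predicate[i], "iri"),
          render_node(ts$object[i], ts$object_kind[i]), ".")
  }, "")
  paste0(paste(sort(unique(lines), method = "radix"), collapse = "\n"), "\n")
}

#' Write a triple set to an N-Triples file
#' @param ts A triple set.
#' @param path Output path (conventionally `.nt`).
#' @return `path`, invisibly.
#' @export
write_ntriples <- function(ts, path) {
  cat(format_ntriples(ts), file = path)
  invisible(path)
}

expand_meta_property <- function(curie) {
  pfx <- curie_prefix(curie)
  base <- if (pfx %in% names(.METADATA_PREFIXES)) .METADATA_PREFIXES[[pfx]]
          else lookup_base(pfx, prefix_map())
  paste0(base, curie_local(curie))
}

.rdf_type <- function() paste0(.BUILTIN_PREFIXES[["rdf"]], "type")

#' Convert a mapping set to JSON
#'
#' One JSON object carrying every populated set-level slot, a `curie_map`
#' object and a `mappings` array of per-row objects. Multivalued slots are
#' arrays; keys are alphabetical; output is deterministic.
#'
#' @param set A `sssom_mapping_set`.
#' @return JSON text (a `json` string from \pkg{jsonlite}).
#' @export
sssom_to_json <- function(set) {
  obj <- set$metadata[populated_set_slots(set)]
  obj <- lapply(obj, function(v) if (length(v) > 1) I(v) else v)
  pm <- unclass(set$curie_map)
  obj$curie_map <- as.list(pm[order(names(pm))])
  obj$mappings <- lapply(seq_len(n_mappings(set)), function(i) {
    rec <- mapping_record(set, i)
    rec <- lapply(rec, function(v) if (length(v) > 1) I(v) else v)
    mv <- names(rec) %in% .MULTIVALUED_MAPPING_SLOTS
    rec[mv] <- lapply(rec[mv], I)  # multivalued slots stay arrays even when length 1
    rec[order(names(rec))]
  })
  obj <- obj[order(names(obj))]
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Convert a mapping set to direct RDF triples
#'
#' One triple `subject predicate object` (all IRIs, expanded through the
#' set's prefix map) per asserted mapping. Rows whose `predicate_modifier`
#' is `Not` are omitted: a rejected mapping cannot be stated as a plain
#' triple without inverting its meaning. Duplicate triples collapse.
#'
#' @param set A `sssom_mapping_set`.
#' @return A triple set.
#' @export
sssom_to_rdf_direct <- function(set) {
  keep <- which(is.na(set$mappings$predicate_modifier))
  s <- vapply(set$mappings$subject_id[keep], curie_expand, "", pm = set$curie_map)
  p <- vapply(set$mappings$predicate_id[keep], curie_expand, "", pm = set$curie_map)
  o <- vapply(set$mappings$object_id[keep], curie_expand, "", pm = set$curie_map)
  new_triple_set(unname(s), unname(p), unname(o),
                 rep("iri", length(keep)))
}

reified_row_triples <- function(set, i, node) {
  pm <- set$curie_map
  owl <- .BUILTIN_PREFIXES[["owl"]]
  subj <- rep(node, 4)
  pred <- c(.rdf_type(), paste0(owl, c("annotatedSource", "annotatedProperty",
                                     "annotatedTarget")))
  obj <- c(paste0(owl, "Axiom"),
           curie_expand(set$mappings$subject_id[i], pm),
           curie_expand(set$mappings$predicate_id[i], pm),
           curie_expand(set$mappings$object_id[i], pm))
  kind <- rep("iri", 4)
  rec <- mapping_record(set, i)
  for (slot in setdiff(names(rec), c("subject_id", "predicate_id", "object_id"))) {
    ext <- external_property_for(slot)
    prop <- if (is.na(ext)) paste0(.BUILTIN_PREFIXES[["sssom"]], slot)
            else expand_meta_property(ext)
    vals <- rec[[slot]]
    for (v in vals) {
      subj <- c(subj, node)
      pred <- c(pred, prop)
      if (slot %in% .ENTITY_REF_MAPPING_SLOTS && is_curie(as.character(v)) &&
          curie_prefix(as.character(v)) %in% resolvable_prefixes(pm)) {
        obj <- c(obj, curie_expand(as.character(v), pm))
        kind <- c(kind, "iri")
      } else {
        obj <- c(obj, if (is.numeric(v)) .num_format(v) else as.character(v))
        kind <- c(kind, "literal")
      }
    }
  }
  list(subject = subj, predicate = pred, object = obj, object_kind = kind)
}

#' Convert a mapping set to reified RDF
#'
#' Each row becomes a fresh annotation node typed `owl:Axiom`, linked to the
#' mapped subject, predicate and object via `owl:annotatedSource/Property/
#' Target`, with one further triple per populated metadata value. Externally
#' mapped slots use their external property (e.g. `mapping_date` via
#' `pav:authoredOn`); SSSOM-native slots use the `https://w3id.org/sssom/`
#' namespace. Negated rows are included, with the modifier stated as
#' `sssom:predicate_modifier "Not"`.
#'
#' @param set A `sssom_mapping_set`.
#' @return A triple set.
#' @export
sssom_to_rdf_reified <- function(set) {
  n <- n_mappings(set)
  parts <- lapply(seq_len(n), function(i) {
    reified_row_triples(set, i, sprintf("_:m%06d", i))
  })
  new_triple_set(
    unlist(lapply(parts, `[[`, "subject")) %||% character(0),
    unlist(lapply(parts, `[[`, "predicate")) %||% character(0),
    unlist(lapply(parts, `[[`, "object")) %||% character(0),
    unlist(lapply(parts, `[[`, "object_kind")) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.KIND_CLASS <- c(class = "Class", individual = "NamedIndividual",
                 property = "ObjectProperty")

#' Convert a mapping set to OWL-conformant RDF
#'
#' The reified output plus one declaration triple per distinct mapped
#' entity: `owl:Class` for class-level predicates (`owl:equivalentClass`,
#' `rdfs:subClassOf` and, by default, the SKOS match predicates),
#' `owl:NamedIndividual` for `owl:sameAs`, `owl:ObjectProperty` for
#' `owl:equivalentProperty` / `rdfs:subPropertyOf`. An entity mapped under
#' predicates of different kinds is an error.
#'
#' @param set A `sssom_mapping_set`.
#' @param default_kind Entity kind assumed for predicates outside the
#'   recommended set (`"class"`, `"individual"` or `"property"`).
#' @return A triple set.
#' @export
sssom_to_owl <- function(set, default_kind = "class") {
  reified <- sssom_to_rdf_reified(set)
  kinds <- list()
  for (i in seq_len(n_mappings(set))) {
    pid <- set$mappings$predicate_id[i]
    j <- match(pid, .PREDICATE_TABLE$predicate_id)
    kind <- if (is.na(j)) default_kind else .PREDICATE_TABLE$entity_kind[j]
    for (ent in c(set$mappings$subject_id[i], set$mappings$object_id[i])) {
      kinds[[ent]] <- union(kinds[[ent]], kind)
    }
  }
  clash <- names(kinds)[lengths(kinds) > 1]
  if (length(clash) > 0) {
    sssom_abort(paste0("entity mapped under predicates of conflicting kinds: ",
                       paste(clash, collapse = ", ")),
                "sssom_kind_conflict", entity = clash)
  }
  ents <- names(kinds)
  decl <- new_triple_set(
    vapply(ents, curie_expand, "", pm = set$curie_map, USE.NAMES = FALSE),
    rep(.rdf_type(), length(ents)),
    paste0(.BUILTIN_PREFIXES[["owl"]],
           .KIND_CLASS[vapply(kinds, `[[`, "", 1)]),
    rep("iri", length(ents)))
  new_triple_set(c(reified$subject, decl$subject),
                 c(reified$predicate, decl$predicate),
                 c(reified$object, decl$object),
                 c(reified$object_kind, decl$object_kind))
}
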