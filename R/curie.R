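# Prefix-map management and CURIE <-> IRI conversion. A prefix map is a named
# character vector: names are prefixes, values are absolute IRI bases.

# Prefixes that always resolve, so the recommended predicates and SSSOM-native
# properties parse without any declaration.
.BUILTIN_PREFIXES <- c(
  owl  = "http://www.w3.org/2002/07/owl#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  skos = "http://www.w3.org/2004/02/skos/core#",
  sssom = "https://w3id.org/sssom/"
)

# Metadata-property namespaces used only by the RDF converters.
.METADATA_PREFIXES <- c(
  pav = "http://purl.org/pav/",
  prov = "http://www.w3.org/ns/prov#",
  dcterms = "http://purl.org/dc/terms/"
)

.PREFIX_RE <- "^[A-Za-z_][A-Za-z0-9_.]*$"

#' Builtin prefix map
#'
#' Prefixes (`owl`, `rdfs`, `rdf`, `skos`, `sssom`) that are always
#' resolvable without declaration in a set's `curie_map`.
#'
#' @return Named character vector mapping prefix to IRI base.
#' @export
builtin_prefixes <- function() .BUILTIN_PREFIXES

is_curie <- function(x) {
  is.character(x) & !is.na(x) & grepl("^[^:[:space:]]+:[^[:space:]]+$", x) &
    !grepl("[[:space:]]", x)
}

assert_curie <- function(x) {
  if (length(x) != 1 || !is_curie(x)) {
    sssom_abort(paste0("not a well-formed CURIE: ", paste(x, collapse = ", ")),
                "sssom_format_error")
  }
  invisible(x)
}

curie_prefix <- function(curie) sub(":.*$", "", curie)
curie_local <- function(curie) sub("^[^:]*:", "", curie)

#' Construct a prefix map
#'
#' @param ... Named IRI bases, e.g. `UBERON = "http://purl.obolibrary.org/obo/UBERON_"`.
#' @param entries Alternatively, a named character vector or named list.
#' @return A validated named character vector (class `sssom_prefix_map`).
#' @export
prefix_map <- function(..., entries = NULL) {
  pm <- if (!is.null(entries)) unlist(entries) else c(...)
  if (length(pm) == 0) {
    pm <- character(0)
  }
  pm <- vapply(pm, as.character, "")
  if (length(pm) > 0) {
    if (is.null(names(pm)) || any(names(pm) == "")) {
      sssom_abort("all prefix map entries must be named", "sssom_usage_error")
    }
    bad <- names(pm)[!grepl(.PREFIX_RE, names(pm))]
    if (length(bad) > 0) {
      sssom_abort(paste0("invalid prefix(es): ", paste(bad, collapse = ", ")),
                  "sssom_format_error")
    }
    if (anyDuplicated(names(pm))) {
      dup <- unique(names(pm)[duplicated(names(pm))])
      clash <- vapply(dup, function(p) length(unique(pm[names(pm) == p])) > 1, NA)
      if (any(clash)) {
        sssom_abort(paste0("prefix bound to different bases: ",
                           paste(dup[clash], collapse = ", ")),
                    "sssom_prefix_clash", prefix = dup[clash])
      }
      pm <- pm[!duplicated(names(pm))]
    }
    if (anyDuplicated(pm)) {
      sssom_warn("multiple prefixes share an identical IRI base",
                 "sssom_duplicate_base")
    }
  }
  structure(pm, class = "sssom_prefix_map")
}

resolvable_prefixes <- function(pm) {
  c(names(.BUILTIN_PREFIXES), names(pm))
}

lookup_base <- function(prefix, pm) {
  if (prefix %in% names(pm)) {
    unname(pm[[prefix]])
  } else if (prefix %in% names(.BUILTIN_PREFIXES)) {
    unname(.BUILTIN_PREFIXES[[prefix]])
  } else {
    NA_character_
  }
}

#' Expand a CURIE to an IRI
#'
#' @param curie A CURIE string, `prefix:local`.
#' @param pm A prefix map; builtin prefixes are always consulted as fallback.
#' @return The IRI string `base + local`.
#' @examples
#' pm <- prefix_map(UBERON = "http://purl.obolibrary.org/obo/UBERON_")
#' curie_expand("UBERON:0002101", pm)
#' @export
curie_expand <- function(curie, pm = prefix_map()) {
  assert_curie(curie)
  base <- lookup_base(curie_prefix(curie), pm)
  if (is.na(base)) {
    sssom_abort(paste0("undeclared prefix: ", curie_prefix(curie)),
                "sssom_undeclared_prefix", prefix = curie_prefix(curie))
  }
  paste0(base, curie_local(curie))
}

#' Contract an IRI to a CURIE
#'
#' The longest declared base that prefixes the IRI wins; ties on base length
#' are broken by the lexicographically smallest prefix.
#'
#' @param iri An absolute IRI string.
#' @param pm A prefix map; builtins included.
#' @return The CURIE string.
#' @export
curie_contract <- function(iri, pm = prefix_map()) {
  all_pm <- c(.BUILTIN_PREFIXES, unclass(pm))
  hit <- vapply(all_pm, function(b) startsWith(iri, b), NA)
  if (!any(hit)) {
    sssom_abort(paste0("no declared base matches IRI: ", iri),
                "sssom_no_matching_prefix")
  }
  cand <- all_pm[hit]
  ord <- order(-nchar(cand), names(cand))
  best <- ord[1]
  paste0(names(cand)[best], ":", substring(iri, nchar(cand[[best]]) + 1))
}

#' Merge prefix maps
#'
#' Union of declarations; identical duplicates collapse, the same prefix
#' bound to different bases is an error.
#'
#' @param ... Prefix maps (named character vectors).
#' @return The merged prefix map.
#' @export
merge_prefix_maps <- function(...) {
  maps <- list(...)
  all <- unlist(lapply(maps, unclass))
  if (is.null(all)) all <- character(0)
  suppressWarnings(prefix_map(entries = all))
}
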