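# Predicate-aware cross-walking ("hopping"): derive indirect correspondences
# by chaining mappings through intermediate terms. Every hop composes
# strength classes through an explicit composition algebra, so a chain is
# only reported when the predicate semantics license it.

.STRENGTH_RANK <- c(EXACT = 4, CLOSE = 3, RELATED = 2, BROAD = 1, NARROW = 1)

compose2 <- function(a, b) {
  if (a == "EXACT") return(b)
  if (b == "EXACT") return(a)
  if (a == "BROAD" && b == "BROAD") return("BROAD")
  if (a == "NARROW" && b == "NARROW") return("NARROW")
  if (a == "CLOSE" && b == "CLOSE") return("RELATED")
  NA_character_
}

#' Compose a chain of strength classes
#'
#' Left fold of the composition algebra: `EXACT` is the identity; `BROAD`
#' and `NARROW` compose with themselves; `CLOSE` followed by `CLOSE`
#' degrades to `RELATED` (close matches are not transitive); every other
#' combination is undefined and the whole chain is rejected.
#'
#' @param strengths Non-empty character vector of strength classes along a
#'   path.
#' @return The derived strength class, or `NA_character_` when undefined.
#' @examples
#' compose_strengths(c("EXACT", "EXACT"))   # "EXACT"
#' compose_strengths(c("BROAD", "NARROW"))  # NA
#' @export
compose_strengths <- function(strengths) {
  if (length(strengths) == 0) {
    sssom_abort("cannot compose an empty path", "sssom_usage_error")
  }
  if (!all(strengths %in% .STRENGTHS)) {
    sssom_abort("unknown strength class in path", "sssom_usage_error")
  }
  acc <- strengths[1]
  for (s in strengths[-1]) {
    if (is.na(acc)) return(NA_character_)
    acc <- compose2(acc, s)
  }
  acc
}

#' Build a mapping graph for cross-walking
#'
#' Nodes are entity CURIEs; each non-negated row whose predicate has a known
#' strength class contributes one undirected edge. Traversing an edge
#' against the mapping's direction uses the inverse strength (a `BROAD`
#' mapping read backwards is `NARROW`). Rows below the confidence threshold
#' (rows without confidence pass), rows with an unregistered predicate and
#' rows touching an obsolete term are excluded.
#'
#' @param set A `sssom_mapping_set`.
#' @param min_confidence Minimum confidence in `[0, 1]`; default 0.
#' @param obsolete Character vector of obsolete term CURIEs to exclude.
#' @return An object of class `sssom_mapping_graph`.
#' @export
build_mapping_graph <- function(set, min_confidence = 0, obsolete = character(0)) {
  if (min_confidence < 0 || min_confidence > 1) {
    sssom_abort("min_confidence must lie in [0,1]", "sssom_usage_error")
  }
  tab <- set$mappings
  strength <- if (nrow(tab) > 0) {
    vapply(tab$predicate_id, predicate_class, "")
  } else character(0)
  keep <- is.na(tab$predicate_modifier) &
    strength != "UNKNOWN" &
    (is.na(tab$confidence) | tab$confidence >= min_confidence) &
    !(tab$subject_id %in% obsolete) & !(tab$object_id %in% obsolete)
  edges <- tibble::tibble(
    from = tab$subject_id[keep],
    to = tab$object_id[keep],
    strength = strength[keep],
    confidence = tab$confidence[keep],
    row = which(keep))
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$from, edges$to)), method = "radix")),
            class = "sssom_mapping_graph")
}

# adjacency: for each node, outgoing (neighbor, strength) pairs in both
# edge directions, inverse strength when traversed object -> subject
graph_adjacency <- function(graph) {
  e <- graph$edges
  inv <- vapply(e$strength, strength_inverse, "")
  adj <- tibble::tibble(
    from = c(e$from, e$to),
    to = c(e$to, e$from),
    strength = c(e$strength, unname(inv)))
  unique(adj)
}

#' Entities reachable by cross-walking
#'
#' Enumerates simple paths (no node revisited) of length at most
#' `max_distance` from `start` whose composed strength is defined. Each
#' reachable entity is reported once, at its minimum distance; among the
#' minimal-distance paths the strongest derived strength wins
#' (EXACT > CLOSE > RELATED > BROAD = NARROW), with ties broken by the
#' lexicographically first path. The start entity itself is never reported.
#'
#' @param graph A `sssom_mapping_graph`.
#' @param start Start entity CURIE. If absent from the graph the result is
#'   empty.
#' @param max_distance Maximum number of hops (>= 1).
#' @param min_strength Optional strength class; only entities whose derived
#'   strength ranks at least this high are reported.
#' @return A tibble (`entity`, `strength`, `distance`, `path`) sorted by
#'   distance then entity; `path` is the witness path as
#'   `"A -> B -> C"`.
#' @export
sssom_neighbors <- function(graph, start, max_distance, min_strength = NULL) {
  if (max_distance < 1) {
    sssom_abort("max_distance must be >= 1", "sssom_usage_error")
  }
  if (!is.null(min_strength) && !min_strength %in% .STRENGTHS) {
    sssom_abort("unknown min_strength", "sssom_usage_error")
  }
  empty <- tibble::tibble(entity = character(0), strength = character(0),
                          distance = integer(0), path = character(0))
  if (!start %in% graph$nodes) return(empty)
  adj <- graph_adjacency(graph)

  # DFS over simple paths, pruning as soon as composition is undefined
  hits <- list()
  walk <- function(node, visited, strength_acc, dist) {
    out <- adj[adj$from == node, , drop = FALSE]
    if (nrow(out) == 0) return()
    ord <- order(out$to, out$strength, method = "radix")
    for (k in ord) {
      nxt <- out$to[k]
      if (nxt %in% visited) next
      s <- if (is.null(strength_acc)) out$strength[k]
           else compose2(strength_acc, out$strength[k])
      if (is.na(s)) next
      hits[[length(hits) + 1]] <<- list(entity = nxt, strength = s,
                                        distance = dist,
                                        path = c(visited, nxt))
      if (dist < max_distance) walk(nxt, c(visited, nxt), s, dist + 1L)
    }
  }
  walk(start, start, NULL, 1L)
  if (length(hits) == 0) return(empty)

  # equal-rank ties: lexicographically first path wins; identical paths can
  # still differ in strength via parallel edges, then the smaller name wins
  tie_key <- function(h) paste(c(h$path, h$strength), collapse = "\x1e")
  best <- list()
  for (h in hits) {
    cur <- best[[h$entity]]
    replace <- is.null(cur) ||
      h$distance < cur$distance ||
      (h$distance == cur$distance &&
         (.STRENGTH_RANK[h$strength] > .STRENGTH_RANK[cur$strength] ||
            (.STRENGTH_RANK[h$strength] == .STRENGTH_RANK[cur$strength] &&
               tie_key(h) < tie_key(cur))))
    if (replace) best[[h$entity]] <- h
  }
  out <- tibble::tibble(
    entity = unname(vapply(best, `[[`, "", "entity")),
    strength = unname(vapply(best, `[[`, "", "strength")),
    distance = unname(vapply(best, function(h) as.integer(h$distance), 0L)),
    path = unname(vapply(best, function(h) paste(h$path, collapse = " -> "), "")))
  if (!is.null(min_strength)) {
    out <- out[.STRENGTH_RANK[out$strength] >= .STRENGTH_RANK[[min_strength]], ,
               drop = FALSE]
  }
  out <- out[order(out$distance, out$entity, method = "radix"), , drop = FALSE]
  tibble::as_tibble(out)
}
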