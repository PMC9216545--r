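# Fixture builders and independent oracles. Everything here is generated in
# code; the oracles deliberately re-derive results by brute force, separate
# from the implementation paths they check.

test_pm <- function() {
  prefix_map(
    A = "https://example.org/a/",
    B = "https://example.org/b/",
    X = "https://example.org/x/",
    UBERON = "http://purl.obolibrary.org/obo/UBERON_",
    FMA = "http://purl.obolibrary.org/obo/FMA_",
    orcid = "https://orcid.org/",
    oboInOwl = "http://www.geneontology.org/formats/oboInOwl#"
  )
}

simple_mapping <- function(s = "A:1", p = "skos:exactMatch", o = "X:1",
                           mt = "HumanCurated", ...) {
  make_mapping(subject_id = s, predicate_id = p, object_id = o,
               match_type = mt, ...)
}

simple_set <- function(mappings, id = "https://example.org/ms/test", ...) {
  mapping_set(mappings, mapping_set_id = id, curie_map = test_pm(), ...)
}

# A randomly populated but always-valid mapping set, for property tests.
random_mapping_set <- function(seed, n_rows = NULL) {
  set.seed(seed)
  if (is.null(n_rows)) n_rows <- sample(0:8, 1)
  preds <- sssom_predicates()$predicate_id
  mts <- sssom_match_types()
  rows <- lapply(seq_len(n_rows), function(i) {
    rec <- list(
      subject_id = sprintf("A:%d", sample(1:6, 1)),
      predicate_id = sample(c(preds, "X:customRel"), 1),
      object_id = sprintf("B:%d", sample(1:6, 1)),
      match_type = sample(mts, 1))
    if (runif(1) < 0.4) rec$confidence <- round(runif(1), 4)
    if (runif(1) < 0.3) rec$predicate_modifier <- "Not"
    if (runif(1) < 0.3) rec$author_id <- sprintf("orcid:%d", sample(1:9, sample(1:3, 1)))
    if (runif(1) < 0.3) rec$mapping_date <- format(as.Date("2020-01-01") + sample(0:900, 1))
    if (runif(1) < 0.3) rec$comment <- paste("note", sample(1:99, 1))
    if (runif(1) < 0.3) rec$subject_label <- paste("label", sample(1:99, 1))
    if (runif(1) < 0.2) rec$match_string <- paste0("str", sample(1:9, sample(1:2, 1)))
    if (runif(1) < 0.2) rec$semantic_similarity_score <- round(runif(1), 4)
    if (runif(1) < 0.2) rec$see_also <- paste0("https://example.org/see/", sample(1:9, 1))
    do.call(make_mapping, rec)
  })
  meta <- list(mapping_set_id = sprintf("https://example.org/ms/%d", seed))
  if (runif(1) < 0.5) meta$license <- "https://creativecommons.org/licenses/by/4.0/"
  if (runif(1) < 0.4) meta$mapping_set_version <- sprintf("%d.0", sample(1:5, 1))
  if (runif(1) < 0.3) meta$creator_id <- sprintf("orcid:%d", sample(1:9, sample(1:2, 1)))
  do.call(mapping_set, c(list(mappings = rows, curie_map = test_pm()), meta))
}

mappings_tibble_for_test <- function(subjects, objects) {
  rows <- mapply(function(s, o) {
    make_mapping(subject_id = s, predicate_id = "skos:exactMatch",
                 object_id = o, match_type = "HumanCurated")
  }, subjects, objects, SIMPLIFY = FALSE)
  sssomr:::mappings_tibble(unname(rows))
}

# -- crosswalk oracle ---------------------------------------------------------

# Exhaustive simple-path enumeration folded through compose_strengths().
# Independent of sssom_neighbors(): no pruning, all paths first, reduce after.
oracle_neighbors <- function(edges, start, max_distance, min_strength = NULL) {
  # edges: data.frame(from, to, strength) of undirected mapping edges
  adj <- rbind(
    data.frame(from = edges$from, to = edges$to, strength = edges$strength,
               stringsAsFactors = FALSE),
    data.frame(from = edges$to, to = edges$from,
               strength = vapply(edges$strength, strength_inverse, ""),
               stringsAsFactors = FALSE))
  adj <- unique(adj)
  paths <- list()
  grow <- function(path, strengths) {
    node <- path[length(path)]
    if (length(strengths) > 0) {
      paths[[length(paths) + 1]] <<- list(path = path, strengths = strengths)
    }
    if (length(strengths) == max_distance) return()
    nxt <- adj[adj$from == node, , drop = FALSE]
    for (k in seq_len(nrow(nxt))) {
      if (nxt$to[k] %in% path) next
      grow(c(path, nxt$to[k]), c(strengths, nxt$strength[k]))
    }
  }
  grow(start, character(0))
  rank <- c(EXACT = 4, CLOSE = 3, RELATED = 2, BROAD = 1, NARROW = 1)
  best <- list()
  for (p in paths) {
    s <- compose_strengths(p$strengths)
    if (is.na(s)) next
    ent <- p$path[length(p$path)]
    d <- length(p$strengths)
    cur <- best[[ent]]
    if (is.null(cur) || d < cur$distance ||
        (d == cur$distance && (rank[s] > rank[cur$strength] ||
          (rank[s] == rank[cur$strength] &&
             paste(c(p$path, s), collapse = "\x1e") <
               paste(c(cur$path, cur$strength), collapse = "\x1e"))))) {
      best[[ent]] <- list(entity = ent, strength = s, distance = d,
                          path = p$path)
    }
  }
  if (!is.null(min_strength)) {
    best <- Filter(function(h) rank[h$strength] >= rank[[min_strength]], best)
  }
  out <- data.frame(
    entity = vapply(best, `[[`, "", "entity"),
    strength = vapply(best, `[[`, "", "strength"),
    distance = vapply(best, function(h) as.integer(h$distance), 0L),
    path = vapply(best, function(h) paste(h$path, collapse = " -> "), ""),
    stringsAsFactors = FALSE)
  out[order(out$distance, out$entity, method = "radix"), , drop = FALSE]
}

random_graph_set <- function(seed, n_nodes = NULL, n_edges = NULL) {
  set.seed(seed)
  if (is.null(n_nodes)) n_nodes <- sample(4:12, 1)
  if (is.null(n_edges)) n_edges <- sample(3:16, 1)
  nodes <- sprintf("A:%02d", seq_len(n_nodes))
  preds <- sssom_predicates()$predicate_id
  rows <- lapply(seq_len(n_edges), function(i) {
    ends <- sample(nodes, 2)
    simple_mapping(ends[1], sample(preds, 1), ends[2], mt = "Lexical")
  })
  simple_set(rows)
}

# -- triple-count oracles -----------------------------------------------------

# |direct| by brute-force row scan over distinct non-negated (s, p, o)
oracle_direct_count <- function(set) {
  tab <- set$mappings
  keep <- is.na(tab$predicate_modifier)
  nrow(unique(data.frame(s = tab$subject_id[keep], p = tab$predicate_id[keep],
                         o = tab$object_id[keep])))
}

# |reified| = sum over rows of 4 + number of populated optional slot values
# (multivalued slots contribute one triple per value); assumes rows carry
# distinct annotation nodes so no cross-row collapsing occurs
oracle_reified_count <- function(set) {
  total <- 0
  for (i in seq_len(n_mappings(set))) {
    rec <- sssomr:::mapping_record(set, i)
    meta <- rec[setdiff(names(rec), c("subject_id", "predicate_id", "object_id"))]
    total <- total + 4 + sum(lengths(meta))
  }
  total
}
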