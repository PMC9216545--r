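anatomy_fixture <- function() {
  pm <- prefix_map(FMA = "http://purl.obolibrary.org/obo/FMA_",
                   UBERON = "http://purl.obolibrary.org/obo/UBERON_",
                   MA = "http://purl.obolibrary.org/obo/MA_",
                   UMLS = "https://uts.nlm.nih.gov/uts/umls/concept/",
                   EFO = "http://www.ebi.ac.uk/efo/EFO_")
  mk <- function(s, p, o) make_mapping(subject_id = s, predicate_id = p,
                                       object_id = o, match_type = "HumanCurated")
  mapping_set(list(
    mk("FMA:24875", "skos:exactMatch", "UBERON:0002101"),
    mk("UBERON:0002101", "skos:exactMatch", "MA:0000007"),
    mk("UBERON:0002101", "skos:relatedMatch", "UMLS:C0015385"),
    mk("UBERON:0002101", "skos:exactMatch", "EFO:0000876")),
    mapping_set_id = "https://example.org/ms/anatomy", curie_map = pm)
}

test_that("composition algebra: identity, self-composition, degradation", {
  expect_equal(compose_strengths(c("EXACT", "EXACT")), "EXACT")
  expect_equal(compose_strengths(c("EXACT", "RELATED")), "RELATED")
  expect_equal(compose_strengths(c("CLOSE", "EXACT")), "CLOSE")
  expect_equal(compose_strengths(c("BROAD", "BROAD")), "BROAD")
  expect_equal(compose_strengths(c("CLOSE", "CLOSE")), "RELATED")
  expect_true(is.na(compose_strengths(c("BROAD", "NARROW"))))
  expect_true(is.na(compose_strengths(c("RELATED", "RELATED"))))
  expect_error(compose_strengths(character(0)), class = "sssom_usage_error")
})

test_that("composition matches a brute-force fold over all short tuples", {
  strengths <- c("EXACT", "CLOSE", "RELATED", "BROAD", "NARROW")
  # independent oracle: pair table written out in full, folded by Reduce
  pair <- function(a, b) {
    if (a == "EXACT") return(b)
    if (b == "EXACT") return(a)
    if (a == b && a %in% c("BROAD", "NARROW")) return(a)
    if (a == "CLOSE" && b == "CLOSE") return("RELATED")
    NA_character_
  }
  fold <- function(xs) Reduce(function(a, b) if (is.na(a)) NA_character_ else
    pair(a, b), xs[-1], xs[1])
  tuples <- list()
  for (a in strengths) {
    tuples[[length(tuples) + 1]] <- a
    for (b in strengths) {
      tuples[[length(tuples) + 1]] <- c(a, b)
      for (c3 in strengths) tuples[[length(tuples) + 1]] <- c(a, b, c3)
    }
  }
  for (tp in tuples) {
    expect_identical(compose_strengths(tp), fold(tp),
                     label = paste(tp, collapse = ","))
  }
})

test_that("graph construction applies negation, confidence, class and obsolete filters", {
  set <- simple_set(list(
    simple_mapping(confidence = 0.4),
    simple_mapping("A:2", o = "X:2", predicate_modifier = "Not"),
    simple_mapping("A:3", p = "B:mystery", o = "X:3"),
    simple_mapping("A:4", o = "X:4"),
    simple_mapping("A:5", o = "X:5")))
  g <- build_mapping_graph(set, min_confidence = 0.5, obsolete = "X:5")
  expect_equal(sort(g$edges$from), "A:4")
  # rows lacking confidence pass the threshold
  expect_true("A:4" %in% g$nodes)
  expect_false(any(c("A:1", "A:2", "A:3", "A:5") %in% g$edges$from))
})

test_that("one-hop search finds the single exact neighbor of the limb fixture", {
  g <- build_mapping_graph(anatomy_fixture(), obsolete = "EFO:0000876")
  nb <- sssom_neighbors(g, "FMA:24875", 1)
  expect_equal(nrow(nb), 1)
  expect_equal(nb$entity, "UBERON:0002101")
  expect_equal(nb$strength, "EXACT")
  expect_equal(nb$distance, 1L)
})

test_that("two-hop search separates exact from related-derived entities", {
  g <- build_mapping_graph(anatomy_fixture(), obsolete = "EFO:0000876")
  exact_only <- sssom_neighbors(g, "FMA:24875", 2, min_strength = "EXACT")
  expect_setequal(exact_only$entity, c("UBERON:0002101", "MA:0000007"))
  all_nb <- sssom_neighbors(g, "FMA:24875", 2)
  expect_true("UMLS:C0015385" %in% all_nb$entity)
  expect_equal(all_nb$strength[all_nb$entity == "UMLS:C0015385"], "RELATED")
  # the obsolete term never appears
  expect_false("EFO:0000876" %in% all_nb$entity)
})

test_that("unknown start node gives an empty result, not an error", {
  g <- build_mapping_graph(anatomy_fixture())
  expect_equal(nrow(sssom_neighbors(g, "GO:0000001", 2)), 0)
  expect_error(sssom_neighbors(g, "FMA:24875", 0), class = "sssom_usage_error")
})

test_that("neighbors agrees exactly with exhaustive path enumeration", {
  for (seed in 1:40) {
    set <- random_graph_set(seed)
    g <- build_mapping_graph(set)
    edges <- data.frame(from = g$edges$from, to = g$edges$to,
                        strength = g$edges$strength, stringsAsFactors = FALSE)
    for (d in 1:3) {
      start <- g$nodes[1]
      got <- sssom_neighbors(g, start, d)
      want <- oracle_neighbors(edges, start, d)
      expect_equal(got$entity, want$entity, label = sprintf("seed %d d %d", seed, d))
      expect_equal(got$strength, want$strength,
                   label = sprintf("seed %d d %d strengths", seed, d))
      expect_equal(got$distance, want$distance,
                   label = sprintf("seed %d d %d distances", seed, d))
    }
  }
})

test_that("enlarging the search radius is monotone", {
  for (seed in c(5, 23, 31)) {
    g <- build_mapping_graph(random_graph_set(seed))
    start <- g$nodes[1]
    rank <- c(EXACT = 4, CLOSE = 3, RELATED = 2, BROAD = 1, NARROW = 1)
    prev <- sssom_neighbors(g, start, 1)
    for (d in 2:4) {
      cur <- sssom_neighbors(g, start, d)
      expect_true(all(prev$entity %in% cur$entity))
      for (e in prev$entity) {
        if (cur$distance[cur$entity == e] == prev$distance[prev$entity == e]) {
          expect_gte(rank[[cur$strength[cur$entity == e]]],
                     rank[[prev$strength[prev$entity == e]]])
        }
      }
      prev <- cur
    }
  }
})

test_that("exact-only chains stay exact at any length", {
  pm <- prefix_map(N = "https://example.org/n/")
  chain <- lapply(1:6, function(i) {
    make_mapping(subject_id = sprintf("N:%d", i), predicate_id = "skos:exactMatch",
                 object_id = sprintf("N:%d", i + 1), match_type = "Lexical")
  })
  set <- mapping_set(chain, mapping_set_id = "https://example.org/ms/chain",
                     curie_map = pm)
  nb <- sssom_neighbors(build_mapping_graph(set), "N:1", 6)
  expect_true(all(nb$strength == "EXACT"))
  expect_equal(max(nb$distance), 6L)
})
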