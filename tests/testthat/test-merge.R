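test_that("merge concatenates rows, merges prefixes and records sources", {
  a <- simple_set(list(simple_mapping()), id = "https://example.org/ms/a")
  b <- simple_set(list(simple_mapping("A:2", o = "X:2")),
                  id = "https://example.org/ms/b")
  m <- sssom_merge(list(a, b), "https://example.org/ms/merged")
  expect_equal(n_mappings(m), 2)
  expect_equal(m$metadata$mapping_set_id, "https://example.org/ms/merged")
  expect_setequal(m$metadata$see_also,
                  c("https://example.org/ms/a", "https://example.org/ms/b"))
  # identity on a single set's mappings
  single <- sssom_merge(list(a), "https://example.org/ms/one")
  expect_identical(single$mappings, a$mappings)
  # clashing prefix maps propagate
  c_set <- mapping_set(list(make_mapping(subject_id = "A:1",
                                         predicate_id = "skos:exactMatch",
                                         object_id = "A:2",
                                         match_type = "Lexical")),
                       mapping_set_id = "https://example.org/ms/c",
                       curie_map = prefix_map(A = "https://elsewhere/"))
  expect_error(sssom_merge(list(a, c_set), "https://example.org/ms/x"),
               class = "sssom_prefix_clash")
})

test_that("merge is associative up to row order", {
  sets <- lapply(1:3, random_mapping_set)
  lhs <- sssom_merge(list(sssom_merge(sets[1:2], "https://e.org/ab"), sets[[3]]),
                     "https://e.org/abc")
  rhs <- sssom_merge(list(sets[[1]], sssom_merge(sets[2:3], "https://e.org/bc")),
                     "https://e.org/abc")
  key <- function(s) sort(vapply(seq_len(n_mappings(s)),
                                 function(i) sssomr:::row_key_full(s, i), ""))
  expect_identical(key(lhs), key(rhs))
})

test_that("dedup collapses byte-identical rows but keeps distinct rules", {
  same <- simple_mapping(match_string = "limb")
  rule2 <- simple_mapping(match_string = "limb",
                          subject_match_field = "oboInOwl:hasExactSynonym")
  set <- simple_set(list(same, same, rule2))
  dd <- sssom_dedup(set)
  expect_equal(n_mappings(dd), 2)
  expect_identical(sssom_dedup(dd)$mappings, dd$mappings)  # idempotent
  expect_equal(n_mappings(sssom_dedup(simple_set(list()))), 0)
})

test_that("collapse_rules merges rule rows into one mapping per (s,p,mod,o)", {
  r1 <- simple_mapping(mt = "Lexical", confidence = 0.7,
                       subject_match_field = "rdfs:label",
                       object_match_field = "rdfs:label", match_string = "limb")
  r2 <- simple_mapping(mt = "Lexical", confidence = 0.9,
                       subject_match_field = "oboInOwl:hasExactSynonym",
                       object_match_field = "rdfs:label", match_string = "limb")
  set <- collapse_rules(simple_set(list(r1, r2)))
  expect_equal(n_mappings(set), 1)
  expect_equal(set$mappings$confidence, 0.9)
  expect_equal(set$mappings$match_type, "Lexical")
  expect_setequal(set$mappings$subject_match_field[[1]],
                  c("rdfs:label", "oboInOwl:hasExactSynonym"))

  # disagreeing match types degrade to Complex
  mix <- simple_set(list(simple_mapping(mt = "Lexical"),
                         simple_mapping(mt = "Logical")))
  expect_equal(collapse_rules(mix)$mappings$match_type, "Complex")

  # singleton rows and already-collapsed sets are unchanged
  single <- simple_set(list(r1))
  expect_true(sssom_equal(collapse_rules(single), single))
  expect_true(sssom_equal(collapse_rules(collapse_rules(mix)),
                          collapse_rules(mix)))
})

test_that("cardinality labels follow the subject/object degree counts", {
  mk <- function(s, o) simple_mapping(s, o = o)
  set <- simple_set(list(mk("A:1", "X:1"), mk("A:1", "X:2"), mk("A:2", "X:2"),
                         simple_mapping("A:3", o = "X:3",
                                        predicate_modifier = "Not")))
  out <- compute_cardinality(set)$mappings
  expect_equal(out$mapping_cardinality, c("1:n", "n:n", "n:1", NA))
  # both-isolated pairs are 1:1
  iso <- compute_cardinality(simple_set(list(mk("A:1", "X:1"), mk("A:2", "X:2"))))
  expect_equal(iso$mappings$mapping_cardinality, c("1:1", "1:1"))
})

test_that("unique-object reconciliation keeps one winner per object", {
  set <- simple_set(list(
    simple_mapping("A:1", o = "X:1", mt = "Lexical", confidence = 0.9),
    simple_mapping("A:2", o = "X:1", mt = "Lexical", confidence = 0.8)))
  res <- reconcile_unique_object(set)
  expect_equal(res$accepted$mappings$subject_id, "A:1")
  expect_equal(res$rejected$mappings$subject_id, "A:2")
  expect_equal(res$rejected$mappings$predicate_modifier, "Not")
  expect_match(res$rejected$mappings$comment, "rejected")

  # equal confidence: HumanCurated outranks Lexical
  tie <- simple_set(list(
    simple_mapping("A:1", o = "X:1", mt = "Lexical", confidence = 0.8),
    simple_mapping("A:2", o = "X:1", mt = "HumanCurated", confidence = 0.8)))
  expect_equal(reconcile_unique_object(tie)$accepted$mappings$subject_id, "A:2")

  # full tie: lexicographically smallest subject
  tie2 <- simple_set(list(simple_mapping("A:2", o = "X:1", mt = "Lexical"),
                          simple_mapping("A:1", o = "X:1", mt = "Lexical")))
  expect_equal(reconcile_unique_object(tie2)$accepted$mappings$subject_id, "A:1")

  # single row passes untouched; non-EXACT rows are never rejected
  one <- simple_set(list(simple_mapping()))
  r1 <- reconcile_unique_object(one)
  expect_true(sssom_equal(r1$accepted, one))
  expect_equal(n_mappings(r1$rejected), 0)
  rel <- simple_set(list(simple_mapping(p = "skos:relatedMatch"),
                         simple_mapping("A:2", p = "skos:relatedMatch", o = "X:1")))
  expect_equal(n_mappings(reconcile_unique_object(rel)$rejected), 0)
})

test_that("reconciliation invariants hold on random collapsed sets", {
  for (seed in 1:25) {
    set <- collapse_rules(random_mapping_set(seed))
    res <- reconcile_unique_object(set)
    acc <- res$accepted$mappings
    strength <- vapply(acc$predicate_id, predicate_class, "")
    exact_obj <- acc$object_id[strength == "EXACT" & is.na(acc$predicate_modifier)]
    expect_equal(anyDuplicated(exact_obj), 0, label = sprintf("seed %d", seed))
    # accepted + rejected partition the input rows
    expect_equal(n_mappings(res$accepted) + n_mappings(res$rejected),
                 n_mappings(set))
    if (n_mappings(res$rejected) > 0) {
      expect_true(all(res$rejected$mappings$predicate_modifier == "Not"))
    }
  }
})

test_that("conflict detection reports negation and strength clashes by pair", {
  set <- simple_set(list(
    simple_mapping(),                                            # A:1 exact X:1
    simple_mapping(predicate_modifier = "Not"),                  # negated twin
    simple_mapping("A:2", o = "X:2"),
    simple_mapping("A:2", p = "skos:relatedMatch", o = "X:2")))
  conf <- detect_conflicts(set)
  expect_equal(conf$kind, c("NEGATION_CLASH", "STRENGTH_CLASH"))
  expect_equal(conf$subject_id, c("A:1", "A:2"))
  expect_equal(sort(conf$rows[[1]]), c(1L, 2L))
  clean <- simple_set(list(simple_mapping(), simple_mapping("A:2", o = "X:2")))
  expect_equal(nrow(detect_conflicts(clean)), 0)
})
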