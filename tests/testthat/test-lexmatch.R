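label_tab <- function(...) {
  rows <- list(...)
  tibble::tibble(entity_id = vapply(rows, `[[`, "", 1),
                 field = vapply(rows, `[[`, "", 2),
                 text = vapply(rows, `[[`, "", 3))
}

lex_pm <- prefix_map(S = "https://example.org/s/", O = "https://example.org/o/")

test_that("preprocessing steps apply left to right with defined semantics", {
  steps <- c("lowercase", "strip_nonalphanumeric", "collapse_whitespace")
  expect_equal(preprocess_label("Alzheimer 2", steps), "alzheimer 2")  # digits kept
  expect_equal(preprocess_label("Alzheimer 2",
                                c("lowercase", "strip_nonalphanumeric",
                                  "strip_digits", "collapse_whitespace")),
               "alzheimer")
  expect_equal(preprocess_label("  Limb ", c("lowercase", "collapse_whitespace")),
               "limb")
  expect_equal(preprocess_label("anything", character(0)), "anything")
  expect_equal(preprocess_label("a-b,c!", c("strip_nonalphanumeric")), "abc")
  expect_error(preprocess_label("x", "stemming"), class = "sssom_usage_error")
})

test_that("case-folded label equality produces a fully annotated row", {
  set <- lexical_match(label_tab(list("S:1", "rdfs:label", "limb")),
                       label_tab(list("O:1", "rdfs:label", "Limb")),
                       curie_map = lex_pm)
  expect_equal(n_mappings(set), 1)
  tab <- set$mappings
  expect_equal(tab$subject_id, "S:1")
  expect_equal(tab$object_id, "O:1")
  expect_equal(tab$match_type, "Lexical")
  expect_equal(tab$match_string[[1]], "limb")
  expect_equal(tab$subject_match_field[[1]], "rdfs:label")
  expect_equal(tab$subject_preprocessing[[1]],
               c("lowercase", "collapse_whitespace"))
  expect_equal(tab$confidence, 0.9)
  # emitted set validates cleanly apart from the (decided) license warning
  issues <- validate_sssom(set)
  expect_true(all(issues$severity != "ERROR"))
})

test_that("agreement on both label and synonym yields one row per rule", {
  subj <- label_tab(list("S:1", "rdfs:label", "limb"),
                    list("S:1", "oboInOwl:hasExactSynonym", "free limb"))
  obj <- label_tab(list("O:1", "rdfs:label", "limb"),
                   list("O:1", "oboInOwl:hasExactSynonym", "free limb"))
  set <- lexical_match(subj, obj, curie_map = lex_pm)
  expect_equal(n_mappings(set), 2)
  expect_equal(set$mappings$subject_id, c("S:1", "S:1"))
  # label/label rule outranks synonym/synonym, and rows sort confidence-desc
  expect_equal(set$mappings$confidence, c(0.9, 0.7))
  fields <- vapply(seq_len(2), function(i)
    paste(set$mappings$subject_match_field[[i]],
          set$mappings$object_match_field[[i]], sep = "~"), "")
  expect_setequal(fields, c("rdfs:label~rdfs:label",
                            "oboInOwl:hasExactSynonym~oboInOwl:hasExactSynonym"))
})

test_that("digit-stripping exposes the misleading-variant hazard transparently", {
  subj <- label_tab(list("S:1", "rdfs:label", "Alzheimer 2"))
  obj <- label_tab(list("O:1", "rdfs:label", "Alzheimer 3"))
  default <- lexical_match(subj, obj, curie_map = lex_pm)
  expect_equal(n_mappings(default), 0)  # digits distinguish the variants
  destructive <- match_config(preprocessing = c("lowercase", "strip_digits",
                                                "collapse_whitespace"))
  risky <- lexical_match(subj, obj, config = destructive, curie_map = lex_pm)
  expect_equal(n_mappings(risky), 1)
  expect_equal(risky$mappings$match_string[[1]], "alzheimer")
  # the hazard is visible in the preprocessing slots, and costs confidence
  expect_true("strip_digits" %in% risky$mappings$subject_preprocessing[[1]])
  expect_equal(risky$mappings$confidence, 0.85)
})

test_that("self-matches are suppressed and overlap warns", {
  tabs <- label_tab(list("S:1", "rdfs:label", "limb"))
  expect_equal(n_mappings(suppressWarnings(
    lexical_match(tabs, tabs, curie_map = lex_pm))), 0)
  expect_warning(lexical_match(tabs, tabs, curie_map = lex_pm),
                 class = "sssom_entity_overlap")
})

test_that("matching is symmetric up to subject/object transposition", {
  subj <- label_tab(list("S:1", "rdfs:label", "alpha"),
                    list("S:2", "oboInOwl:hasExactSynonym", "beta"))
  obj <- label_tab(list("O:1", "rdfs:label", "beta"),
                   list("O:2", "rdfs:label", "alpha"))
  fwd <- lexical_match(subj, obj, curie_map = lex_pm)
  rev <- lexical_match(obj, subj, curie_map = lex_pm)
  expect_equal(n_mappings(fwd), n_mappings(rev))
  fwd_pairs <- sort(paste(fwd$mappings$subject_id, fwd$mappings$object_id,
                          fwd$mappings$confidence))
  rev_pairs <- sort(paste(rev$mappings$object_id, rev$mappings$subject_id,
                          rev$mappings$confidence))
  expect_identical(fwd_pairs, rev_pairs)
})

test_that("matcher output is byte-deterministic", {
  corpus <- generate_corpus(corpus_spec(n_concepts = 15, p_synonym = 0.3, seed = 3))
  one <- format_sssom(lexical_match(corpus$labels$NS1, corpus$labels$NS2,
                                    curie_map = corpus$curie_map))
  two <- format_sssom(lexical_match(corpus$labels$NS1, corpus$labels$NS2,
                                    curie_map = corpus$curie_map))
  expect_identical(one, two)
})

test_that("invalid label tables are rejected", {
  expect_error(lexical_match(tibble::tibble(entity_id = "S:1"), label_tab(),
                             curie_map = lex_pm),
               class = "sssom_usage_error")
  expect_error(lexical_match(label_tab(list("S:1", "rdfs:label", "")),
                             label_tab(list("O:1", "rdfs:label", "x")),
                             curie_map = lex_pm),
               class = "sssom_format_error")
  expect_error(lexical_match(label_tab(list("S:1", "dc:title", "x")),
                             label_tab(list("O:1", "rdfs:label", "x")),
                             curie_map = lex_pm),
               class = "sssom_format_error")
})
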