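# Seeded generator of label corpora with ground-truth mapping sets, so the
# matcher, the TSV round trip, validation and reconciliation are all
# exercisable without downloading any ontology. The corpus emulates K
# vocabularies ("namespaces") naming the same abstract concepts, with
# per-namespace label noise of the kinds that real terminologies exhibit
# (case variation, stray punctuation, digit-suffixed variants).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.NOISE_STEPS <- c("case_flip", "punctuation_insert", "digit_suffix")

#' Specification for a synthetic label corpus
#'
#' @param n_namespaces Number of vocabularies (>= 2).
#' @param n_concepts Number of shared abstract concepts (>= 1).
#' @param p_synonym Probability that an entity additionally carries an exact
#'   synonym record.
#' @param noise_steps Character subset of `case_flip`, `punctuation_insert`,
#'   `digit_suffix`; each step perturbs a given label with probability
#'   `p_noise`.
#' @param p_noise Per-label application probability of each noise step.
#' @param seed Integer seed; the same spec always generates identical output.
#' @return A list of class `sssom_corpus_spec`.
#' @export
corpus_spec <- function(n_namespaces = 2, n_concepts = 50, p_synonym = 0.2,
                        noise_steps = character(0), p_noise = 0.5, seed = 42) {
  if (n_namespaces < 2 || n_concepts < 1) {
    sssom_abort("need n_namespaces >= 2 and n_concepts >= 1", "sssom_usage_error")
  }
  if (p_synonym < 0 || p_synonym > 1 || p_noise < 0 || p_noise > 1) {
    sssom_abort("probabilities must lie in [0,1]", "sssom_usage_error")
  }
  bad <- setdiff(noise_steps, .NOISE_STEPS)
  if (length(bad) > 0) {
    sssom_abort(paste0("unknown noise step(s): ", paste(bad, collapse = ", ")),
                "sssom_usage_error")
  }
  structure(list(n_namespaces = as.integer(n_namespaces),
                 n_concepts = as.integer(n_concepts),
                 p_synonym = p_synonym, noise_steps = noise_steps,
                 p_noise = p_noise, seed = as.integer(seed)),
            class = "sssom_corpus_spec")
}

# pronounceable pseudo-words, unique across concepts
random_labels <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  make_word <- function() {
    k <- sample(2:4, 1)
    paste0(paste0(sample(cons, k, replace = TRUE),
                  sample(vow, k, replace = TRUE)), collapse = "")
  }
  out <- character(0)
  while (length(out) < n) {
    w <- paste(make_word(), make_word())
    if (!w %in% out) out <- c(out, w)
  }
  out
}

apply_noise <- function(label, steps, p) {
  for (step in steps) {
    if (stats::runif(1) >= p) next
    label <- switch(step,
      case_flip = {
        ch <- strsplit(label, "")[[1]]
        flip <- stats::runif(length(ch)) < 0.3
        ch[flip] <- toupper(ch[flip])
        paste(ch, collapse = "")
      },
      punctuation_insert = {
        pos <- sample(nchar(label) - 1, 1)
        paste0(substr(label, 1, pos), sample(c("-", ",", "'"), 1),
               substr(label, pos + 1, nchar(label)))
      },
      digit_suffix = paste0(label, " ", sample(1:9, 1)))
  }
  label
}

#' Generate a synthetic label corpus with ground truth
#'
#' Realizes each abstract concept as one entity per namespace (CURIEs
#' `NS<i>:<zero-padded index>`) sharing a base label, perturbed per
#' namespace by the spec's noise steps; synonym records are added with
#' probability `p_synonym`. The ground-truth set contains every
#' cross-namespace pair, oriented subject-namespace-index <
#' object-namespace-index (`n_concepts * choose(n_namespaces, 2)` rows),
#' with predicate `skos:exactMatch` and `match_type = HumanCurated`.
#'
#' @param spec A [corpus_spec()].
#' @return A list with `labels` (named list of per-namespace label tables:
#'   `entity_id`, `field`, `text`), `truth` (a `sssom_mapping_set`) and
#'   `curie_map`.
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  if (!inherits(spec, "sssom_corpus_spec")) {
    sssom_abort("spec must be a corpus_spec()", "sssom_usage_error")
  }
  with_seed(spec$seed, {
    K <- spec$n_namespaces
    N <- spec$n_concepts
    base <- random_labels(N)
    pm_entries <- stats::setNames(
      paste0("https://example.org/ns", seq_len(K), "/"),
      paste0("NS", seq_len(K)))
    pm <- merge_prefix_maps(prefix_map(entries = pm_entries), .OBOINOWL_PREFIX)

    labels <- list()
    for (ns in seq_len(K)) {
      ids <- sprintf("NS%d:%04d", ns, seq_len(N))
      text <- vapply(base, apply_noise, "", steps = spec$noise_steps,
                     p = spec$p_noise, USE.NAMES = FALSE)
      tab <- tibble::tibble(entity_id = ids, field = "rdfs:label", text = text)
      syn <- which(stats::runif(N) < spec$p_synonym)
      if (length(syn) > 0) {
        tab <- rbind(tab, tibble::tibble(
          entity_id = ids[syn],
          field = "oboInOwl:hasExactSynonym",
          text = paste(base[syn], "variant")))
      }
      labels[[paste0("NS", ns)]] <- tab
    }

    rows <- list()
    for (concept in seq_len(N)) {
      for (i in seq_len(K - 1)) {
        for (j in seq((i + 1), K)) {
          rows[[length(rows) + 1]] <- make_mapping(
            subject_id = sprintf("NS%d:%04d", i, concept),
            subject_label = base[concept],
            predicate_id = "skos:exactMatch",
            object_id = sprintf("NS%d:%04d", j, concept),
            match_type = "HumanCurated")
        }
      }
    }
    truth <- new_mapping_set(
      list(mapping_set_id = "https://example.org/sssomr/synthetic/truth",
           license = "https://creativecommons.org/publicdomain/zero/1.0/",
           mapping_set_description = "synthetic ground-truth mapping set"),
      pm, mappings_tibble(rows))
    list(labels = labels, truth = truth, curie_map = pm)
  })
}

exact_pairs <- function(set) {
  tab <- set$mappings
  if (nrow(tab) == 0) return(character(0))
  strength <- vapply(tab$predicate_id, predicate_class, "")
  keep <- strength == "EXACT" & is.na(tab$predicate_modifier)
  s <- tab$subject_id[keep]
  o <- tab$object_id[keep]
  unique(paste(pmin(s, o), pmax(s, o), sep = "\x1e"))
}

#' Precision, recall and F1 against a ground-truth set
#'
#' Comparison is over unordered (subject, object) pairs, restricted to
#' non-negated EXACT-class rows in both sets. Degenerate cases (no
#' predictions, no truth) score 0 by convention.
#'
#' @param predicted,truth Mapping sets.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
evaluate_mappings <- function(predicted, truth) {
  p <- exact_pairs(predicted)
  t <- exact_pairs(truth)
  tp <- length(intersect(p, t))
  precision <- if (length(p) == 0) 0 else tp / length(p)
  recall <- if (length(t) == 0) 0 else tp / length(t)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}
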