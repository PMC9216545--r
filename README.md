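# sssomr

Tools for the **Simple Standard for Sharing Ontological Mappings (SSSOM)**
in R.

Integrating biomedical data across databases and ontologies requires
*mappings* — statements that a term in one vocabulary corresponds to a term
in another — and mappings are only reusable when they carry metadata: the
precision of the correspondence (`skos:exactMatch` vs `skos:relatedMatch`),
who or what established it, with what confidence, and on which evidence.
SSSOM standardizes this as a flat TSV table of mappings plus a block of
set-level metadata written as commented YAML, so mapping sets stay
consumable by ordinary data-science toolchains while remaining
semantically precise.

`sssomr` is for curators and data engineers who produce, check, combine or
consume such mapping sets. It provides:

* **I/O** — `read_sssom()` / `write_sssom()` / `parse_sssom()` for the
  SSSOM TSV format in embedded and external metadata modes, with canonical
  byte-deterministic output; CURIE/prefix-map handling
  (`curie_expand()`, `curie_contract()`, `merge_prefix_maps()`).
* **Schema registry** — the 38 mapping-level and 23 set-level metadata
  slots (`sssom_slots()`), the five match types, the ten recommended
  predicates with their strength classes (`sssom_predicates()`,
  `predicate_class()`), and the thirteen slots mapped to external
  vocabularies (`external_property_for()`).
* **Validation** — `validate_sssom()` applies thirteen rules (required
  slots, CURIE resolvability, vocabularies, ranges, dates, duplicate rows,
  the preprocessing/match-field hazard) and returns findings as a tibble.
* **Conversion** — `sssom_to_json()`, and N-Triples RDF in three profiles:
  direct triples, `owl:Axiom`-reified triples carrying all metadata, and
  OWL-conformant output with entity declarations.
* **Set operations** — `sssom_merge()`, `sssom_dedup()`,
  `collapse_rules()`, `compute_cardinality()` (1:1 / 1:n / n:1 / n:n),
  `reconcile_unique_object()` (no object term mapped from more than one
  subject; losers kept as explicitly negated rows) and
  `detect_conflicts()`.
* **Cross-walking** — `build_mapping_graph()` and `sssom_neighbors()`
  derive indirect correspondences by chaining mappings, composing strength
  classes through an explicit algebra (`EXACT` is the identity;
  `CLOSE∘CLOSE` degrades to `RELATED`; undefined compositions kill a path).
* **Lexical matching** — `lexical_match()` over flat label tables, one
  output row per mapping rule with match fields, match strings,
  preprocessing and confidences.
* **Synthetic corpora** — `generate_corpus()` builds seeded label corpora
  with ground truth; `evaluate_mappings()` scores precision/recall/F1.

A `sssom` command-line wrapper (subcommands `parse`, `validate`,
`convert`, `merge`, `dedup`, `cardinality`, `reconcile`, `crosswalk`,
`match`, `generate`) is provided as `inst/cli/sssom`, a thin Rscript over
`sssom_main()`.

## Worked example

The package ships a small demonstration set around the classic anatomical
"limb" cross-walk:

```r
library(sssomr)
set <- read_sssom(system.file("extdata", "limb-demo.sssom.tsv", package = "sssomr"))
set
#> <sssom_mapping_set> https://example.org/mappings/limb-demo
#>   mappings: 3 | prefixes declared: 5
#>   optional slots populated: subject_label, object_label, author_id, mapping_date

nrow(validate_sssom(set))   # 0 issues: the set is clean
```

Hopping outward from `FMA:24875` ("Free limb"), the derived strength of
each neighbour is the composition of the strengths along its path — the
two-hop neighbour reached through an exact chain stays `EXACT`, while the
one reached through a related match is only `RELATED` and would be dropped
by `min_strength = "EXACT"`:

```r
g <- build_mapping_graph(set)
sssom_neighbors(g, "FMA:24875", max_distance = 2)
#>           entity strength distance                                         path
#> 1 UBERON:0002101    EXACT        1                  FMA:24875 -> UBERON:0002101
#> 2     MA:0000007    EXACT        2    FMA:24875 -> UBERON:0002101 -> MA:0000007
#> 3  UMLS:C0015385  RELATED        2 FMA:24875 -> UBERON:0002101 -> UMLS:C0015385
```

Export the asserted mappings as plain RDF (negated rows, if any, are
omitted — a rejected mapping must not be asserted as a triple):

```r
cat(format_ntriples(sssom_to_rdf_direct(set)))
#> <http://purl.obolibrary.org/obo/FMA_24875> <http://www.w3.org/2004/02/skos/core#exactMatch> <http://purl.obolibrary.org/obo/UBERON_0002101> .
#> <http://purl.obolibrary.org/obo/UBERON_0002101> <http://www.w3.org/2004/02/skos/core#exactMatch> <http://purl.obolibrary.org/obo/MA_0000007> .
#> <http://purl.obolibrary.org/obo/UBERON_0002101> <http://www.w3.org/2004/02/skos/core#relatedMatch> <https://uts.nlm.nih.gov/uts/umls/concept/C0015385> .
```

Generate a synthetic two-vocabulary corpus and check that the lexical
matcher recovers the ground truth exactly when labels carry no noise:

```r
corpus <- generate_corpus(corpus_spec(n_namespaces = 2, n_concepts = 50,
                                      p_synonym = 0, seed = 1))
pred <- lexical_match(corpus$labels$NS1, corpus$labels$NS2,
                      curie_map = corpus$curie_map)
evaluate_mappings(pred, corpus$truth)
#> precision    recall        f1
#>         1         1         1
```

Precision and recall of 1 mean every one of the 50 true cross-vocabulary
pairs was found and nothing spurious was emitted.

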