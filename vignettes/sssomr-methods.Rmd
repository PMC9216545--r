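---
title: "Working with SSSOM mapping sets: model, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working with SSSOM mapping sets: model, methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sssomr)
```

## The problem

Biomedical databases and ontologies assign their own identifiers to the
same real-world concepts: a single anatomical structure may be `FMA:24875`
in one resource, `UBERON:0002101` in another and `MA:0000007` in a third.
Integrating data across such resources requires *mappings* — directed
subject–predicate–object correspondences between terms — and, just as
importantly, the metadata that makes a mapping interpretable: is it exact
or merely related? Who or what established it, when, with what confidence,
and on which evidence? The Simple Standard for Sharing Ontological Mappings
(SSSOM) answers this with a flat, tabular data model: a *mapping set* is a
TSV table of mappings plus a block of set-level metadata, deliberately
consumable by generic data-science toolchains. `sssomr` implements that
model end to end: parsing and writing, validation, conversion to JSON and
RDF, merging and reconciliation, predicate-aware cross-walking and a
lexical matcher that emits fully annotated SSSOM output.

## The data model

A mapping carries up to **38** metadata slots, of which four are required:
`subject_id`, `predicate_id`, `object_id` and `match_type`. A mapping set
carries **23** slots, including `mapping_set_id`, `license`, `creator_id`
and the prefix map. The registry is fixed and interrogable:

```{r}
sssom_slots("mapping")[sssom_slots("mapping")$required, "name"]
nrow(sssom_slots("mapping_set"))
```

The standard names the slot counts and many individual slots, but not the
complete enumeration; the registry in this package fixes one concrete
enumeration consistent with all of those constraints, and treats it as the
package's schema. Likewise, thirteen slots are mapped to external
vocabularies — two to PAV (`author_id` → `pav:authoredBy`, `mapping_date`
→ `pav:authoredOn`), one to PROV-O (`reviewer_id` →
`prov:wasAttributedTo`) and the remainder to Dublin Core terms and RDFS.
Which ten slots fill out the thirteen beyond the documented examples is a
design decision of this package, recorded in `sssom_slots()` as the
`external_property` column. We also count `curie_map` among the 23
set-level slots.

All identifiers are CURIEs, `prefix:local`. Parsing splits at the *first*
colon, so local parts may themselves contain colons. The prefixes `owl`,
`rdfs`, `rdf`, `skos` and `sssom` are builtin — without them the
recommended predicates could not even be written down — and every other
prefix must be declared in the set's `curie_map`. Contraction of an IRI
back to a CURIE uses the longest matching base, ties broken by the
alphabetically smallest prefix.

### Predicates and strength classes

Ten recommended predicates (from SKOS and OWL) are registered, each with a
*strength class* used throughout the package:

```{r}
sssom_predicates()
```

`BROAD` here means the subject is the narrower term (`skos:broadMatch`,
`rdfs:subClassOf`); reading a mapping backwards swaps `BROAD` and `NARROW`
and leaves the symmetric classes fixed. Unregistered predicates are legal —
they classify as `UNKNOWN`, pass through parsing and serialization, and are
flagged by the validator as informational findings; the cross-walker
refuses to traverse them because no composition semantics can be assumed.

`match_type` records *how* a mapping was established — `Lexical`,
`Logical`, `HumanCurated`, `SemanticSimilarity` or `Complex` — and each
type has characteristic companion metadata (match fields and match strings
for lexical matches, a similarity measure for similarity scores), whose
absence the validator reports as warnings rather than errors.

`predicate_modifier` has the single value `Not`: a negated row records an
*explicitly rejected* mapping, so that the absence of a mapping can be
distinguished from a considered-and-rejected one. Negated rows are inert
almost everywhere: they produce no direct RDF triple (asserting
`skos:exactMatch` for a rejected pair would invert its meaning), no graph
edge, and no cardinality count — but they are preserved in the reified RDF
export, where the modifier is stated openly.

## The TSV dialect

A document has a metadata header of commented YAML (every line prefixed
`#`) followed by a plain TSV table whose first row names the mapping-level
columns. Both the embedded mode (one file) and the external mode (YAML in
a side file) are supported and interconvert losslessly.

Decisions the format specification leaves open, fixed here:

* **No quoting dialect.** Tabs and newlines are illegal inside cells, as
  are cell values starting with `#`; the writer rejects them instead of
  quoting. This keeps every SSSOM file readable by `read.delim`,
  `pandas.read_csv` and any other generic TSV reader, which is the point
  of the format.
* **Multivalued slots** serialize with the `|` delimiter, so `|` is in turn
  illegal inside a multivalued value.
* **Canonical output.** Header keys are written alphabetically; columns in
  registry declaration order, restricted to populated slots plus the four
  required ones; numbers formatted to 15 significant digits. The same set
  always produces identical bytes, and `write(parse(x))` is a fixed point.
* **Strict vs lenient.** Unknown columns are errors in strict mode
  (default); in lenient mode they are warned about and their values are
  preserved concatenated into the free-text `other` slot, so no data is
  silently dropped.
* `#` only introduces metadata *before* the column header row; there are
  no inline comments.

Dates must be ISO-8601 (`YYYY-MM-DD`). Unambiguous long forms such as
`"1 January 2020"` are normalized on input; anything else is rejected
rather than guessed at.

Note that the constructors (`make_mapping()`) enforce type invariants at
build time, so vocabulary and range violations cannot arise through this
package's own writing path; the validator's corresponding rules (R05, R07,
R10, R11) exist for tables assembled elsewhere and handed over as data.

## Validation

`validate_sssom()` applies a fixed rule table (`sssom_rules()`) and returns
findings as data — code, severity, locus, message — never as exceptions.
Severity assignments are package decisions: a missing license is a
`WARNING` (the standard lists `license` among the set slots without
declaring it mandatory), an unrecommended predicate is `INFO`, and the
preprocessing-without-match-field hazard (see the matcher section) is a
`WARNING` lint rather than a hard failure.

## RDF and JSON exports

Three RDF profiles are emitted as sorted N-Triples (deterministic bytes):

* **direct** — one plain triple per non-negated row, duplicates collapsed;
* **reified** — one fresh annotation node per row using the `owl:Axiom`
  annotation pattern (`owl:annotatedSource/Property/Target`), plus one
  triple per populated metadata value, through the external property where
  one exists and through the `https://w3id.org/sssom/` namespace
  otherwise. The reification pattern itself is a package decision; the
  standard names RDF/OWL outputs without fixing one.
* **owl** — the reified profile plus one `rdf:type` declaration per mapped
  entity, with the kind derived from the predicates it appears under
  (`owl:Class` for class-level predicates, `owl:NamedIndividual` for
  `owl:sameAs`, `owl:ObjectProperty` for the property predicates). SKOS
  predicates default to the class kind — the dominant use across OBO
  ontologies — with `default_kind` exposed for other corpora. An entity
  appearing under predicates of conflicting kinds is an error rather than
  a silent pick.

These profiles obey two countable contracts, used as test oracles: the
direct triple count equals the number of distinct non-negated
(subject, predicate, object) rows, and the reified count equals
$\sum_{\text{rows}} (4 + \#\text{populated metadata values})$.

## Merging, deduplication and reconciliation

`sssom_merge()` concatenates sets, merges prefix maps (clashes are errors,
never silent overrides) and records the source set identifiers in
`see_also`. `sssom_dedup()` removes only rows identical on *every*
populated slot: rows sharing (s, p, o) but differing in match evidence are
distinct mapping rules and survive. `collapse_rules()` is the inverse
operation — rule rows merge into one mapping with the maximum confidence,
the unanimous match type (else `Complex`), and unioned evidence slots.

`reconcile_unique_object()` enforces the harmonization discipline used by
curated disease terminology efforts: among non-negated EXACT-class rows,
no object term may remain mapped from more than one subject. Winners are
chosen by confidence, then match-type rank (`HumanCurated` > `Logical` >
`Lexical` > `SemanticSimilarity` > `Complex` — only the top of this
ranking is implied by practice; the rest of the order is a package
decision), then smallest subject. A row without a confidence ranks below
any row with one. Losers are *materialized* as negated rows with an
explanatory comment rather than dropped, following the principle that
rejections should be explicit; the uniqueness constraint is scoped to the
EXACT class, since broader/narrower mappings legitimately fan in.

## Cross-walking and the composition algebra

`sssom_neighbors()` derives indirect correspondences by chaining mappings.
The standard requires that chaining be possible "where allowed by the
semantics of the predicate" but defines no algebra; the composition table
here is therefore the central design decision of the module:

* `EXACT` is the two-sided identity;
* `BROAD∘BROAD = BROAD` and `NARROW∘NARROW = NARROW` (subsumption chains);
* `CLOSE∘CLOSE = RELATED` — SKOS declares close matches non-transitive, so
  two close hops deliberately degrade;
* everything else (mixing `BROAD` with `NARROW`, any chain through
  `RELATED` other than via `EXACT`) is undefined, and an undefined step
  kills the whole path. This is conservative on purpose: no inference
  through vague links.

Search enumerates *simple* paths only (no node revisits), which prevents
strength inflation around cycles; each entity is reported at its minimum
distance with the strongest strength among minimal-distance paths, ties
broken by the lexicographically first path (and, for parallel edges that
share a path, the alphabetically first strength name). Obsolete terms are
supplied as a plain list and excluded at graph construction; the package
deliberately does not consult live ontologies to discover them. Graph
filtering drops rows below a confidence threshold, but rows *without* a
confidence pass — absence of a score is not evidence of a bad mapping.

## The lexical matcher

`lexical_match()` consumes flat three-column label tables
(`entity_id`, `field`, `text`) rather than OWL ontologies, which keeps the
module free of ontology parsing. Two records match when their preprocessed
texts are equal, and every (field, field) agreement becomes its own output
row — one row per mapping rule — carrying the match fields, the shared
match string, the preprocessing steps and a confidence.

Preprocessing steps are `lowercase`, `strip_nonalphanumeric`,
`strip_digits` and `collapse_whitespace`, applied in the order given.
`strip_digits` exists to make the classic hazard expressible: "Alzheimer
2" and "Alzheimer 3" are different diseases, and stripping digits matches
them misleadingly. Under the default steps the pair does not match; with
digit stripping enabled the match is emitted *with the preprocessing slots
populated*, so the hazard is visible to any consumer that reads them —
which is exactly why the validator lints preprocessing-without-match-field.

The confidence scheme is declared, not reconstructed from any reference
matcher: label/label pairs score 0.9, label/synonym 0.8, synonym/synonym
0.7, minus 0.05 per destructive preprocessing step
(`strip_nonalphanumeric`, `strip_digits`) in effect. The scale is ordinal —
it ranks evidence quality for downstream filtering and reconciliation and
claims nothing probabilistic. Weights are overridable per field pair in
`match_config()`.

## The synthetic corpus generator

`generate_corpus()` emulates K vocabularies naming the same N concepts:
unique pronounceable base labels, one entity per namespace per concept,
per-namespace noise (random case flips, inserted punctuation, digit
suffixes — each applied to a label with probability `p_noise`, default
0.5), and optional synonym records with probability `p_synonym`. The
ground truth contains every cross-namespace pair, oriented from the lower
to the higher namespace index so that evaluation is deterministic. The
same seed yields byte-identical output, and generated truth sets always
pass validation with no errors.

What the generator does *not* emulate: realistic biomedical label
distributions, multilingual labels, homonyms (distinct concepts sharing a
label), partial concept overlap between vocabularies, or wrong
ground-truth entries. Matcher recovery of 1.0 precision and recall on a
noise-free corpus therefore demonstrates correctness of the matching
machinery, not expected performance on real terminologies, where homonymy
and near-miss labels dominate the error budget.

`evaluate_mappings()` compares unordered subject–object pairs restricted
to non-negated EXACT-class rows and returns precision, recall and F1,
scoring 0 on degenerate inputs.

## Problem sizes and numerical choices

The test suite checks the serialization round trip on 200 randomly
populated sets, cross-walking against an exhaustive simple-path oracle on
100 random graphs of up to 12 nodes, reconciliation invariants on 50
collapsed random sets, the triple-count contracts on 100 sets, and matcher
recovery on a 2-namespace, 50-concept noise-free corpus — sizes at which
the brute-force oracles are still exact. Confidence and similarity scores
are constrained to [0, 1] (the standard states no range; every published
use we model treats them as unit-interval scores). Set equality is
field-level with a 1e-12 numeric tolerance; serialized numbers carry 15
significant digits, so the TSV round trip is exact for any realistically
quantized confidence.

## Known limitations

* Complex mappings (expression-valued subjects or objects) and contextual
  or conditional mappings are out of scope, as is probabilistic
  reconciliation over ontology axioms.
* The validator checks structure and vocabulary, not semantics against
  live ontologies; obsolete-term knowledge must be supplied by the caller.
* The 38/23-slot enumeration and the 13 external property targets are a
  concrete consistent choice, not normative text, and may need adjustment
  as the upstream schema evolves.
* The crosswalk returns one witness path per entity, not all of them; the
  composition algebra is intentionally conservative and will miss chains a
  more permissive semantics would accept.
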