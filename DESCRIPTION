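Package: sssomr
Title: Parse, Validate, Convert and Reconcile SSSOM Ontology Mappings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the Simple Standard for Sharing Ontological Mappings
    (SSSOM). Reads and writes the SSSOM TSV format in embedded and external
    metadata modes, manages CURIE prefix maps, validates mapping sets against
    the SSSOM metadata schema, converts sets to JSON and to direct, reified
    or OWL-conformant RDF (N-Triples), merges and deduplicates mapping sets,
    computes mapping cardinality, reconciles sets under a unique-object
    constraint with explicitly recorded rejections, performs predicate-aware
    cross-walks over mapping graphs, and generates SSSOM output from a
    lexical label matcher. A seeded synthetic-corpus generator makes every
    operation testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
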