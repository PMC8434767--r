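Package: nrcshred
Title: Nested-Collection Query Compilation with Shredding and Skew-Aware Execution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale nested relational calculus (NRC) over bags of tuples,
    with two compilation routes to a flat dataflow algebra: flattening-based
    "standard" compilation (outer-flatten with NULL padding and unique-id
    re-nesting) and "shredded" compilation (flat per-level programs linked by
    label dictionaries with foreign-key semantics). Plans execute on a simulated
    partitioned runtime that accounts shuffle and broadcast volume and supports
    skew-resilient heavy-key handling (full/partial/sample/slice detection and
    broadcast joins). Ships a suite of multi-omics analysis programs (mutational
    burden, cancer driver-gene scoring over mutation, copy-number, network and
    expression data) and a synthetic multi-omics data generator with
    controllable nesting, empty-bag probability, key skew and annotation
    sharing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
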