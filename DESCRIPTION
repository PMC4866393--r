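Package: coexshift
Title: Differential Coexpression Analysis Across a Two-Condition Boundary
Version: 0.1.0
Authors@R:
    person("coexshift", "developers", email = "coexshift@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and characterise modular rewiring of gene
    coexpression networks between two biological conditions (for example
    prenatal versus postnatal brain development). Implements clustering of
    expression profiles and of whole coexpression structures, a weighted
    differential-coexpression pipeline (signed squared correlation
    differences, soft thresholding, topological overlap, adaptive dendrogram
    cutting and eigengene-based module merging), permutation significance of
    module rewiring, module-wise gene-set enrichment with resampling nulls,
    transcription-factor motif exclusivity tests, and condition-specific
    network edge extraction. Ships a ground-truthed synthetic-data generator
    with planted rewired modules used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
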