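Package: mitoscreen
Title: Pan-Cancer Single-Cell Screen for Mitochondrial Genes Linked to
    CD8+ T-Cell Exhaustion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing mitochondria-related genes
    associated with CD8+ T-cell exhaustion across cancer types. Assembles a
    multi-source mitochondrial gene universe, performs per-cancer-type
    Wilcoxon differential expression between exhausted and non-exhausted
    CD8+ T cells with Benjamini-Hochberg correction, combines evidence
    across cancers by Fisher's method, scores genes by cross-cancer
    enrichment, correlation with an exhaustion signature (PDCD1, CTLA4,
    HAVCR2, LAG3, TOX), and universality, and ranks final candidates.
    Companion modules compute Human-Protein-Atlas-style expression
    specificity over cell-type TPM tables, pathway dysregulation scores
    with a permutation null on tumor/normal cohorts after quantile
    normalization, and the closed-form assay quantities (killing
    efficiency, bead-normalized proliferation, tumor volume, standard-curve
    calibration). Seeded synthetic-data generators emulate every input so
    all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    limma,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
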