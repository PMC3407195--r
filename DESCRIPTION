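Package: acechip
Title: Promoter ChIP-chip Analysis of Histone H3 Acetylation and Its
    Coupling to Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for acetylated-histone-H3 (H3K9K14ac)
    ChIP-chip promoter tiling arrays compared between two conditions
    (wild-type and transgenic striatum). Calls bound probes from
    per-probe enrichment p-values, aggregates them to gene-level binding
    profiles and location signatures, computes a per-gene composite
    differential-acetylation score with five-way categorisation, makes
    gene-level expression and differential-expression calls, and
    cross-tabulates binding against expression with odds ratios, Wald
    confidence intervals and Fisher exact tests. Includes a synthetic
    promoter-array study generator with ground truth for calibration and
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
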