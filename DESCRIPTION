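Package: trscore
Title: Weighted-Median Transcriptomic Risk Scores with Survival
    Validation and FFPE Signature Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and validating prognostic gene-expression
    signatures in prostate cancer and similar settings. Computes a
    weighted-median transcriptomic risk score (TRS) from gene-wise
    z-scores, refines signatures for formalin-fixed paraffin-embedded
    (FFPE) material via specimen-age regression and external-cohort
    consistency filters, validates scores with Kaplan-Meier, log-rank,
    (weighted, multivariable) Cox regression and Harrell's concordance,
    builds matched random-gene-set null distributions, combines per-gene
    effects across cohorts by random-effects meta-analysis, benchmarks
    direction-annotated signatures, scores single cells and spatial
    spots, and ships a synthetic-cohort generator with known ground
    truth so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    metafor,
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
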