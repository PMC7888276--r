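Package: crpmr
Title: One-Sample Mendelian Randomization of C-Reactive Protein and
    Time-to-Breast-Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Instrument curation and one-sample Mendelian-randomization
    analysis of a genetically predicted exposure (C-reactive protein) on a
    time-to-event outcome (incident invasive breast cancer). Provides
    quality-control and linkage-disequilibrium pruning of genetic
    instruments, cross-study harmonisation, weighted polygenic scores with
    rescaling to the exposure unit, per-variant Cox proportional-hazards
    estimation with Schoenfeld diagnostics and fixed-effect meta-analysis
    across sub-studies, summary-statistic estimators (inverse-variance
    weighted, weighted median, penalized weighted median, MR-Egger,
    Cochran's Q), a gene-environment-interaction corrected estimate, and
    lifestyle- and subtype-stratified pipelines with Benjamini-Hochberg
    correction. A calibrated survival-cohort simulator reproduces the
    statistical structure the method assumes so that every stage is
    testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
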