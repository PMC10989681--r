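Package: mrscreen
Title: Bidirectional Two-Sample Mendelian Randomization Screening of
    GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening a panel of traits against a disease
    outcome with bidirectional two-sample Mendelian randomization from
    GWAS summary statistics. Covers reading and validation of summary
    statistics, effect-allele harmonization with an explicit palindromic
    policy, instrument selection by p-value threshold and greedy
    linkage-disequilibrium clumping, instrument strength (R-squared and
    F-statistic), causal estimation by Wald ratios, fixed- and
    multiplicative random-effects inverse-variance weighting, MR-Egger
    regression and the weighted median with a parametric bootstrap
    standard error, sensitivity diagnostics (Cochran's Q, the Egger
    intercept test, an MR-PRESSO global and per-variant outlier test,
    leave-one-out), Benjamini-Hochberg false-discovery-rate control over
    the trait family, tabular report export, and a seeded synthetic
    summary-statistics generator with known causal structure for
    calibration and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    withr,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
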