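Package: mrchain
Title: Two-Sample Mendelian Randomization with Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: instrument selection by genome-wide significance, greedy LD
    clumping and per-variant F-statistics; effect-allele harmonization with
    palindrome handling; inverse-variance weighted (fixed, random and
    heterogeneity-gated), MR-Egger, weighted-median and weighted-mode causal
    estimators; Cochran's Q, Egger-intercept, leave-one-out, funnel and
    MR-PRESSO diagnostics; multivariable MR by weighted least squares;
    two-step mediation with product-of-coefficients decomposition,
    delta-method confidence intervals and Benjamini-Hochberg screening of
    candidate mediators; plus a summary-statistics simulator with known
    causal ground truth and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
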