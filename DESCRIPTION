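Package: mrmediate
Title: Two-Sample, Multivariable and Mediation Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument selection (association p-value threshold,
    greedy LD clumping, per-SNP F-statistic filter, exclusion lists), allele
    harmonization with palindromic-SNP handling, five causal estimators
    (inverse-variance weighted, MR-Egger, weighted median, simple mode and
    weighted mode), multivariable MR, sensitivity diagnostics (Cochran's Q,
    Egger-intercept pleiotropy test, leave-one-out), two-step mediation MR
    with delta-method intervals for the mediated proportion, and a synthetic
    summary-statistics generator with known ground truth for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
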