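Package: admr
Title: Two-Sample Mendelian Randomization of Atopic Dermatitis on
    Cardiovascular Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization from
    GWAS summary statistics: instrument selection (genome-wide significance,
    LD pruning, minor-allele-frequency and confounder filters), allele
    harmonization with palindromic-variant resolution and proxy
    substitution, causal estimation (Wald ratio, inverse-variance weighted
    in fixed- and multiplicative random-effects form, weighted median,
    MR-Egger), pleiotropy diagnostics (Cochran's Q, the Egger intercept
    test, MR-PRESSO global/outlier/distortion tests, leave-one-out),
    fixed-effect meta-analysis across outcome datasets, Bonferroni
    classification, and analytical power calculation for binary outcomes.
    Includes a synthetic summary-statistics generator with known ground
    truth so every stage is testable without consortium downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
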