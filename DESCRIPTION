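Package: mrcohort
Title: One-Sample, Non-Linear and Within-Sibling Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for Mendelian randomization (MR) analyses of cohort data
    using a weighted genetic risk score as the instrument: two-stage least
    squares for continuous outcomes and two-stage ("2SPS") logistic models
    for binary outcomes with robust standard errors, Fisher z tests for sex
    differences, summary-statistic pleiotropy sensitivity estimators
    (inverse-variance weighted, MR-Egger, weighted median), non-linear MR
    over strata of instrument-free exposure with piecewise-linear effect
    curves and non-linearity tests, and within-sibling non-genetic and MR
    estimators based on family centring. Includes a synthetic cohort
    generator with Hardy-Weinberg genotypes, Mendelian transmission within
    sibships, individual-level confounding, dynastic effects and assortative
    mating, so that every estimator can be validated by parameter recovery
    against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    metafor,
    jsonlite
Config/testthat/edition: 3
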