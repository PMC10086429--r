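Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit built
    around GWAS summary statistics: instrument selection (p-value
    thresholding, greedy LD clumping, proxy substitution, F-statistics),
    allele harmonization with frequency-based resolution of palindromic
    variants, univariable estimators (inverse-variance weighted, MR-Egger,
    weighted and penalized weighted median, maximum likelihood, radial IVW)
    with heterogeneity and pleiotropy diagnostics, MR-PRESSO outlier
    detection, SIMEX correction for regression dilution, multivariable MR
    (IVW, Egger, Q-heterogeneity minimization), and two-step MR mediation
    with delta-method uncertainty and proportions mediated. Includes a
    synthetic GWAS generator with known causal structure so every stage is
    testable without external data, and a pipeline orchestrating the full
    analysis from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
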