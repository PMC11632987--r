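Package: mrpath
Title: Two-Step Two-Sample Mendelian Randomization with Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: allele harmonization, instrument selection
    (p-value filter, greedy LD clumping, F-statistic filter), five causal
    estimators (Wald ratio, inverse-variance weighted, MR-Egger, weighted
    median, mode-based), heterogeneity and pleiotropy diagnostics
    (Cochran's Q, Egger intercept, MR-PRESSO, leave-one-out), reverse-MR
    screening, and product-of-coefficients mediation with mediated
    proportions. Includes a seeded simulator of three-trait GWAS summary
    statistics with a latent exposure-mediator-outcome causal system, so
    the whole pipeline can be exercised without downloading data.
License: MIT
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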