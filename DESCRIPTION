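Package: mrpipe
Title: Two-Sample Mendelian Randomization with Harmonization, Diagnostics,
    and Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-sample Mendelian
    randomization from GWAS summary statistics: instrument selection at
    genome-wide significance, allele harmonization (strand flips,
    palindromic resolution, LD-proxy substitution), instrument-strength
    diagnostics (per-SNP variance explained, F-statistics) and binary-outcome
    power, univariable causal estimators (random-effects inverse-variance
    weighted, weighted median, MR-Egger) with Cochran Q / I-squared
    heterogeneity and pleiotropy checks, multivariable MR for direct effects,
    and two-step mediation via the product-of-coefficients method with
    delta-method standard errors. Includes a synthetic summary-statistics
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
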