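Package: longscan
Title: Scan Protein Alignments for Longevity-Selected Positions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects alignment columns conserved in long-lived but not
    short-lived mammals ("longevity-selected positions"). Implements
    sliding-window masking of divergent subsequences, column
    classification, mutation-rate-corrected BLOSUM similarity scoring
    against a long-lived reference species, per-column phylogenetic
    generalized least squares (PGLS) regression of similarity on maximum
    lifespan and body mass under a Brownian-motion covariance, a
    trait-permutation randomized control, and downstream summaries
    (p-value density diagnostics, secondary-structure composition
    chi-squared tests, domain aggregation, rolling-window median p-values,
    and region residue-count regressions). A synthetic-data generator
    produces ultrametric trees, correlated Brownian life-history traits,
    and alignments with conserved, neutral, and trait-coupled columns for
    end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
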