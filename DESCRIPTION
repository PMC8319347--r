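Package: syntrophevo
Title: Statistical Machinery for Experimental Evolution of Syntrophic Cocultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for two-species syntrophic coculture evolution
    experiments. Implements per-gene and genome-wide G-scores for parallel
    evolution with a randomization null and Z-score, margin-preserving
    permutation tests on longitudinal mutation-frequency trajectories
    (co-occurrence, simultaneous and nested fixation, cross-species selective
    sweeps), multi-caller variant consensus filtering and impact
    classification, single-cell mutation-matrix construction and
    maximum-likelihood mutation-tree inference under a false-positive /
    allelic-dropout error model, logistic and Gompertz growth-kinetics
    estimation for dilution and pairing assays, and Excess-over-Bliss synergy
    scoring with propagated error. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
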