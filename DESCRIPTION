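Package: dmnet
Title: Graph-Theoretic Analysis of Resting-State Functional Connectivity
    in the Rodent Default Mode Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for resting-state functional
    connectivity analysis of region-of-interest (ROI) BOLD time series,
    built around the 12-node rodent default mode network. Provides a
    synthetic cohort generator with known ground-truth correlation
    structure, temporal preprocessing (linear detrending, zero-phase
    0.01-0.08 Hz band-pass filtering, motion-parameter nuisance
    regression, and motion-based subject exclusion), Pearson
    functional-connectivity matrices, weighted graph metrics (global,
    local, and nodal efficiency, clustering coefficient, characteristic
    path length) across proportional sparsity thresholds, small-world
    indices against degree-preserving random-network null models, and
    group comparison via the network-based statistic (NBS) permutation
    test and Benjamini-Hochberg false-discovery-rate correction.
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
    igraph,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
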