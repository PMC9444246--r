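Package: tm2d
Title: Two-Dimensional Template Matching and SNR-Ratio Classification for Cryo-EM Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale engine for locating and classifying structurally
    related macromolecular complexes in 2D cryo-electron microscopy images.
    Implements exhaustive two-dimensional template matching (2DTM) with a
    whitened matched filter producing per-pixel signal-to-noise ratio (SNR)
    maps, extreme-value false-positive thresholds, local pose refinement and
    fixed-pose SNR evaluation; multi-template log2 SNR-ratio comparison at
    matched poses with an extreme-value noise-bias correction; a
    maximum-likelihood Gaussian-mixture classifier with Bayes-rule posterior
    confidences; template-truncation occupancy probing; and a synthetic
    phantom/micrograph simulator with planted ground truth so every stage is
    testable without external data. MRC2014 volumes and micrographs are read
    and written natively; all tabular results are tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
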