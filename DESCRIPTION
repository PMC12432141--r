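Package: caeqc
Title: Autoencoder-Based Artifact Screening for Quantitative Fluorescence
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised quality control for sparse point-signal
    fluorescence microscopy images (e.g. surface-based fluorescence
    intensity distribution analysis imaged by TIRF microscopy).
    Raw 14-bit frames are blurred, background-zeroed at five standard
    deviations above the mean, block-mean downsampled and normalized; a
    compact convolutional autoencoder is trained on artifact-free images
    only; each image is scored by its image reproduction error (the
    99.99th percentile of squared per-pixel reconstruction errors) and
    flagged as artifact-laden beyond a dataset-adaptive quantile
    threshold. Includes a seeded synthetic image generator, balanced
    bootstrap ROC/AUC evaluation via single-feature logistic regression,
    and tidy accessors and plots for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
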