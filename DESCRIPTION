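Package: hcaclassify
Title: Brain-Injury State Classification from Home-Cage Behavioural Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the injury state (naive, brain-injured, sham) of
    group-housed mice from four-channel home-cage behavioural time series
    recorded at 15-minute resolution. Implements the full analysis pipeline:
    a seeded cosinor-based synthetic cohort generator, HCA-style CSV import
    and export, binning and featurisation of weekly recordings, continuous
    wavelet transform scaleograms, a dual-branch convolutional plus LSTM
    sequence classifier written in base matrix operations, shallow baselines
    (support vector machine, depth-limited random forest, feed-forward
    network), class-imbalance handling via class weights and SMOTE, and
    leakage-safe leave-one-out cross-validation with macro-averaged metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
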