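Package: harsdae
Title: Human Activity Recognition with Stacked Denoising Autoencoders and
    Boosted K-Fold Gradient Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying human activities (walking, postures,
    elevator and escalator riding) from multichannel smartphone inertial
    sensor recordings. Fixed-length sliding windows are min-max standardised
    and fed to one stacked denoising autoencoder per sensor; the learned
    features from all sensors are concatenated and classified by a boosting
    k-fold ensemble of gradient-boosted decision trees in which samples
    misclassified in one fold's validation set are duplicated into the next
    fold's training set, with final predictions by majority vote. Includes
    within/between-class scatter diagnostics of feature separability,
    single-autoencoder softmax and hand-crafted-feature baselines,
    macro-averaged evaluation metrics, a reader for the UCI smartphone
    activity-recognition layout, and a synthetic inertial-sensor data
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
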