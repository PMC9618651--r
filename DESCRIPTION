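Package: gaitattn
Title: Branched Recurrent Networks with Temporal Attention for Continuous Limb Motion Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates a target limb's resultant acceleration from wearable
    inertial-sensor channels measured on complementary body segments, using
    stacked (bidirectional) long short-term memory networks with an optional
    two-stage temporal attention mechanism and per-output branched dense
    heads. Provides a synthetic multi-subject gait-signal generator with a
    known input-to-target coupling, the full sliding-window preprocessing
    pipeline (target smoothing, subject-disjoint splitting, training-set
    normalization), mean-absolute-percentage-error training with plateau
    learning-rate decay and early stopping, per-output accuracy metrics
    (NRMSE, MAE, MAPE), and FFT band-power tools for assessing the spectral
    robustness of model predictions.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
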