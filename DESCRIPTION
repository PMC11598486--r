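Package: tremorcast
Title: Prediction and Suppression of Physiological Hand Tremor with
    EEMD, an Improved Whale Optimizer and LSTM Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forecasting physiological hand-tremor time series and
    cancelling the predicted tremor from a measured control signal. The
    measured signal is modelled as desired motion plus tremor; the tremor is
    decomposed by ensemble empirical mode decomposition (EEMD) into intrinsic
    mode functions, each mode is forecast one step ahead by a peephole LSTM
    network whose hyperparameters are tuned by a whale optimization algorithm
    with quasi-opposition initialization, adaptive weighting and Gaussian
    elite mutation, and the summed forecast is subtracted from the measured
    signal to recover the desired motion. Includes a seedable synthetic
    tremor generator, the four standard forecast metrics (R-squared, MAE,
    MSE, SMAPE), baseline models (plain LSTM, untuned EEMD-LSTM, ARMA) and
    plotting helpers.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
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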