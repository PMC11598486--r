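# End-to-end decompose / tune / forecast / suppress orchestration.
# The tremor series is decomposed by EEMD, each mode (and the residual) gets
# its own LSTM forecaster tuned by the improved whale optimizer, the
# per-mode forecasts are summed, and the summed tremor forecast is
# subtracted from the measured signal to recover the desired motion.

#' Search space for the four tuned forecaster hyperparameters
#'
#' Epochs and hidden units are integer dimensions; learning rate and L2
#' weight are searched on a log10 scale.
#'
#' @param epochs,hidden_units,learning_rate,l2_lambda Length-2 numeric
#'   bounds per hyperparameter.
#' @return A [search_space()] with dimensions named `epochs`,
#'   `hidden_units`, `learning_rate`, `l2_lambda`.
#' @export
forecaster_search_space <- function(epochs = c(10, 200),
                                    hidden_units = c(4, 128),
                                    learning_rate = c(1e-4, 1e-2),
                                    l2_lambda = c(1e-6, 1e-2)) {
  search_space(lower = c(epochs[1], hidden_units[1], learning_rate[1], l2_lambda[1]),
               upper = c(epochs[2], hidden_units[2], learning_rate[2], l2_lambda[2]),
               integer = c(TRUE, TRUE, FALSE, FALSE),
               log = c(FALSE, FALSE, TRUE, TRUE),
               names = c("epochs", "hidden_units", "learning_rate", "l2_lambda"))
}

#' Pipeline configuration
#'
#' @param train_fraction Chronological fraction of the series used for
#'   training; default 0.7 (70/30 split).
#' @param window Forecaster input step length; default 12.
#' @param activation Activation layer for every forecaster; default tanh.
#' @param ensemble_size,noise_sd_ratio,max_imfs EEMD settings (see
#'   [eemd()]).
#' @param iwoa_n,iwoa_max_t Whale-optimizer population size and iteration
#'   budget; defaults 10 and 30.
#' @param bounds Hyperparameter [search_space()]; default
#'   [forecaster_search_space()].
#' @param base_spec An [lstm_spec()] used for the untuned models (plain
#'   LSTM and untuned EEMD-LSTM) and as the non-tuned fields of tuned
#'   specs.
#' @param decomposition_mode `"full_series"` (decompose the whole series,
#'   then split windows chronologically; mirrors the method's original workflow but
#'   lets the non-causal decomposition see test samples) or `"train_only"`
#'   (decompose only the training prefix and extend causally over the test
#'   tail by re-decomposing the history before each test point; slower,
#'   leakage-free).
#' @param target Which component the forecasters model: the tremor series
#'   (default) or the raw actual signal.
#' @param seed Integer seed governing every random draw in the pipeline.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(train_fraction = 0.7,
                            window = 12,
                            activation = "tanh",
                            ensemble_size = 100,
                            noise_sd_ratio = 0.2,
                            max_imfs = Inf,
                            iwoa_n = 10,
                            iwoa_max_t = 30,
                            bounds = forecaster_search_space(),
                            base_spec = NULL,
                            decomposition_mode = c("full_series", "train_only"),
                            target = c("tremor", "actual"),
                            seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  decomposition_mode <- match.arg(decomposition_mode)
  target <- match.arg(target)
  if (is.null(base_spec)) {
    base_spec <- lstm_spec(window = window, activation = activation, seed = seed)
  }
  structure(list(train_fraction = train_fraction, window = as.integer(window),
                 activation = activation, ensemble_size = ensemble_size,
                 noise_sd_ratio = noise_sd_ratio, max_imfs = max_imfs,
                 iwoa_n = iwoa_n, iwoa_max_t = iwoa_max_t, bounds = bounds,
                 base_spec = base_spec, decomposition_mode = decomposition_mode,
                 target = target, seed = seed),
            class = "pipeline_config")
}

# All component series of a decomposition, residual last.
decomposition_components <- function(imfset) {
  comps <- c(as.list(as.data.frame(imfset$imfs)), list(res = imfset$residual))
  comps[lengths(comps) > 0]
}

# Windows for one component under the config's decomposition mode. In
# full_series mode the component spans the whole series and rows are split
# chronologically; in train_only mode the component covers the training
# prefix only, so every row is a training row.
component_windows <- function(series, config) {
  tf <- if (config$decomposition_mode == "full_series") config$train_fraction else 1
  build_windows(series, config$window, train_fraction = tf)
}

#' Tune and train one forecaster per decomposition component
#'
#' For every IMF and the residual, the whale optimizer searches the
#' four-dimensional hyperparameter space; each candidate is scored by
#' training a forecaster on the first 80% of the component's training
#' windows and measuring mean squared error on the last 20% (the validation
#' tail), so tuning never touches test data. The best candidate is then
#' retrained on the full training portion. With `tune = FALSE` every
#' component uses `config$base_spec` unchanged (the untuned EEMD-LSTM
#' baseline).
#'
#' @param imfset An `"imf_decomposition"` of the (training regime of the)
#'   target series.
#' @param config A [pipeline_config()].
#' @param tune Run the whale optimizer per component (default) or use the
#'   base spec.
#' @return A list of class `"component_models"`: `models` (one
#'   `"lstm_forecaster"` per component), `specs`, `curves` (tibble of
#'   per-component elite fitness per iteration, empty when `tune = FALSE`),
#'   and `component` names.
#' @export
fit_component_models <- function(imfset, config, tune = TRUE) {
  stopifnot(inherits(imfset, "imf_decomposition"),
            inherits(config, "pipeline_config"))
  comps <- decomposition_components(imfset)
  models <- vector("list", length(comps))
  specs <- vector("list", length(comps))
  curves <- list()
  for (ci in seq_along(comps)) {
    series <- comps[[ci]]
    if (length(series) < config$window + 2) {
      abort(sprintf("Component %d (%s) is too short (%d samples) for window %d.",
                    ci, names(comps)[ci], length(series), config$window))
    }
    ds <- component_windows(series, config)
    train_rows <- which(ds$is_train)
    spec <- config$base_spec
    if (tune) {
      n_val <- max(1L, floor(0.2 * length(train_rows)))
      val_rows <- tail(train_rows, n_val)
      tune_rows <- setdiff(train_rows, val_rows)
      if (length(tune_rows) < 1) abort(sprintf(
        "Component %d has too few training windows to tune.", ci))
      objective <- function(hp) {
        sp <- lstm_spec(window = config$window,
                        hidden_units = hp[["hidden_units"]],
                        epochs = hp[["epochs"]],
                        learning_rate = hp[["learning_rate"]],
                        l2_lambda = hp[["l2_lambda"]],
                        activation = config$activation,
                        seed = config$seed)
        m <- fit_lstm(ds, sp, rows = tune_rows)
        pred <- predict(m, ds, rows = val_rows)
        mse(pred, ds$targets[val_rows])
      }
      res <- iwoa_minimize(objective, config$bounds, n = config$iwoa_n,
                           max_t = config$iwoa_max_t,
                           seed = child_seed(config$seed, 1000 + ci))
      hp <- res$best_position
      spec <- lstm_spec(window = config$window,
                        hidden_units = hp[["hidden_units"]],
                        epochs = hp[["epochs"]],
                        learning_rate = hp[["learning_rate"]],
                        l2_lambda = hp[["l2_lambda"]],
                        activation = config$activation,
                        seed = config$seed)
      curves[[ci]] <- dplyr::mutate(res$curve, component = names(comps)[ci],
                                    .before = 1)
    }
    models[[ci]] <- fit_lstm(ds, spec, rows = train_rows)
    specs[[ci]] <- spec
  }
  structure(list(models = setNames(models, names(comps)),
                 specs = setNames(specs, names(comps)),
                 curves = if (length(curves)) dplyr::bind_rows(curves) else
                   tibble(component = character(0), iteration = integer(0),
                          fitness = numeric(0)),
                 component = names(comps)),
            class = "component_models")
}

#' Combine per-component forecasts into the final prediction
#'
#' Predicts one step ahead for every held-out row of every component and
#' sums the component forecasts element-wise.
#'
#' @param models A `"component_models"` from [fit_component_models()].
#' @param imfset The `"imf_decomposition"` the models were trained against.
#' @param config A [pipeline_config()].
#' @param rows Which windowed rows to predict: `"test"` (default; the rows
#'   after the chronological split) or `"all"`.
#' @return A tibble with `index` (series index of each prediction), one
#'   column per component, and `forecast` (their sum).
#' @export
forecast_components <- function(models, imfset, config, rows = c("test", "all")) {
  rows <- match.arg(rows)
  stopifnot(inherits(models, "component_models"))
  comps <- decomposition_components(imfset)
  if (length(comps) != length(models$models)) {
    abort(sprintf("Decomposition has %d components but %d models were supplied.",
                  length(comps), length(models$models)))
  }
  out <- NULL
  for (ci in seq_along(comps)) {
    ds <- component_windows(comps[[ci]], config)
    sel <- if (rows == "test") which(!ds$is_train) else seq_along(ds$targets)
    pred <- predict(models$models[[ci]], ds, rows = sel)
    col <- tibble(index = ds$target_index[sel], value = pred)
    names(col)[2] <- models$component[ci]
    out <- if (is.null(out)) col else dplyr::inner_join(out, col, by = "index")
  }
  out$forecast <- rowSums(out[, models$component, drop = FALSE])
  out
}

#' Tremor suppression: subtract the predicted tremor from the actual signal
#'
#' The suppression model recovers the desired control signal as
#' \eqn{e'(k) = a(k) - t'(k)}: the measured actual signal minus the
#' predicted tremor. When the tremor prediction is exact the recovery is
#' exact, and for any prediction the recovery error equals the tremor
#' prediction error sample by sample.
#'
#' @param actual Measured signal \eqn{a(k)}.
#' @param predicted_tremor Predicted tremor \eqn{t'(k)}, same length.
#' @param true_desired Optional known desired signal \eqn{e(k)} for
#'   evaluation.
#' @return A tibble with columns `actual`, `predicted_tremor`, `recovered`
#'   (exactly `actual - predicted_tremor`) and, when supplied, `desired`.
#' @export
suppress_tremor <- function(actual, predicted_tremor, true_desired = NULL) {
  check_numeric_vector(actual, "actual", 1)
  check_numeric_vector(predicted_tremor, "predicted_tremor", 1)
  check_equal_length(actual, predicted_tremor, "actual", "predicted_tremor")
  out <- tibble(actual = actual, predicted_tremor = predicted_tremor,
                recovered = actual - predicted_tremor)
  if (!is.null(true_desired)) {
    check_equal_length(actual, true_desired, "actual", "true_desired")
    out$desired <- true_desired
  }
  out
}

# One-step-ahead ARMA baseline: order selected by AIC on the training
# prefix, one-step predictions on the test tail from the frozen fit.
arma_one_step <- function(series, split, test_index) {
  train <- series[seq_len(split)]
  best <- NULL
  for (p in 0:3) for (q in 0:2) {
    fit <- tryCatch(
      stats::arima(train, order = c(p, 0, q), method = "ML"),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && (is.null(best) || fit$aic < best$aic)) {
      best <- fit
      best$order <- c(p, 0, q)
    }
  }
  if (is.null(best)) return(rep(mean(train), length(test_index)))
  refit <- tryCatch(
    stats::arima(series, order = best$order, fixed = stats::coef(best),
                 include.mean = TRUE, transform.pars = FALSE),
    error = function(e) NULL)
  if (is.null(refit)) return(rep(mean(train), length(test_index)))
  fitted_all <- series - as.numeric(stats::residuals(refit))
  fitted_all[test_index]
}

#' Compare forecasting models on a simulated truth
#'
#' Trains each requested model per axis on the chronological training
#' portion of the target series (the tremor component by default),
#' evaluates one-step-ahead forecasts on the held-out tail with the four
#' standard metrics, and also scores the recovered signal
#' (actual - predicted tremor) against the known desired motion.
#'
#' Models: `"lstm"` (one forecaster on the raw series, base spec),
#' `"eemd_lstm"` (EEMD decomposition, one base-spec forecaster per mode),
#' `"eemd_iwoa_lstm"` (EEMD plus whale-optimizer tuning per mode) and
#' `"arma"` (AIC-selected ARMA one-step baseline).
#'
#' @param truth A `"tremor_truth"` from [simulate_tremor()].
#' @param config A [pipeline_config()].
#' @param models Character subset of
#'   `c("lstm", "eemd_lstm", "eemd_iwoa_lstm", "arma")`.
#' @param axes Axes to evaluate; default all axes in `truth`.
#' @return A list of class `"model_comparison"`: `metrics` (tibble, one
#'   row per model/axis/target with columns `model`, `axis`, `target`,
#'   `n`, `mae`, `mse`, `smape`, `r2`), `predictions` (tibble of per-index
#'   forecasts and observations), and `curves` (whale-optimizer fitness
#'   curves of the tuned model).
#' @export
run_comparison <- function(truth, config,
                           models = c("lstm", "eemd_lstm", "eemd_iwoa_lstm"),
                           axes = NULL) {
  stopifnot(inherits(truth, "tremor_truth"), inherits(config, "pipeline_config"))
  known <- c("lstm", "eemd_lstm", "eemd_iwoa_lstm", "arma")
  bad <- setdiff(models, known)
  if (length(bad) > 0) abort(sprintf("Unknown model(s): %s", paste(bad, collapse = ", ")))
  if (is.null(axes)) axes <- unique(truth$axis)
  metrics <- list()
  preds <- list()
  curves <- list()
  for (ai in seq_along(axes)) {
    ax <- axes[ai]
    sub <- truth[truth$axis == ax, ]
    if (nrow(sub) < 200) abort("Need at least 200 samples per axis.")
    series <- if (config$target == "tremor") sub$tremor else sub$actual
    n <- length(series)
    split <- floor(config$train_fraction * n)
    test_index <- (split + 1):n
    for (mi in seq_along(models)) {
      mod <- models[mi]
      axis_cfg <- config
      axis_cfg$seed <- child_seed(config$seed, 100 * ai)
      axis_cfg$base_spec$seed <- axis_cfg$seed
      res <- switch(
        mod,
        lstm = {
          ds <- build_windows(series, config$window,
                              train_fraction = config$train_fraction)
          m <- fit_lstm(ds, axis_cfg$base_spec)
          sel <- which(!ds$is_train)
          tibble(index = ds$target_index[sel], predicted = predict(m, ds, rows = sel))
        },
        arma = tibble(index = test_index,
                      predicted = arma_one_step(series, split, test_index)),
        eemd_lstm = ,
        eemd_iwoa_lstm = {
          dec_series <- if (config$decomposition_mode == "full_series") series
                        else series[seq_len(split)]
          imfset <- eemd(dec_series, ensemble_size = config$ensemble_size,
                         noise_sd_ratio = config$noise_sd_ratio,
                         seed = axis_cfg$seed, max_imfs = config$max_imfs)
          cm <- fit_component_models(imfset, axis_cfg,
                                     tune = (mod == "eemd_iwoa_lstm"))
          if (mod == "eemd_iwoa_lstm" && nrow(cm$curves) > 0) {
            curves[[length(curves) + 1]] <- dplyr::mutate(cm$curves, axis = ax,
                                                          .before = 1)
          }
          if (config$decomposition_mode == "full_series") {
            fc <- forecast_components(cm, imfset, axis_cfg, rows = "test")
            tibble(index = fc$index, predicted = fc$forecast)
          } else {
            causal_forecast(series, split, cm, axis_cfg)
          }
        })
      res <- res[res$index %in% test_index, ]
      observed <- series[res$index]
      rep_main <- safe_evaluate(res$predicted, observed, mod, ax, "tremor")
      metrics[[length(metrics) + 1]] <- rep_main
      if (config$target == "tremor") {
        sup <- suppress_tremor(sub$actual[res$index], res$predicted,
                               true_desired = sub$desired[res$index])
        metrics[[length(metrics) + 1]] <-
          safe_evaluate(sup$recovered, sup$desired, mod, ax, "recovered")
      }
      preds[[length(preds) + 1]] <- tibble(axis = ax, model = mod,
                                           index = res$index,
                                           predicted = res$predicted,
                                           observed = observed)
    }
  }
  structure(list(metrics = dplyr::bind_rows(metrics),
                 predictions = dplyr::bind_rows(preds),
                 curves = if (length(curves)) dplyr::bind_rows(curves) else NULL),
            class = "model_comparison")
}

# evaluate_forecast, but constant observed series yield NA R-squared
# instead of an error (a tremor-free axis is a legitimate degenerate case).
safe_evaluate <- function(predicted, observed, model_name, axis, target) {
  r2 <- tryCatch(r_squared(predicted, observed), error = function(e) NA_real_)
  tibble(model = model_name, axis = axis, target = target,
         n = length(observed),
         mae = mae(predicted, observed), mse = mse(predicted, observed),
         smape = smape(predicted, observed), r2 = r2)
}

# Leakage-free forecasts for the test tail: before each test index k the
# history series[1:(k-1)] is re-decomposed (plain EMD, aligned to the
# models' component count) and the last `window` values of each component
# form the input windows. Only data observed before k is ever used.
causal_forecast <- function(series, split, models, config) {
  n <- length(series)
  k_targets <- (split + 1):n
  n_comp <- length(models$component)
  preds <- numeric(length(k_targets))
  for (j in seq_along(k_targets)) {
    k <- k_targets[j]
    hist <- series[seq_len(k - 1)]
    dec <- emd(hist, max_imfs = n_comp - 1)
    comps <- decomposition_components(dec)
    total <- 0
    for (ci in seq_len(n_comp)) {
      comp_series <- if (ci <= length(comps)) comps[[ci]] else rep(0, length(hist))
      win <- matrix(tail(comp_series, config$window), nrow = 1)
      total <- total + predict(models$models[[ci]], win)
    }
    preds[j] <- total
  }
  tibble(index = k_targets, predicted = preds)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$metrics, n = Inf)
  invisible(x)
}

#' @export
tidy.model_comparison <- function(x, ...) x$metrics

#' @export
autoplot.model_comparison <- function(object, target = "tremor", ...) {
  sub <- object$predictions
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "grey50",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted, colour = .data$model),
                       linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$axis)) +
    ggplot2::labs(x = "sample", y = "tremor", colour = NULL)
}
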