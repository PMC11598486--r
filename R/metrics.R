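# Forecast evaluation metrics: coefficient of determination, mean absolute
# error, mean squared error and symmetric mean absolute percentage error.

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (\hat y_i - y_i)^2 / \sum_i (\bar y - y_i)^2},
#' where \eqn{\bar y} is the mean of the observed values. Equals 1 for a
#' perfect forecast and 0 for the constant mean forecast; can be negative
#' for forecasts worse than the mean.
#'
#' @param predicted Numeric vector of forecasts.
#' @param observed Numeric vector of observations, same length, not
#'   constant.
#' @return A single number, at most 1.
#' @export
r_squared <- function(predicted, observed) {
  check_numeric_vector(predicted, "predicted", 2)
  check_numeric_vector(observed, "observed", 2)
  check_equal_length(predicted, observed)
  denom <- sum((mean(observed) - observed)^2)
  if (denom == 0) {
    abort("`observed` is constant: R-squared is undefined.")
  }
  1 - sum((predicted - observed)^2) / denom
}

#' Mean absolute error
#' @inheritParams r_squared
#' @return A non-negative number.
#' @export
mae <- function(predicted, observed) {
  check_numeric_vector(predicted, "predicted", 1)
  check_numeric_vector(observed, "observed", 1)
  check_equal_length(predicted, observed)
  mean(abs(predicted - observed))
}

#' Mean squared error
#' @inheritParams r_squared
#' @return A non-negative number.
#' @export
mse <- function(predicted, observed) {
  check_numeric_vector(predicted, "predicted", 1)
  check_numeric_vector(observed, "observed", 1)
  check_equal_length(predicted, observed)
  mean((predicted - observed)^2)
}

#' Symmetric mean absolute percentage error
#'
#' Mean over samples of \eqn{|\hat y_i - y_i| / ((\hat y_i + y_i)/2)}. The
#' denominator is the signed pairwise mean (not its absolute value); terms
#' with \eqn{\hat y_i + y_i = 0} contribute 0 by convention, which also
#' makes the all-zero pair well defined.
#'
#' @inheritParams r_squared
#' @return A non-negative value for non-negative series; for series taking
#'   negative values individual terms can be negative, reflecting the
#'   signed denominator.
#' @export
smape <- function(predicted, observed) {
  check_numeric_vector(predicted, "predicted", 1)
  check_numeric_vector(observed, "observed", 1)
  check_equal_length(predicted, observed)
  denom <- (predicted + observed) / 2
  term <- ifelse(denom == 0, 0, abs(predicted - observed) / denom)
  mean(term)
}

#' Evaluate a forecast with the four standard metrics
#'
#' @inheritParams r_squared
#' @param model_name Label for the forecasting model.
#' @param axis Label for the signal axis.
#' @return A one-row tibble with columns `model`, `axis`, `n`, `mae`,
#'   `mse`, `smape`, `r2` (the layout used for model comparison tables).
#' @export
evaluate_forecast <- function(predicted, observed, model_name = "model",
                              axis = "x") {
  tibble(model = model_name, axis = axis, n = length(observed),
         mae = mae(predicted, observed),
         mse = mse(predicted, observed),
         smape = smape(predicted, observed),
         r2 = r_squared(predicted, observed))
}
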