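# Windowed one-step-ahead LSTM forecaster. The compiled backend (src/) does
# batched forward/backward passes and Adam; this file owns windowing,
# scaling, initialization, the single-step cell used for verification, and
# persistence.

ACTIVATIONS <- c(linear = 0L, sigmoid = 1L, relu = 2L, tanh = 3L)

#' Forecaster architecture and training hyperparameters
#'
#' The four quantities tuned by the whale optimizer are `epochs`,
#' `hidden_units`, `learning_rate` and `l2_lambda`; `window` is the input
#' step length (12 by default) and `activation` the extra activation layer
#' between the LSTM hidden state and the linear output unit (tanh is the
#' best-performing choice for zero-mean signals).
#'
#' @param window Input step length: how many past values feed one
#'   prediction (>= 1).
#' @param hidden_units LSTM hidden state size (>= 1).
#' @param epochs Full-batch training epochs (>= 1).
#' @param learning_rate Adam learning rate (> 0).
#' @param l2_lambda L2 regularization weight on all weight matrices
#'   (biases exempt; >= 0).
#' @param activation One of `"tanh"`, `"sigmoid"`, `"linear"`, `"relu"`.
#' @param seed Integer seed for weight initialization.
#' @return A list of class `"lstm_spec"`.
#' @export
lstm_spec <- function(window = 12, hidden_units = 16, epochs = 60,
                      learning_rate = 5e-3, l2_lambda = 1e-5,
                      activation = c("tanh", "sigmoid", "linear", "relu"),
                      seed = 1) {
  activation <- match.arg(activation)
  stopifnot(window >= 1, hidden_units >= 1, epochs >= 1,
            learning_rate > 0, l2_lambda >= 0)
  structure(list(window = as.integer(window),
                 hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 l2_lambda = l2_lambda,
                 activation = activation,
                 seed = seed),
            class = "lstm_spec")
}

# Min-max scaler to [-1, 1]; a degenerate (constant) range maps everything
# to 0 and inverts to the constant.
make_scaler <- function(x) {
  list(min = min(x), max = max(x))
}

scale_values <- function(x, scaler) {
  rng <- scaler$max - scaler$min
  if (rng == 0) return(rep(0, length(x)))
  2 * (x - scaler$min) / rng - 1
}

unscale_values <- function(z, scaler) {
  rng <- scaler$max - scaler$min
  if (rng == 0) return(rep(scaler$min, length(z)))
  (z + 1) / 2 * rng + scaler$min
}

#' Build sliding windows for one-step-ahead forecasting
#'
#' Row `k` of the window matrix holds the `window` consecutive values
#' ending at series index `k + window - 1`; its target is the value at
#' index `k + window`. Min-max scaling to \[-1, 1\] is fitted on the first
#' `train_fraction` of the series only (no test leakage) and applied to the
#' whole series; rows whose target index falls inside that training prefix
#' are flagged `is_train`.
#'
#' @param series Numeric vector, longer than `window`.
#' @param window Number of past values per row (>= 1).
#' @param train_fraction Fraction of the series (chronological prefix) used
#'   to fit the scaler and to flag training rows; default 1 (all rows).
#' @return A list of class `"windowed_dataset"` with raw and scaled inputs
#'   and targets, target indices, the fitted scaler and the `is_train`
#'   flags.
#' @export
build_windows <- function(series, window, train_fraction = 1) {
  check_numeric_vector(series, "series", 2)
  stopifnot(window >= 1, train_fraction > 0, train_fraction <= 1)
  n <- length(series)
  if (n < window + 1) {
    abort(sprintf("Series of length %d is too short for window %d (need >= %d).",
                  n, window, window + 1))
  }
  split <- floor(train_fraction * n)
  if (split < window + 1) {
    abort(sprintf("Training prefix (%d samples) too short for window %d.",
                  split, window))
  }
  scaler <- make_scaler(series[seq_len(split)])
  scaled <- scale_values(series, scaler)
  n_rows <- n - window
  idx <- seq_len(n_rows)
  inputs <- matrix(series[outer(idx, 0:(window - 1), `+`)], nrow = n_rows)
  inputs_scaled <- matrix(scaled[outer(idx, 0:(window - 1), `+`)], nrow = n_rows)
  target_index <- idx + window
  structure(list(inputs = inputs,
                 targets = series[target_index],
                 inputs_scaled = inputs_scaled,
                 targets_scaled = scaled[target_index],
                 target_index = target_index,
                 scaler = scaler,
                 window = as.integer(window),
                 series_length = n,
                 is_train = target_index <= split),
            class = "windowed_dataset")
}

# Small random initialization; forget-gate biases start at 1 so early
# training does not wipe the cell state.
init_lstm_params <- function(hidden_units, seed) {
  H <- hidden_units
  r <- 0.2 / sqrt(H)
  with_seed(seed, {
    rnd <- function(nr, nc) matrix(runif(nr * nc, -r, r), nr, nc)
    list(Wxi = rnd(H, 1), Wxf = rnd(H, 1), Wxc = rnd(H, 1), Wxo = rnd(H, 1),
         Whi = rnd(H, H), Whf = rnd(H, H), Whc = rnd(H, H), Who = rnd(H, H),
         pci = rnd(H, 1), pcf = rnd(H, 1), pco = rnd(H, 1),
         bi = matrix(0, H, 1), bf = matrix(1, H, 1),
         bc = matrix(0, H, 1), bo = matrix(0, H, 1),
         wy = rnd(H, 1), by = matrix(0, 1, 1))
  })
}

#' One step of the peephole LSTM cell
#'
#' Applies the gate equations once: input and forget gates see the previous
#' cell state through diagonal peephole weights, the output gate sees the
#' updated cell state, and the hidden state is the gated tanh of the cell
#' state. Useful for inspecting the cell and for verifying the compiled
#' forward pass.
#'
#' @param params Named list of cell parameters: `Wxi`, `Wxf`, `Wxc`, `Wxo`
#'   (input weights, H x 1), `Whi`, `Whf`, `Whc`, `Who` (recurrent weights,
#'   H x H), `pci`, `pcf`, `pco` (peephole weights, length H), `bi`, `bf`,
#'   `bc`, `bo` (biases, length H).
#' @param x_t Scalar input at time t.
#' @param h_prev,c_prev Previous hidden and cell state vectors (length H).
#' @return A list with `h`, `c` and the gate activations `i`, `f`, `o`,
#'   `g`; gate values lie in (0, 1) and `|h| <= 1` element-wise.
#' @export
lstm_step <- function(params, x_t, h_prev, c_prev) {
  sig <- function(z) 1 / (1 + exp(-z))
  p <- lapply(params, function(w) if (is.matrix(w)) w else as.matrix(w))
  H <- nrow(p$Whi)
  stopifnot(length(h_prev) == H, length(c_prev) == H, length(x_t) == 1)
  i <- sig(drop(p$Wxi) * x_t + drop(p$Whi %*% h_prev) + drop(p$pci) * c_prev + drop(p$bi))
  f <- sig(drop(p$Wxf) * x_t + drop(p$Whf %*% h_prev) + drop(p$pcf) * c_prev + drop(p$bf))
  g <- tanh(drop(p$Wxc) * x_t + drop(p$Whc %*% h_prev) + drop(p$bc))
  c_t <- f * c_prev + i * g
  o <- sig(drop(p$Wxo) * x_t + drop(p$Who %*% h_prev) + drop(p$pco) * c_t + drop(p$bo))
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, i = i, f = f, o = o, g = g)
}

#' Train an LSTM forecaster on a windowed dataset
#'
#' Full-batch gradient training with Adam, minimizing mean squared error on
#' the scaled targets plus `l2_lambda` times the squared weight norm.
#' Deterministic given the spec's seed. Training uses the rows flagged
#' `is_train` in the dataset unless `rows` narrows them further.
#'
#' @param dataset A `"windowed_dataset"` from [build_windows()].
#' @param spec An `"lstm_spec"`.
#' @param rows Integer row indices to train on; default all training rows.
#' @return An object of class `"lstm_forecaster"` holding the trained
#'   parameters, the spec, the dataset's scaler and the per-epoch loss
#'   history.
#' @export
fit_lstm <- function(dataset, spec, rows = NULL) {
  stopifnot(inherits(dataset, "windowed_dataset"), inherits(spec, "lstm_spec"))
  if (dataset$window != spec$window) {
    abort(sprintf("Dataset window (%d) does not match spec window (%d).",
                  dataset$window, spec$window))
  }
  if (is.null(rows)) rows <- which(dataset$is_train)
  if (length(rows) < 1) abort("No training rows.")
  X <- t(dataset$inputs_scaled[rows, , drop = FALSE])  # window x n
  y <- dataset$targets_scaled[rows]
  params0 <- init_lstm_params(spec$hidden_units, spec$seed)
  fit <- lstm_train_cpp(params0, X, y, spec$epochs, spec$learning_rate,
                        spec$l2_lambda, ACTIVATIONS[[spec$activation]])
  structure(list(spec = spec,
                 params = fit$params,
                 scaler = dataset$scaler,
                 loss_history = as.numeric(fit$loss_history),
                 final_loss = fit$final_loss,
                 n_train = length(rows)),
            class = "lstm_forecaster")
}

#' Predict with a trained LSTM forecaster
#'
#' @param object An `"lstm_forecaster"`.
#' @param newdata A `"windowed_dataset"` or a numeric matrix of windows in
#'   raw (unscaled) units, one row per prediction; the column count must
#'   equal the model's window.
#' @param rows Optional row indices to predict (default all rows).
#' @param ... Unused.
#' @return Numeric vector of one-step-ahead predictions in raw units.
#' @export
predict.lstm_forecaster <- function(object, newdata, rows = NULL, ...) {
  inputs <- if (inherits(newdata, "windowed_dataset")) newdata$inputs else as.matrix(newdata)
  if (!is.null(rows)) inputs <- inputs[rows, , drop = FALSE]
  if (nrow(inputs) == 0) return(numeric(0))
  if (ncol(inputs) != object$spec$window) {
    abort(sprintf("Input windows have %d columns; model expects %d.",
                  ncol(inputs), object$spec$window))
  }
  scaled <- matrix(scale_values(as.numeric(inputs), object$scaler),
                   nrow = nrow(inputs))
  z <- lstm_forward_cpp(object$params, t(scaled),
                        ACTIVATIONS[[object$spec$activation]])
  unscale_values(as.numeric(z), object$scaler)
}

#' Save / load a trained forecaster
#'
#' The model is written as a single self-describing JSON file holding the
#' spec, the scaler and all weights at full precision, so predictions are
#' unchanged after a round trip.
#'
#' @param model An `"lstm_forecaster"`.
#' @param path File path.
#' @return `write_forecaster()` returns `path` invisibly;
#'   `read_forecaster()` returns the restored `"lstm_forecaster"`.
#' @export
write_forecaster <- function(model, path) {
  stopifnot(inherits(model, "lstm_forecaster"))
  payload <- list(
    spec = unclass(model$spec),
    scaler = model$scaler,
    params = lapply(model$params, function(w) list(dim = dim(w), data = as.numeric(w))),
    loss_history = model$loss_history,
    final_loss = model$final_loss,
    n_train = model$n_train
  )
  # 17 significant digits: doubles survive the round trip bit for bit
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_forecaster
#' @export
read_forecaster <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(lstm_spec, payload$spec)
  params <- lapply(payload$params, function(w) {
    matrix(w$data, nrow = w$dim[1], ncol = w$dim[2])
  })
  structure(list(spec = spec,
                 params = params,
                 scaler = as.list(payload$scaler),
                 loss_history = as.numeric(payload$loss_history),
                 final_loss = payload$final_loss,
                 n_train = payload$n_train),
            class = "lstm_forecaster")
}

#' @export
print.lstm_forecaster <- function(x, ...) {
  cat(sprintf("<lstm_forecaster> window %d, %d hidden units, %s activation\n",
              x$spec$window, x$spec$hidden_units, x$spec$activation))
  cat(sprintf("  trained %d epochs on %d windows; final loss %.3g\n",
              x$spec$epochs, x$n_train, x$final_loss))
  invisible(x)
}

#' @export
tidy.lstm_forecaster <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @export
glance.lstm_forecaster <- function(x, ...) {
  tibble(window = x$spec$window, hidden_units = x$spec$hidden_units,
         epochs = x$spec$epochs, learning_rate = x$spec$learning_rate,
         l2_lambda = x$spec$l2_lambda, activation = x$spec$activation,
         n_train = x$n_train, initial_loss = x$loss_history[1],
         final_loss = x$final_loss)
}
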