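# Independent brute-force oracles used to verify the package's
# implementations. These are deliberately written as plain loops, separate
# from the vectorized code paths they check.

oracle_r2 <- function(pred, obs) {
  ybar <- sum(obs) / length(obs)
  num <- 0; den <- 0
  for (i in seq_along(obs)) {
    num <- num + (pred[i] - obs[i])^2
    den <- den + (ybar - obs[i])^2
  }
  1 - num / den
}

oracle_mae <- function(pred, obs) {
  s <- 0
  for (i in seq_along(obs)) s <- s + abs(pred[i] - obs[i])
  s / length(obs)
}

oracle_mse <- function(pred, obs) {
  s <- 0
  for (i in seq_along(obs)) s <- s + (pred[i] - obs[i])^2
  s / length(obs)
}

oracle_smape <- function(pred, obs) {
  s <- 0
  for (i in seq_along(obs)) {
    d <- (pred[i] + obs[i]) / 2
    if (d != 0) s <- s + abs(pred[i] - obs[i]) / d
  }
  s / length(obs)
}

# Independent evaluation of the peephole LSTM gate equations for one step.
oracle_lstm_step <- function(params, x_t, h_prev, c_prev) {
  sigmoid <- function(z) ifelse(z >= 0, 1 / (1 + exp(-z)), exp(z) / (1 + exp(z)))
  as_vec <- function(w) as.numeric(w)
  i <- sigmoid(as_vec(params$Wxi) * x_t + as.numeric(params$Whi %*% h_prev) +
               as_vec(params$pci) * c_prev + as_vec(params$bi))
  f <- sigmoid(as_vec(params$Wxf) * x_t + as.numeric(params$Whf %*% h_prev) +
               as_vec(params$pcf) * c_prev + as_vec(params$bf))
  g <- tanh(as_vec(params$Wxc) * x_t + as.numeric(params$Whc %*% h_prev) +
            as_vec(params$bc))
  c_t <- f * c_prev + i * g
  o <- sigmoid(as_vec(params$Wxo) * x_t + as.numeric(params$Who %*% h_prev) +
               as_vec(params$pco) * c_t + as_vec(params$bo))
  list(h = o * tanh(c_t), c = c_t, i = i, f = f, o = o)
}

random_lstm_params <- function(H, sd = 0.5) {
  rnd <- function(nr, nc) matrix(rnorm(nr * nc, 0, sd), nr, nc)
  list(Wxi = rnd(H, 1), Wxf = rnd(H, 1), Wxc = rnd(H, 1), Wxo = rnd(H, 1),
       Whi = rnd(H, H), Whf = rnd(H, H), Whc = rnd(H, H), Who = rnd(H, H),
       pci = rnd(H, 1), pcf = rnd(H, 1), pco = rnd(H, 1),
       bi = rnd(H, 1), bf = rnd(H, 1), bc = rnd(H, 1), bo = rnd(H, 1),
       wy = rnd(H, 1), by = rnd(1, 1))
}

# Fraction of periodogram power inside [f_lo, f_hi] Hz.
band_power_fraction <- function(x, dt, f_lo, f_hi) {
  sp <- stats::spec.pgram(stats::ts(x, deltat = dt), taper = 0, fast = FALSE,
                          detrend = FALSE, plot = FALSE)
  sum(sp$spec[sp$freq >= f_lo & sp$freq <= f_hi]) / sum(sp$spec)
}

# Orthogonality index of a decomposition: sum over component pairs of
# |<u_i, u_j>| / ||signal||^2 (residual included as a component).
orthogonality_index <- function(dec, signal) {
  comps <- cbind(dec$imfs, dec$residual)
  k <- ncol(comps)
  s <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    s <- s + abs(sum(comps[, i] * comps[, j]))
  }
  s / sum(signal^2)
}

# Interior correlation between an extracted mode and a reference tone,
# ignoring the outer 5% of samples on each side (boundary effects).
interior_cor <- function(a, b, frac = 0.9) {
  n <- length(a)
  drop_n <- floor((1 - frac) / 2 * n)
  idx <- (drop_n + 1):(n - drop_n)
  stats::cor(a[idx], b[idx])
}

two_tone_fixture <- function() {
  t <- (0:999) * 0.005
  list(t = t,
       fast = sin(2 * pi * 20 * t),
       slow = sin(2 * pi * 2 * t),
       signal = sin(2 * pi * 20 * t) + sin(2 * pi * 2 * t))
}

# An lstm_forecaster whose output is identically zero in raw units.
zero_forecaster <- function(window = 12, H = 2) {
  z <- function(nr, nc) matrix(0, nr, nc)
  params <- list(Wxi = z(H, 1), Wxf = z(H, 1), Wxc = z(H, 1), Wxo = z(H, 1),
                 Whi = z(H, H), Whf = z(H, H), Whc = z(H, H), Who = z(H, H),
                 pci = z(H, 1), pcf = z(H, 1), pco = z(H, 1),
                 bi = z(H, 1), bf = z(H, 1), bc = z(H, 1), bo = z(H, 1),
                 wy = z(H, 1), by = z(1, 1))
  structure(list(spec = lstm_spec(window = window, hidden_units = H),
                 params = params, scaler = list(min = -1, max = 1),
                 loss_history = 0, final_loss = 0, n_train = 1),
            class = "lstm_forecaster")
}
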