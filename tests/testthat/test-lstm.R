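test_that("sliding windows line up with the series indices", {
  ds <- build_windows(as.numeric(1:20), window = 12)
  expect_equal(nrow(ds$inputs), 8)
  expect_equal(ds$inputs[1, ], as.numeric(1:12))
  expect_equal(ds$targets[1], 13)
  expect_equal(ds$inputs[8, ], as.numeric(8:19))
  expect_equal(ds$targets[8], 20)

  one <- build_windows(as.numeric(1:10), window = 9)
  expect_equal(nrow(one$inputs), 1)
  expect_error(build_windows(as.numeric(1:10), window = 10), "too short")
})

test_that("scaling is fitted on the training prefix only", {
  series <- c(rep(1, 50), rep(100, 50))
  ds <- build_windows(series, window = 5, train_fraction = 0.5)
  expect_equal(ds$scaler$max, 1)  # the test-half spike never touches the scaler
  expect_true(all(ds$is_train == (ds$target_index <= 50)))

  flat <- build_windows(rep(3, 30), window = 5)
  expect_true(all(flat$inputs_scaled == 0))  # degenerate range guard
  expect_true(all(flat$targets_scaled == 0))
})

test_that("the cell matches an independent evaluation of the gate equations", {
  worst <- 0
  for (k in 1:50) {
    case <- tremorcast:::with_seed(1000 + k, {
      H <- sample(1:6, 1)
      list(p = random_lstm_params(H), x = rnorm(1),
           h = rnorm(H, 0, 0.5), c = rnorm(H, 0, 0.5))
    })
    got <- lstm_step(case$p, case$x, case$h, case$c)
    want <- oracle_lstm_step(case$p, case$x, case$h, case$c)
    worst <- max(worst, abs(got$h - want$h), abs(got$c - want$c))
    expect_true(all(got$i > 0 & got$i < 1))
    expect_true(all(got$f > 0 & got$f < 1))
    expect_true(all(got$o > 0 & got$o < 1))
    expect_true(all(abs(got$h) <= 1))
  }
  expect_lt(worst, 1e-10)
})

test_that("the cell honours its limiting regimes", {
  H <- 3
  zero <- lapply(random_lstm_params(H), function(w) w * 0)
  st <- lstm_step(zero, x_t = 0.7, h_prev = rep(0, H), c_prev = rep(0, H))
  expect_identical(st$i, rep(0.5, H))
  expect_identical(st$f, rep(0.5, H))
  expect_identical(st$o, rep(0.5, H))
  expect_identical(st$c, rep(0, H))
  expect_identical(st$h, rep(0, H))

  memory <- lapply(random_lstm_params(H), function(w) w * 0)
  memory$bf <- matrix(40, H, 1)   # forget gate saturates to 1
  memory$bi <- matrix(-40, H, 1)  # input gate saturates to 0
  c_prev <- c(0.3, -0.8, 0.1)
  st <- lstm_step(memory, x_t = 1.3, h_prev = rnorm(H), c_prev = c_prev)
  expect_equal(st$c, c_prev, tolerance = 1e-12)
})

test_that("the compiled forward pass equals composed single steps", {
  case <- tremorcast:::with_seed(7, {
    list(p = random_lstm_params(4), X = matrix(rnorm(12 * 3), 12, 3))
  })
  for (act in c("linear", "sigmoid", "relu", "tanh")) {
    code <- tremorcast:::ACTIVATIONS[[act]]
    got <- tremorcast:::lstm_forward_cpp(case$p, case$X, code)
    for (s in 1:3) {
      h <- rep(0, 4); cc <- rep(0, 4)
      for (t in 1:12) {
        st <- lstm_step(case$p, case$X[t, s], h, cc)
        h <- st$h; cc <- st$c
      }
      u <- switch(act, linear = h, sigmoid = 1 / (1 + exp(-h)),
                  relu = pmax(h, 0), tanh = tanh(h))
      want <- sum(as.numeric(case$p$wy) * u) + case$p$by[1, 1]
      expect_equal(got[s], want, tolerance = 1e-10)
    }
  }
})

test_that("analytic gradients match finite differences", {
  case <- tremorcast:::with_seed(21, {
    list(p = random_lstm_params(3, sd = 0.4),
         X = matrix(rnorm(4 * 5), 4, 5), y = rnorm(5))
  })
  lg <- tremorcast:::lstm_loss_grad_cpp(case$p, case$X, case$y, 0.01, 3L)
  eps <- 1e-6
  worst <- 0
  for (nm in names(case$p)) {
    for (j in seq_along(case$p[[nm]])) {
      up <- case$p; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- case$p; dn[[nm]][j] <- dn[[nm]][j] - eps
      num <- (tremorcast:::lstm_loss_grad_cpp(up, case$X, case$y, 0.01, 3L)$loss -
              tremorcast:::lstm_loss_grad_cpp(dn, case$X, case$y, 0.01, 3L)$loss) /
             (2 * eps)
      worst <- max(worst, abs(num - lg$gradients[[nm]][j]))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("training learns easy targets and is seed-deterministic", {
  flat <- build_windows(rep(2.5, 60), window = 12)
  m <- fit_lstm(flat, lstm_spec(epochs = 20, seed = 1))
  expect_lt(mse(predict(m, flat), flat$targets), 1e-4)

  t <- 1:300
  ds <- build_windows(sin(2 * pi * t / 25), window = 12, train_fraction = 0.7)
  spec <- lstm_spec(window = 12, hidden_units = 16, epochs = 200,
                    activation = "tanh", seed = 3)
  m <- fit_lstm(ds, spec)
  test_rows <- which(!ds$is_train)
  r2 <- r_squared(predict(m, ds, rows = test_rows), ds$targets[test_rows])
  expect_gt(r2, 0.95)

  expect_true(all(is.finite(m$loss_history)))
  expect_lte(min(m$loss_history), m$loss_history[1])

  m2 <- fit_lstm(ds, spec)
  expect_identical(predict(m, ds), predict(m2, ds))
})

test_that("prediction validates its inputs", {
  ds <- build_windows(sin(1:80), window = 8)
  m <- fit_lstm(ds, lstm_spec(window = 8, epochs = 5))
  expect_identical(predict(m, matrix(numeric(0), 0, 8)), numeric(0))
  expect_error(predict(m, matrix(0, 2, 5)), "expects")
  expect_error(fit_lstm(ds, lstm_spec(window = 12, epochs = 5)), "match")
})

test_that("a saved model predicts identically after reloading", {
  ds <- build_windows(cos(1:100 / 7), window = 10)
  m <- fit_lstm(ds, lstm_spec(window = 10, hidden_units = 6, epochs = 30, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_forecaster(m, path)
  back <- read_forecaster(path)
  expect_identical(predict(back, ds), predict(m, ds))
  expect_equal(glance(back)$final_loss, glance(m)$final_loss)
})

test_that("every activation layer trains and predicts finitely", {
  ds <- build_windows(sin(1:120 / 5), window = 8)
  for (act in c("linear", "sigmoid", "relu", "tanh")) {
    m <- fit_lstm(ds, lstm_spec(window = 8, hidden_units = 4, epochs = 15,
                                activation = act, seed = 1))
    expect_true(all(is.finite(predict(m, ds))), info = act)
    expect_true(all(is.finite(m$loss_history)), info = act)
  }
})
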