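test_that("metrics reproduce hand-computed values", {
  expect_equal(r_squared(c(1, 2, 3, 5), c(1, 2, 3, 4)), 0.8)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 4)), 1 / 3)
  expect_equal(mse(c(1, 2, 3), c(1, 2, 4)), 1 / 3)
  expect_equal(smape(3, 1), 1.0)
})

test_that("metrics satisfy their analytic identities", {
  y <- c(0.3, -1.2, 2.5, 0.7, 1.1)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(rep(mean(y), 5), y), 0)
  expect_equal(mae(y, y), 0)
  expect_equal(mse(y, y), 0)
  expect_equal(smape(y + 1e-9, y + 1e-9), 0, tolerance = 1e-6)
  expect_equal(mae(y, rev(y)), mae(rev(y), y))
  expect_equal(mse(2 * y, 2 * rev(y)), 4 * mse(y, rev(y)))
  expect_equal(smape(0, 0), 0)  # zero-denominator convention
})

test_that("metrics agree with brute-force evaluation on random pairs", {
  worst <- 0
  for (k in 1:100) {
    pair <- tremorcast:::with_seed(k, {
      n <- sample(5:50, 1)
      list(pred = rnorm(n, sd = runif(1, 0.1, 10)),
           obs = rnorm(n, sd = runif(1, 0.1, 10)))
    })
    rel <- function(a, b) abs(a - b) / max(abs(b), 1e-300)
    worst <- max(worst,
                 rel(r_squared(pair$pred, pair$obs), oracle_r2(pair$pred, pair$obs)),
                 rel(mae(pair$pred, pair$obs), oracle_mae(pair$pred, pair$obs)),
                 rel(mse(pair$pred, pair$obs), oracle_mse(pair$pred, pair$obs)),
                 rel(smape(pair$pred, pair$obs), oracle_smape(pair$pred, pair$obs)))
  }
  expect_lt(worst, 1e-12)
})

test_that("degenerate metric inputs are rejected", {
  expect_error(r_squared(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_error(mae(1:3, 1:4), "equal length")
  expect_error(mse(1:3, 1:4), "equal length")
  expect_error(smape(c(1, NA), c(1, 2)), "missing")
})

test_that("forecast reports carry the comparison-table layout", {
  rep <- evaluate_forecast(c(1, 2, 3, 5), c(1, 2, 3, 4),
                           model_name = "demo", axis = "y")
  expect_named(rep, c("model", "axis", "n", "mae", "mse", "smape", "r2"))
  expect_equal(rep$n, 4)
  expect_equal(rep$r2, 0.8)
})
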