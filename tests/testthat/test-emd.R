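test_that("monotone input yields no IMFs and the input as residual", {
  ramp <- seq(0, 1, length.out = 64)
  dec <- emd(ramp)
  expect_equal(ncol(dec$imfs), 0)
  expect_identical(dec$residual, ramp)
  expect_true(dec$degenerate)
})

test_that("a pure sinusoid is captured by the first IMF", {
  t <- seq(0, 20, length.out = 800)  # 20 cycles
  x <- sin(2 * pi * t)
  dec <- emd(x)
  expect_gte(ncol(dec$imfs), 1)
  expect_gt(abs(interior_cor(dec$imfs[, 1], x)), 0.99)
})

test_that("two tones separate into the first two IMFs, fast mode first", {
  tt <- two_tone_fixture()
  dec <- emd(tt$signal)
  expect_gte(ncol(dec$imfs), 2)
  expect_gt(abs(interior_cor(dec$imfs[, 1], tt$fast)), 0.95)
  expect_gt(abs(interior_cor(dec$imfs[, 2], tt$slow)), 0.95)
  expect_lt(orthogonality_index(dec, tt$signal), 0.1)
})

test_that("decomposition reconstructs the input and orders modes by rate", {
  for (s in 1:10) {
    x <- tremorcast:::with_seed(s, {
      t <- seq(0, 4, length.out = 400)
      rnorm(1) + cumsum(rnorm(400, 0, 0.1)) + sin(2 * pi * runif(1, 5, 15) * t)
    })
    dec <- emd(x)
    recon <- if (ncol(dec$imfs) > 0) rowSums(dec$imfs) + dec$residual else dec$residual
    expect_lte(max(abs(x - recon)), 1e-8 * max(abs(x)))
  }
})

test_that("ensemble decomposition orders modes from fast to slow", {
  tt <- two_tone_fixture()
  zc2 <- apply(emd(tt$signal)$imfs[, 1:2], 2, count_zero_crossings)
  expect_true(zc2[1] > zc2[2])
  for (s in 1:4) {
    truth <- simulate_tremor(n = 500, axes = "x", seed = s)
    dec <- eemd(truth$actual, ensemble_size = 30, seed = s)
    zc <- apply(dec$imfs, 2, count_zero_crossings)
    # counts below 5 are not a measurable oscillation rate and are exempt
    measurable <- zc[zc >= 5]
    expect_true(all(diff(measurable) <= 0))
  }
})

test_that("eemd reduces to emd for a noiseless ensemble and is seed-stable", {
  tt <- two_tone_fixture()
  plain <- emd(tt$signal)
  degenerate <- eemd(tt$signal, ensemble_size = 1, noise_sd_ratio = 0)
  expect_identical(plain$imfs, degenerate$imfs)
  expect_identical(plain$residual, degenerate$residual)

  a <- eemd(tt$signal, ensemble_size = 10, noise_sd_ratio = 0.2, seed = 42)
  b <- eemd(tt$signal, ensemble_size = 10, noise_sd_ratio = 0.2, seed = 42)
  expect_identical(a, b)
  c <- eemd(tt$signal, ensemble_size = 10, noise_sd_ratio = 0.2, seed = 43)
  expect_false(identical(a$imfs, c$imfs))
})

test_that("ensemble averaging shrinks the reconstruction error", {
  t <- seq(0, 4, length.out = 512)
  x <- sin(2 * pi * 10 * t) * (1 + 0.3 * sin(2 * pi * 0.5 * t)) + 0.5 * sin(2 * pi * t)
  err <- function(es, seed) {
    dec <- eemd(x, ensemble_size = es, noise_sd_ratio = 0.2, seed = seed)
    max(abs(x - rowSums(dec$imfs) - dec$residual))
  }
  small <- sapply(1:5, function(s) err(10, s))
  large <- sapply(1:5, function(s) err(100, s))
  expect_lt(median(large), median(small))
})

test_that("invalid decomposition settings are rejected", {
  x <- sin(seq(0, 10, length.out = 100))
  expect_error(emd(x, sd_threshold = 0), "sd_threshold")
  expect_error(emd(x, max_sift_iters = 0), "max_sift_iters")
  expect_error(emd(c(1, NA, 3, 4, 5, 6, 7, 8)), "missing")
  expect_error(eemd(x, ensemble_size = 0), "ensemble_size")
  expect_error(eemd(x, noise_sd_ratio = -0.1), "noise_sd_ratio")
})

test_that("decomposition tidies to a long component table", {
  tt <- two_tone_fixture()
  dec <- emd(tt$signal)
  tb <- tibble::as_tibble(dec)
  expect_named(tb, c("index", "component", "value"))
  expect_equal(nrow(tb), 1000 * (ncol(dec$imfs) + 1))
  expect_equal(tb$value[tb$component == "res"], dec$residual)
})
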