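test_that("the shrinking factor and adaptive weight hit their endpoints", {
  expect_equal(convergence_factor(0, 30), 2)
  expect_equal(convergence_factor(30, 30), 0)
  expect_equal(adaptive_weight(0, 30), 1)
  expect_equal(adaptive_weight(15, 30), 0, tolerance = 1e-12)
  expect_equal(adaptive_weight(30, 30), -1)
  a <- convergence_factor(0:30, 30)
  w <- adaptive_weight(0:30, 30)
  expect_true(all(diff(a) <= 0))
  expect_true(all(diff(w) <= 0))
  expect_error(convergence_factor(31, 30), "max_t")
  expect_error(adaptive_weight(-1, 30), "max_t")
})

test_that("quasi-opposite points land between the midpoint and reflection", {
  # a=0, b=10, x=3: reflection 7, midpoint 5
  expect_equal(quasi_opposite(3, 0, 10, 0), 5)
  expect_equal(quasi_opposite(3, 0, 10, 1), 7)
  q <- quasi_opposite(3, 0, 10, runif(50))
  expect_true(all(q >= 5 & q <= 7))
  expect_equal(quasi_opposite(5, 0, 10, runif(5)), rep(5, 5))  # fixed point
})

test_that("quasi-opposition init evaluates 2n candidates and keeps the best n", {
  sp <- search_space(c(0, -2), c(10, 2))
  seen <- new.env(); seen$pts <- list()
  obj <- function(x) {
    seen$pts[[length(seen$pts) + 1]] <- x
    sum((x - c(2, 1))^2)
  }
  pop <- quasi_reverse_init(obj, sp, n = 6, seed = 5)
  cand <- do.call(rbind, seen$pts)
  expect_equal(nrow(cand), 12)
  expect_true(all(cand[, 1] >= 0 & cand[, 1] <= 10))
  expect_true(all(cand[, 2] >= -2 & cand[, 2] <= 2))
  # second half are quasi-opposite points of the first half
  for (j in 1:2) {
    a <- sp$lower[j]; b <- sp$upper[j]; m <- (a + b) / 2
    x <- cand[1:6, j]; q <- cand[7:12, j]; xhat <- a + b - x
    expect_true(all(q >= pmin(m, xhat) - 1e-12 & q <= pmax(m, xhat) + 1e-12))
  }
  fits <- apply(cand, 1, function(x) sum((x - c(2, 1))^2))
  expect_equal(sort(pop$fitness), sort(fits)[1:6])
  expect_equal(pop$best_fitness, min(fits))
  expect_true(all(pop$positions >= rep(sp$lower, each = 6) &
                  pop$positions <= rep(sp$upper, each = 6)))
})

test_that("population updates stay in bounds and never lose the elite", {
  sp <- search_space(rep(-5, 3), rep(5, 3))
  obj <- benchmark_objective("rastrigin")
  pop <- quasi_reverse_init(obj, sp, n = 8, seed = 1)
  best <- pop$best_fitness
  for (t in 1:15) {
    pop <- update_population(pop, obj, sp, t, 15, seed = t)
    expect_true(all(pop$positions >= -5 & pop$positions <= 5))
    expect_lte(pop$best_fitness, best)
    best <- pop$best_fitness
    pop <- gaussian_elite_mutation(pop, obj, sp, seed = 100 + t)
    expect_lte(pop$best_fitness, best)
    best <- pop$best_fitness
  }
})

test_that("with A = 0 the encircling move lands exactly on the weighted elite", {
  sp <- search_space(c(-10, -10), c(10, 10))
  obj <- function(x) sum(x^2)
  # find a seed whose p-draws put both whales in the encircling branch
  seed <- NULL
  for (s in 1:200) {
    draws <- tremorcast:::with_seed(s, runif(2))
    if (all(draws < 0.5)) { seed <- s; break }
  }
  pop <- quasi_reverse_init(obj, sp, n = 2, seed = 3)
  out <- update_population(pop, obj, sp, t = 20, max_t = 20, seed = seed)
  # a(max_t) = 0 so A = 0, and w = cos(pi) = -1: new position = -elite, exactly
  expected <- matrix(rep(-pop$best_position, each = 2), 2)
  expect_equal(out$positions, expected, tolerance = 1e-12)
})

test_that("elite mutation is greedy and draws at the configured scale", {
  sp1 <- search_space(0, 1)
  # force a population whose best sits mid-interval with unbeatable fitness,
  # so proposals are always rejected and we observe the raw perturbations
  pop <- structure(list(positions = matrix(0.5), fitness = -Inf,
                        best_position = 0.5, best_fitness = -Inf),
                   class = "whale_population")
  seen <- new.env(); seen$x <- numeric(0)
  obj <- function(x) { seen$x <- c(seen$x, x); 1 }
  for (s in 1:2500) pop <- gaussian_elite_mutation(pop, obj, sp1, seed = s, scale = 0.1)
  expect_identical(pop$best_position, 0.5)  # nothing ever accepted
  eps <- seen$x - 0.5
  expect_gt(length(eps), 1000)
  expect_lt(abs(sd(eps) - 0.1) / 0.1, 0.1)

  # r < 0.5 leaves the population untouched without evaluating anything
  seed_low <- which(sapply(1:50, function(s) tremorcast:::with_seed(s, runif(1)) < 0.5))[1]
  before <- length(seen$x)
  pop2 <- gaussian_elite_mutation(pop, obj, sp1, seed = seed_low)
  expect_identical(pop2, pop)
  expect_equal(length(seen$x), before)
})

test_that("the optimizer converges on the sphere and reports a monotone curve", {
  sp <- search_space(rep(-5, 5), rep(5, 5))
  obj <- benchmark_objective("sphere")
  fits <- sapply(1:5, function(s) {
    res <- iwoa_minimize(obj, sp, n = 10, max_t = 100, seed = s)
    expect_true(all(diff(res$curve$fitness) <= 0))
    res$best_fitness
  })
  expect_lt(median(fits), 1e-3)
})

test_that("a flat landscape returns the constant and any in-bounds point", {
  sp <- search_space(c(0, 0), c(1, 1))
  res <- iwoa_minimize(function(x) 42, sp, n = 4, max_t = 5, seed = 9)
  expect_equal(res$best_fitness, 42)
  expect_true(all(res$best_position >= 0 & res$best_position <= 1))
})

test_that("minimization is fully reproducible and rejects bad fitness safely", {
  sp <- search_space(rep(-2, 3), rep(2, 3))
  obj <- benchmark_objective("rosenbrock")
  a <- iwoa_minimize(obj, sp, n = 6, max_t = 20, seed = 4)
  b <- iwoa_minimize(obj, sp, n = 6, max_t = 20, seed = 4)
  expect_identical(a, b)

  nasty <- function(x) if (x[1] > 0) NaN else sum(x^2)
  res <- iwoa_minimize(nasty, sp, n = 6, max_t = 10, seed = 1)
  expect_true(is.finite(res$best_fitness))
})

test_that("integer and log dimensions decode to valid hyperparameters", {
  sp <- forecaster_search_space()
  res <- iwoa_minimize(function(hp) {
    expect_true(hp[["epochs"]] == round(hp[["epochs"]]))
    expect_true(hp[["hidden_units"]] == round(hp[["hidden_units"]]))
    expect_gte(hp[["learning_rate"]], 1e-4)
    expect_lte(hp[["learning_rate"]], 1e-2)
    expect_gte(hp[["l2_lambda"]], 1e-6)
    (hp[["learning_rate"]] - 3e-3)^2
  }, sp, n = 4, max_t = 3, seed = 2)
  expect_named(res$best_position,
               c("epochs", "hidden_units", "learning_rate", "l2_lambda"))
})

test_that("disabling the improvements reduces the loop to canonical WOA", {
  sp <- search_space(rep(-5, 5), rep(5, 5))
  obj <- benchmark_objective("sphere")
  iwoa <- sapply(1:8, function(s)
    iwoa_minimize(obj, sp, n = 10, max_t = 50, seed = s)$best_fitness)
  woa <- sapply(1:8, function(s)
    iwoa_minimize(obj, sp, n = 10, max_t = 50, seed = s,
                  improved = FALSE)$best_fitness)
  expect_lte(median(iwoa), median(woa))
})
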