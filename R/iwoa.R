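# Whale Optimization Algorithm (WOA) with four improvements: quasi-opposite
# population initialization, the printed convergence-factor schedule, an
# adaptive cosine weight on the attractor, and Gaussian elite mutation.
# Usable as a generic bounded continuous minimizer and as the forecaster's
# hyperparameter tuner.

#' Define a bounded search space
#'
#' Dimensions flagged `log` are searched on a log10 scale (bounds must be
#' positive); dimensions flagged `integer` are rounded when a position is
#' decoded for the objective.
#'
#' @param lower,upper Numeric vectors of per-dimension bounds,
#'   `lower < upper` element-wise.
#' @param integer Logical vector (recycled): round this dimension when
#'   decoding.
#' @param log Logical vector (recycled): search this dimension in log10
#'   scale.
#' @param names Optional dimension names.
#' @return A list of class `"search_space"`.
#' @export
search_space <- function(lower, upper, integer = FALSE, log = FALSE,
                         names = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, d >= 1)
  if (any(lower >= upper)) abort("`lower` must be < `upper` in every dimension.")
  integer <- rep_len(integer, d)
  log <- rep_len(log, d)
  if (any(log & lower <= 0)) abort("Log-scale dimensions need positive bounds.")
  if (is.null(names)) names <- paste0("x", seq_len(d))
  structure(list(lower = lower, upper = upper, integer = integer,
                 log = log, names = names, d = d),
            class = "search_space")
}

# Bounds in internal search coordinates (log dims are log10-transformed).
space_coords <- function(space) {
  a <- ifelse(space$log, log10(space$lower), space$lower)
  b <- ifelse(space$log, log10(space$upper), space$upper)
  list(a = a, b = b)
}

#' Decode an internal position into natural units
#'
#' @param space A [search_space()].
#' @param position Numeric vector in internal coordinates.
#' @return Named numeric vector: log dimensions exponentiated, integer
#'   dimensions rounded.
#' @export
decode_position <- function(space, position) {
  v <- ifelse(space$log, 10^position, position)
  v <- ifelse(space$integer, round(v), v)
  setNames(v, space$names)
}

clamp <- function(x, a, b) pmin(pmax(x, a), b)

eval_objective <- function(objective, space, position) {
  v <- objective(decode_position(space, position))
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) return(Inf)
  v
}

#' Quasi-opposite point of a position
#'
#' For a position `x` in `[a, b]`, the opposite point is
#' \eqn{\hat x = a + b - x} and the quasi-opposite point is drawn uniformly
#' on the interval between the midpoint \eqn{M = (a+b)/2} and \eqn{\hat x}.
#'
#' @param x,a,b Numeric vectors: position and bounds.
#' @param u Uniform(0,1) draw(s); the point is `M + (a + b - x - M) * u`.
#' @return Numeric vector of quasi-opposite coordinates, always between
#'   `M` and `a + b - x`.
#' @export
quasi_opposite <- function(x, a, b, u) {
  m <- (a + b) / 2
  xhat <- a + b - x
  m + (xhat - m) * u
}

#' Initialize a whale population by quasi-opposition learning
#'
#' Draws `n` uniform positions, computes each one's quasi-opposite point,
#' evaluates all `2n` candidates and keeps the `n` best by fitness.
#'
#' @param objective Function of a decoded position returning a scalar to
#'   minimize; non-finite returns count as `+Inf`.
#' @param space A [search_space()].
#' @param n Population size (>= 2).
#' @param seed Integer seed.
#' @return A list of class `"whale_population"`: `positions` (n x d, in
#'   internal coordinates), `fitness`, `best_position`, `best_fitness`.
#' @export
quasi_reverse_init <- function(objective, space, n, seed = 1) {
  if (n < 2) abort("Population size must be >= 2.")
  co <- space_coords(space)
  d <- space$d
  cand <- with_seed(seed, {
    x <- matrix(runif(n * d, rep(co$a, each = n), rep(co$b, each = n)), n, d)
    u <- matrix(runif(n * d), n, d)
    q <- t(apply(cbind(x, u), 1, function(row) {
      quasi_opposite(row[1:d], co$a, co$b, row[(d + 1):(2 * d)])
    }))
    if (d == 1) q <- matrix(q, ncol = 1)
    rbind(x, q)
  })
  cand <- t(apply(cand, 1, clamp, a = co$a, b = co$b))
  if (d == 1) cand <- matrix(cand, ncol = 1)
  fit <- apply(cand, 1, function(p) eval_objective(objective, space, p))
  keep <- order(fit)[seq_len(n)]
  positions <- cand[keep, , drop = FALSE]
  fitness <- fit[keep]
  structure(list(positions = positions, fitness = fitness,
                 best_position = positions[1, ], best_fitness = fitness[1]),
            class = "whale_population")
}

# Plain random initialization (canonical WOA baseline).
random_init <- function(objective, space, n, seed = 1) {
  co <- space_coords(space)
  d <- space$d
  positions <- with_seed(seed, {
    matrix(runif(n * d, rep(co$a, each = n), rep(co$b, each = n)), n, d)
  })
  fitness <- apply(positions, 1, function(p) eval_objective(objective, space, p))
  i <- which.min(fitness)
  structure(list(positions = positions, fitness = fitness,
                 best_position = positions[i, ], best_fitness = fitness[i]),
            class = "whale_population")
}

#' Convergence factor schedule
#'
#' The shrinking factor \eqn{a = 2 - 2t/t_{max}} controlling the
#' exploration/exploitation balance: 2 at the first iteration, 0 at the
#' last, monotone non-increasing in between.
#'
#' @param t Iteration, `0 <= t <= max_t`.
#' @param max_t Total iterations.
#' @return A value in `[0, 2]`.
#' @export
convergence_factor <- function(t, max_t) {
  if (any(t < 0) || any(t > max_t)) abort("`t` must lie in [0, max_t].")
  2 - 2 * t / max_t
}

#' Adaptive weight schedule
#'
#' \eqn{\omega = \cos(\pi t / t_{max})}: 1 at the start, 0 at mid-run, -1
#' at the end. Scales the attractor (the best-so-far position) in the
#' encircling and spiral moves, so late iterations explore the reflected
#' neighbourhood of the elite.
#'
#' @inheritParams convergence_factor
#' @return A value in `[-1, 1]`.
#' @export
adaptive_weight <- function(t, max_t) {
  if (any(t < 0) || any(t > max_t)) abort("`t` must lie in [0, max_t].")
  cos(pi * t / max_t)
}

#' One whale-population update sweep
#'
#' For each whale, draw `p`: with `p >= 0.5` take the weighted logarithmic
#' spiral move around the best position; otherwise take the weighted
#' encircling move when `|A| < 1` or the exploration move around a random
#' whale when `|A| >= 1`, with `A = 2 a r1 - a` and `C = 2 r2`. Positions
#' are clamped to the bounds and re-evaluated; the elite record is updated
#' so the best-so-far fitness never increases.
#'
#' @param pop A `"whale_population"`.
#' @inheritParams quasi_reverse_init
#' @param t,max_t Iteration counter and budget (drive the convergence
#'   factor and adaptive weight).
#' @param improved Apply the adaptive weight (`TRUE`) or the canonical
#'   unweighted update (`FALSE`).
#' @param spiral_b Logarithmic spiral shape constant.
#' @return The updated `"whale_population"`.
#' @export
update_population <- function(pop, objective, space, t, max_t, seed = 1,
                              improved = TRUE, spiral_b = 1) {
  co <- space_coords(space)
  n <- nrow(pop$positions)
  d <- space$d
  a <- convergence_factor(t, max_t)
  w <- if (improved) adaptive_weight(t, max_t) else 1
  draws <- with_seed(seed, {
    list(p = runif(n), r1 = runif(n), r2 = runif(n),
         l = runif(n, -1, 1), ri = sample.int(n, n, replace = TRUE))
  })
  xp <- pop$best_position
  new_pos <- pop$positions
  for (i in seq_len(n)) {
    x <- pop$positions[i, ]
    A <- 2 * a * draws$r1[i] - a
    C <- 2 * draws$r2[i]
    if (draws$p[i] >= 0.5) {
      D <- abs(xp - x)
      xnew <- w * xp + D * exp(spiral_b * draws$l[i]) * cos(2 * pi * draws$l[i])
    } else if (abs(A) < 1) {
      D <- abs(C * xp - x)
      xnew <- w * xp - A * D
    } else {
      xr <- pop$positions[draws$ri[i], ]
      D <- abs(C * xr - x)
      xnew <- xr - A * D
    }
    new_pos[i, ] <- clamp(xnew, co$a, co$b)
  }
  fitness <- apply(new_pos, 1, function(p) eval_objective(objective, space, p))
  pop$positions <- new_pos
  pop$fitness <- fitness
  i_best <- which.min(fitness)
  if (fitness[i_best] < pop$best_fitness) {
    pop$best_fitness <- fitness[i_best]
    pop$best_position <- new_pos[i_best, ]
  }
  pop
}

#' Gaussian elite mutation
#'
#' With probability 1/2 the elite is left alone; otherwise a Gaussian
#' perturbation with per-dimension standard deviation
#' `scale * (upper - lower)` is proposed around the best position and
#' accepted only if it improves the fitness (greedy), so the elite never
#' worsens.
#'
#' @inheritParams update_population
#' @param scale Perturbation scale as a fraction of each dimension's range.
#' @return The possibly-updated `"whale_population"`.
#' @export
gaussian_elite_mutation <- function(pop, objective, space, seed = 1,
                                    scale = 0.1) {
  co <- space_coords(space)
  draws <- with_seed(seed, {
    list(r = runif(1), eps = rnorm(space$d, 0, scale * (co$b - co$a)))
  })
  if (draws$r < 0.5) return(pop)
  proposal <- clamp(pop$best_position + draws$eps, co$a, co$b)
  f <- eval_objective(objective, space, proposal)
  if (f < pop$best_fitness) {
    i <- which.min(pop$fitness)
    pop$positions[i, ] <- proposal
    pop$fitness[i] <- f
    pop$best_position <- proposal
    pop$best_fitness <- f
  }
  pop
}

#' Minimize an objective with the (improved) whale optimizer
#'
#' Runs quasi-opposition initialization followed by `max_t` sweeps of
#' [update_population()] and [gaussian_elite_mutation()]. With
#' `improved = FALSE` the loop reduces to canonical WOA: plain random
#' initialization, no adaptive weight, no mutation.
#'
#' @inheritParams quasi_reverse_init
#' @param n Population size (>= 2); default 10.
#' @param max_t Iteration budget (>= 1); default 30.
#' @param improved Use the four improvements (default) or canonical WOA.
#' @param mutation_scale Elite-mutation scale, fraction of each
#'   dimension's range.
#' @return A list of class `"iwoa_result"`: `best_position` (named, in
#'   natural units), `best_fitness`, `curve` (tibble of per-iteration
#'   elite fitness, monotone non-increasing), `n_evaluations`, `improved`.
#' @examples
#' sp <- search_space(rep(-5, 2), rep(5, 2))
#' res <- iwoa_minimize(function(x) sum(x^2), sp, n = 8, max_t = 20, seed = 1)
#' res$best_fitness
#' @export
iwoa_minimize <- function(objective, space, n = 10, max_t = 30, seed = 1,
                          improved = TRUE, mutation_scale = 0.1) {
  stopifnot(n >= 2, max_t >= 1)
  pop <- if (improved) {
    quasi_reverse_init(objective, space, n, seed = child_seed(seed, 0))
  } else {
    random_init(objective, space, n, seed = child_seed(seed, 0))
  }
  n_eval <- if (improved) 2L * n else n
  curve <- numeric(max_t)
  for (t in seq_len(max_t)) {
    pop <- update_population(pop, objective, space, t, max_t,
                             seed = child_seed(seed, 2 * t),
                             improved = improved)
    n_eval <- n_eval + n
    if (improved) {
      before <- pop$best_fitness
      pop <- gaussian_elite_mutation(pop, objective, space,
                                     seed = child_seed(seed, 2 * t + 1),
                                     scale = mutation_scale)
      if (!identical(before, pop$best_fitness)) n_eval <- n_eval + 1L
    }
    curve[t] <- pop$best_fitness
  }
  structure(list(best_position = decode_position(space, pop$best_position),
                 best_fitness = pop$best_fitness,
                 curve = tibble(iteration = seq_len(max_t), fitness = curve),
                 n_evaluations = n_eval,
                 improved = improved),
            class = "iwoa_result")
}

#' Standard benchmark objectives
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"rosenbrock"`.
#' @return A function of a numeric vector returning a scalar; all three
#'   have their global minimum 0 at the origin (Rosenbrock at the all-ones
#'   point).
#' @export
benchmark_objective <- function(name = c("sphere", "rastrigin", "rosenbrock")) {
  name <- match.arg(name)
  switch(name,
    sphere = function(x) sum(x^2),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    rosenbrock = function(x) {
      if (length(x) < 2) return(sum((1 - x)^2))
      sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
    })
}

#' @export
print.iwoa_result <- function(x, ...) {
  cat(sprintf("<iwoa_result> %s, best fitness %.6g after %d iterations (%d evaluations)\n",
              if (x$improved) "improved WOA" else "canonical WOA",
              x$best_fitness, nrow(x$curve), x$n_evaluations))
  print(x$best_position)
  invisible(x)
}

#' @export
tidy.iwoa_result <- function(x, ...) x$curve

#' @export
glance.iwoa_result <- function(x, ...) {
  tibble(best_fitness = x$best_fitness, iterations = nrow(x$curve),
         n_evaluations = x$n_evaluations, improved = x$improved)
}

#' @export
autoplot.iwoa_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$iteration, y = .data$fitness)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "elite fitness")
}
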