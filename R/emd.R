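# Empirical mode decomposition by sifting, and its noise-ensemble extension
# (EEMD). Envelopes are natural cubic splines through local extrema with
# mirror-extended boundaries; sifting stops on a Cauchy-type criterion.

# Indices of strict local maxima/minima. Plateaus are handled by carrying
# the last non-zero slope sign, so a flat top counts once.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  s <- sign(diff(x))
  # propagate the previous non-zero sign through zero slopes
  nz <- s != 0
  if (!any(nz)) return(list(maxima = integer(0), minima = integer(0)))
  filled <- s
  last <- 0
  for (i in seq_along(filled)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  ds <- diff(filled)
  maxima <- which(ds == -2) + 1L
  minima <- which(ds == 2) + 1L
  list(maxima = maxima, minima = minima)
}

# Envelope through extrema (idx, x[idx]) evaluated at 1..n. Boundaries are
# mirrored: the outermost extrema are reflected about the first and last
# sample so the spline is supported beyond both ends. With fewer than 4
# extrema the natural spline is replaced by linear interpolation.
envelope <- function(x, idx) {
  n <- length(x)
  if (length(idx) == 0) return(rep(0, n))
  if (length(idx) == 1) return(rep(x[idx], n))
  k <- min(2L, length(idx))
  left_i <- 2 - idx[seq_len(k)]            # reflect about sample 1
  left_v <- x[idx[seq_len(k)]]
  right_src <- idx[seq(length(idx), by = -1L, length.out = k)]
  right_i <- 2 * n - right_src             # reflect about sample n
  right_v <- x[right_src]
  xi <- c(left_i, idx, right_i)
  yi <- c(left_v, x[idx], right_v)
  ord <- order(xi)
  xi <- xi[ord]; yi <- yi[ord]
  keep <- !duplicated(xi)
  xi <- xi[keep]; yi <- yi[keep]
  if (length(idx) < 4) {
    stats::approx(xi, yi, xout = seq_len(n), rule = 2)$y
  } else {
    stats::spline(xi, yi, xout = seq_len(n), method = "natural")$y
  }
}

# Extract one intrinsic mode function from `r` by sifting, or NULL when `r`
# has too few extrema to carry an oscillatory mode.
sift_imf <- function(r, max_sift_iters, sd_threshold) {
  h <- r
  for (iter in seq_len(max_sift_iters)) {
    ext <- local_extrema(h)
    if (length(ext$maxima) + length(ext$minima) < 3) {
      if (iter == 1) return(NULL)
      break
    }
    upper <- envelope(h, ext$maxima)
    lower <- envelope(h, ext$minima)
    m <- (upper + lower) / 2
    h_new <- h - m
    denom <- sum(h^2)
    sd_k <- if (denom > 0) sum((h - h_new)^2) / denom else 0
    h <- h_new
    if (sd_k < sd_threshold) break
  }
  h
}

#' Empirical mode decomposition
#'
#' Decomposes a uniformly sampled series into intrinsic mode functions
#' (IMFs, ordered highest frequency first) and a low-frequency residual by
#' iterative sifting: local extrema are bracketed by upper and lower natural
#' cubic-spline envelopes (mirror-extended at the boundaries), the envelope
#' mean is subtracted, and the step repeats until the Cauchy-type criterion
#' \eqn{SD = \sum (h_{k-1}-h_k)^2 / \sum h_{k-1}^2 < } `sd_threshold` or
#' `max_sift_iters` is hit. The accepted IMF is subtracted and sifting
#' recurses on the remainder until it is monotone, has fewer than 3 extrema,
#' or `max_imfs` modes have been extracted.
#'
#' The decomposition is exactly additive: `rowSums(imfs) + residual`
#' reconstructs the input to floating-point round-off.
#'
#' @param x Numeric vector, length >= 8, finite values.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param max_sift_iters Maximum sifting iterations per IMF (>= 1).
#' @param sd_threshold Sifting stop threshold in (0, 1); default 0.2.
#' @param boundary Boundary handling; only `"mirror"` is implemented.
#' @return An object of class `"imf_decomposition"`: a list with `imfs`
#'   (n-by-k matrix, columns `IMF1`, `IMF2`, ...), `residual`, `n`,
#'   `ensemble_size`, `noise_sd` and `degenerate` (TRUE when the input had
#'   no oscillatory mode, in which case `imfs` has zero columns and the
#'   residual is the input itself).
#' @examples
#' t <- seq(0, 5, by = 0.005)
#' dec <- emd(sin(2 * pi * 20 * t) + sin(2 * pi * 2 * t))
#' ncol(dec$imfs)
#' @export
emd <- function(x, max_imfs = Inf, max_sift_iters = 50, sd_threshold = 0.2,
                boundary = "mirror") {
  check_numeric_vector(x, "x", min_len = 8)
  if (max_sift_iters < 1) abort("`max_sift_iters` must be >= 1.")
  if (sd_threshold <= 0 || sd_threshold >= 1) {
    abort("`sd_threshold` must lie in (0, 1).")
  }
  boundary <- match.arg(boundary, "mirror")
  n <- length(x)
  r <- x
  imfs <- list()
  tol <- 1e-12 * max(abs(x), 1e-300)
  while (length(imfs) < max_imfs) {
    imf <- sift_imf(r, max_sift_iters, sd_threshold)
    # a negligible mode means the remainder carries only numerical noise
    if (is.null(imf) || max(abs(imf)) <= tol) break
    imfs[[length(imfs) + 1L]] <- imf
    r <- r - imf
  }
  k <- length(imfs)
  m <- if (k > 0) do.call(cbind, imfs) else matrix(numeric(0), nrow = n, ncol = 0)
  colnames(m) <- if (k > 0) paste0("IMF", seq_len(k)) else character(0)
  structure(list(imfs = m, residual = r, n = n, ensemble_size = 1L,
                 noise_sd = 0, degenerate = (k == 0)),
            class = "imf_decomposition")
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `ensemble_size` copies of the signal, each perturbed with
#' fresh white Gaussian noise of standard deviation
#' `noise_sd_ratio * sd(x)`, and averages corresponding IMFs across trials.
#' The added noise populates all scales so that modes separate consistently,
#' counteracting the mode mixing that plain sifting suffers on
#' non-stationary signals; the averaged modes retain a residual noise floor
#' that shrinks like `1/sqrt(ensemble_size)`.
#'
#' Trials are aligned to a fixed mode count `min(max_imfs,
#' floor(log2(n)) - 1)`: trials producing fewer IMFs are padded with zero
#' modes, extra IMFs are folded into the trial residual before averaging.
#' With `noise_sd_ratio = 0` (or an ensemble of one noiseless trial) the
#' result is identical to [emd()].
#'
#' @inheritParams emd
#' @param ensemble_size Number of noise-perturbed trials (>= 1).
#' @param noise_sd_ratio Noise standard deviation as a fraction of `sd(x)`
#'   (>= 0); default 0.2, standard EEMD practice.
#' @param seed Integer seed; the full ensemble is reproducible.
#' @return An `"imf_decomposition"` (see [emd()]) with `ensemble_size` and
#'   `noise_sd` recording the ensemble settings.
#' @export
eemd <- function(x, ensemble_size = 100, noise_sd_ratio = 0.2, seed = 1,
                 max_imfs = Inf, max_sift_iters = 50, sd_threshold = 0.2,
                 boundary = "mirror") {
  check_numeric_vector(x, "x", min_len = 8)
  if (ensemble_size < 1) abort("`ensemble_size` must be >= 1.")
  if (noise_sd_ratio < 0) abort("`noise_sd_ratio` must be >= 0.")
  if (noise_sd_ratio == 0) {
    return(emd(x, max_imfs = max_imfs, max_sift_iters = max_sift_iters,
               sd_threshold = sd_threshold, boundary = boundary))
  }
  n <- length(x)
  noise_sd <- noise_sd_ratio * stats::sd(x)
  target <- max(1L, min(max_imfs, floor(log2(n)) - 1L))
  sum_imfs <- matrix(0, nrow = n, ncol = target)
  sum_res <- rep(0, n)
  for (trial in seq_len(ensemble_size)) {
    noise <- with_seed(child_seed(seed, trial), rnorm(n, 0, noise_sd))
    dec <- emd(x + noise, max_imfs = target, max_sift_iters = max_sift_iters,
               sd_threshold = sd_threshold, boundary = boundary)
    k <- ncol(dec$imfs)
    res <- dec$residual
    if (k > target) {
      res <- res + rowSums(dec$imfs[, (target + 1L):k, drop = FALSE])
      k <- target
    }
    if (k > 0) {
      sum_imfs[, seq_len(k)] <- sum_imfs[, seq_len(k)] + dec$imfs[, seq_len(k), drop = FALSE]
    }
    sum_res <- sum_res + res
  }
  m <- sum_imfs / ensemble_size
  colnames(m) <- paste0("IMF", seq_len(target))
  structure(list(imfs = m, residual = sum_res / ensemble_size, n = n,
                 ensemble_size = as.integer(ensemble_size),
                 noise_sd = noise_sd, degenerate = FALSE),
            class = "imf_decomposition")
}

#' Number of zero crossings of a series
#'
#' Counts sign changes, ignoring exact zeros. IMFs from [emd()] are ordered
#' from fastest to slowest oscillation, so their zero-crossing counts are
#' non-increasing.
#' @param x Numeric vector.
#' @return Integer count.
#' @export
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d samples, %d IMF(s) + residual",
              x$n, ncol(x$imfs)))
  if (x$ensemble_size > 1) {
    cat(sprintf(" [EEMD: ensemble %d, noise sd %.4g]", x$ensemble_size, x$noise_sd))
  }
  if (isTRUE(x$degenerate)) cat(" [degenerate: no oscillatory mode]")
  cat("\n")
  invisible(x)
}

#' @export
as_tibble.imf_decomposition <- function(x, ...) {
  comps <- c(as.list(as.data.frame(x$imfs)), list(res = x$residual))
  tibble(index = rep(seq_len(x$n), times = length(comps)),
         component = factor(rep(names(comps), each = x$n), levels = names(comps)),
         value = unlist(comps, use.names = FALSE))
}

#' @export
autoplot.imf_decomposition <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "sample", y = NULL)
}
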