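#' Simulate a tremor-contaminated control signal with known decomposition
#'
#' Generates the additive model used throughout the package: per axis, an
#' actual signal \eqn{a(k) = e(k) + t(k)} where \eqn{e(k)} is a smooth
#' low-frequency desired motion and \eqn{t(k)} is a band-limited,
#' quasi-periodic physiological tremor plus measurement noise. Physiological
#' hand tremor is conventionally an 8--12 Hz oscillation riding on voluntary
#' motion below ~2 Hz; the defaults widen the band slightly to 6--14 Hz.
#'
#' The desired motion is a sum of sinusoids at `drift_freqs` with random
#' phases. The tremor is a sum of `n_carriers` sinusoids with frequencies
#' drawn uniformly from `tremor_band`, each slowly amplitude-modulated
#' (depth 0.3 at 0.1 Hz) and phase-modulated, plus white Gaussian noise of
#' standard deviation `noise_sd`. The noise is part of the tremor component,
#' so `actual == desired + tremor` holds exactly, element-wise.
#'
#' @param n Number of samples per axis (>= 100).
#' @param dt Sampling interval in seconds (> 0).
#' @param tremor_band Length-2 numeric, tremor frequency band in Hz; must
#'   satisfy `0 < f_lo < f_hi < 1/(2*dt)` (the Nyquist limit).
#' @param tremor_amp Peak amplitude of the tremor carriers (signal units).
#'   Zero gives a tremor-free signal.
#' @param drift_freqs Frequencies (Hz) of the desired-motion sinusoids, all
#'   below the tremor band.
#' @param drift_amp Amplitude of the desired-motion sinusoids (signal units).
#' @param noise_sd Standard deviation of the additive white measurement
#'   noise (signal units).
#' @param n_carriers Number of tremor carrier sinusoids (1--3).
#' @param axes Character vector of axis names (1--3 axes).
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#'
#' @return A tibble of class `"tremor_truth"` in long format with columns
#'   `time`, `axis`, `desired`, `tremor`, `actual`, and attributes `dt` and
#'   `seed`.
#' @examples
#' truth <- simulate_tremor(n = 500, seed = 1)
#' dplyr::glimpse(truth)
#' @export
simulate_tremor <- function(n = 960,
                            dt = 0.01,
                            tremor_band = c(6, 14),
                            tremor_amp = 1,
                            drift_freqs = c(0.2, 0.5),
                            drift_amp = 5,
                            noise_sd = 0.05,
                            n_carriers = 2,
                            axes = c("x", "y", "z"),
                            seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 100 || n != round(n)) {
    abort("`n` must be a single integer >= 100.")
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    abort("`dt` must be a single positive number (seconds).")
  }
  if (!is.numeric(tremor_band) || length(tremor_band) != 2 ||
      tremor_band[1] <= 0 || tremor_band[1] >= tremor_band[2] ||
      tremor_band[2] >= 1 / (2 * dt)) {
    abort("`tremor_band` must satisfy 0 < f_lo < f_hi < 1/(2*dt) (Nyquist).")
  }
  if (tremor_amp < 0 || noise_sd < 0 || drift_amp < 0) {
    abort("Amplitudes and `noise_sd` must be non-negative.")
  }
  if (!(n_carriers %in% 1:3)) abort("`n_carriers` must be 1, 2 or 3.")
  if (length(axes) < 1 || length(axes) > 3 || anyDuplicated(axes)) {
    abort("`axes` must be 1-3 distinct axis names.")
  }

  tt <- (seq_len(n) - 1) * dt
  per_axis <- with_seed(seed, {
    purrr::map(seq_along(axes), function(ax) {
      desired <- rep(0, n)
      for (f in drift_freqs) {
        a <- drift_amp * runif(1, 0.5, 1) / length(drift_freqs)
        desired <- desired + a * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
      }
      tremor <- rep(0, n)
      if (tremor_amp > 0) {
        for (j in seq_len(n_carriers)) {
          f <- runif(1, tremor_band[1], tremor_band[2])
          a <- tremor_amp * runif(1, 0.5, 1) / n_carriers
          am <- 1 + 0.3 * sin(2 * pi * 0.1 * tt + runif(1, 0, 2 * pi))
          pm <- 0.3 * sin(2 * pi * 0.05 * tt + runif(1, 0, 2 * pi))
          tremor <- tremor + a * am * sin(2 * pi * f * tt + pm + runif(1, 0, 2 * pi))
        }
      }
      if (noise_sd > 0) tremor <- tremor + rnorm(n, 0, noise_sd)
      tibble(time = tt, axis = axes[ax], desired = desired,
             tremor = tremor, actual = desired + tremor)
    })
  })
  out <- dplyr::bind_rows(per_axis)
  attr(out, "dt") <- dt
  attr(out, "seed") <- seed
  class(out) <- c("tremor_truth", class(out))
  out
}

#' Extract one component of a simulated truth as a wide signal table
#'
#' @param truth A `"tremor_truth"` tibble from [simulate_tremor()].
#' @param component One of `"actual"`, `"desired"`, `"tremor"`.
#' @return A wide tibble with a `time` column and one numeric column per
#'   axis, carrying the sampling interval as attribute `dt`.
#' @export
truth_signal <- function(truth, component = c("actual", "desired", "tremor")) {
  component <- match.arg(component)
  stopifnot(inherits(truth, "tremor_truth"))
  out <- truth |>
    dplyr::select("time", "axis", value = dplyr::all_of(component)) |>
    tidyr::pivot_wider(names_from = "axis", values_from = "value")
  attr(out, "dt") <- attr(truth, "dt")
  out
}

#' @export
autoplot.tremor_truth <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = c("desired", "tremor", "actual"),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$axis)) +
    ggplot2::labs(x = "time (s)", y = "signal", colour = NULL)
}
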