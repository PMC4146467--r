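#' Periodogram of an ensemble series
#'
#' Plain discrete-Fourier periodogram (no tapering or windowing) of the
#' mean-centered series: the signals produced by a finite synchronous
#' network are exactly periodic in steady state, so spectral lines are
#' genuine Dirac-like modes and leakage control is unnecessary. To make the
#' lines land exactly on rational frequencies `k/p`, the analysis window is
#' trimmed to the largest multiple of the detected recurrence module that
#' fits in `n_steps` (disable with `trim_to_module = FALSE`).
#'
#' Frequencies are in cycles per simulation step, in `(0, 1/2]`; the
#' zero-frequency (mean) term is excluded. Power is normalized so that the
#' total power equals the variance of the analyzed window (a Parseval
#' identity).
#'
#' @param series an [ensemble_average()] result, or any data frame with a
#'   `value` column, or a bare numeric vector.
#' @param n_steps number of leading steady-state points analyzed.
#' @param trim_to_module trim the window to a whole number of recurrence
#'   modules before transforming.
#' @return a tibble of class `power_spectrum` with columns `frequency`,
#'   `power`; attributes `n_used` and `module`.
#' @export
power_spectrum <- function(series, n_steps = 1000, trim_to_module = TRUE) {
  v <- series_values(series)
  if (length(v) < n_steps) stop("series has fewer than n_steps points", call. = FALSE)
  v <- v[seq_len(n_steps)]
  module <- NA_integer_
  if (trim_to_module) {
    module <- recurrent_module_length(v, tol = 1e-9)
    if (!is.na(module) && module > 0) {
      v <- v[seq_len((length(v) %/% module) * module)]
    }
  }
  n <- length(v)
  vc <- v - mean(v)
  X <- stats::fft(vc)
  kmax <- n %/% 2
  k <- seq_len(kmax)
  pow <- Mod(X[k + 1])^2 / n^2
  mult <- rep(2, kmax)
  if (n %% 2 == 0) mult[kmax] <- 1
  out <- tibble::tibble(frequency = k / n, power = mult * pow)
  attr(out, "n_used") <- n
  attr(out, "module") <- module
  class(out) <- c("power_spectrum", class(out))
  out
}

series_values <- function(series) {
  if (is.numeric(series)) return(as.numeric(series))
  if (is.data.frame(series) && "value" %in% names(series)) return(series$value)
  stop("expected a numeric vector or a data frame with a 'value' column", call. = FALSE)
}

#' Dominant spectral lines and their integer periods
#'
#' Retains every line whose power is at least `threshold_frac` of the
#' strongest line, maps each to its nearest integer period `round(1/f)`,
#' and annotates lines that sit at integer multiples of a lower retained
#' frequency as harmonics of that fundamental.
#'
#' @param spectrum a [power_spectrum()] result.
#' @param threshold_frac retention threshold as a fraction of the maximum
#'   power, in `(0, 1]`.
#' @return tibble sorted by descending power: `frequency`, `power`,
#'   `period` (nearest integer to `1/frequency`), `harmonic_of` (the
#'   fundamental's period, or `NA` for a fundamental line).
#' @export
dominant_periods <- function(spectrum, threshold_frac = 0.05) {
  stopifnot(threshold_frac > 0, threshold_frac <= 1)
  if (nrow(spectrum) == 0) stop("empty spectrum", call. = FALSE)
  pmax_ <- max(spectrum$power)
  keep <- spectrum[spectrum$power >= threshold_frac * pmax_ & spectrum$power > 0, ]
  keep <- keep[order(-keep$power), ]
  if (nrow(keep) == 0) {
    return(tibble::tibble(frequency = numeric(), power = numeric(),
                          period = integer(), harmonic_of = integer()))
  }
  keep$period <- as.integer(round(1 / keep$frequency))
  keep$harmonic_of <- NA_integer_
  fr <- sort(unique(keep$frequency))
  for (i in seq_len(nrow(keep))) {
    lower <- fr[fr < keep$frequency[i] - 1e-12]
    for (f0 in lower) {
      ratio <- keep$frequency[i] / f0
      if (abs(ratio - round(ratio)) < 1e-6 && round(ratio) >= 2) {
        keep$harmonic_of[i] <- as.integer(round(1 / f0))
        break
      }
    }
  }
  keep
}

#' Number of dominant Fourier modes
#'
#' The regularity metric of the effect matrix: how many spectral lines
#' survive the retention threshold. A single-attractor, single-period series
#' scores low; mixtures of attractors with incommensurate periods score
#' high.
#'
#' @inheritParams dominant_periods
#' @return integer count of retained lines.
#' @export
mode_diversity <- function(spectrum, threshold_frac = 0.05) {
  nrow(dominant_periods(spectrum, threshold_frac))
}

#' Running (sliding) average of a series
#'
#' Arithmetic mean over a sliding window of `w` consecutive points; the
#' output has `length - w + 1` points. Averaging with a window equal to the
#' period of an exactly periodic component removes that component entirely,
#' which is what exposes slower envelope structure (e.g. a beat between two
#' attractor periods) in the averaged calcium traces.
#'
#' @inheritParams power_spectrum
#' @param w window length, `>= 1`.
#' @return same shape as the input: a numeric vector, or a tibble with `t`
#'   (time of the window start) and `value`.
#' @export
running_average <- function(series, w) {
  v <- series_values(series)
  if (w < 1) stop("window must be >= 1", call. = FALSE)
  if (w > length(v)) stop("window exceeds the series length", call. = FALSE)
  out <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 1))
  out <- out[w:length(v)]
  if (is.numeric(series)) return(out)
  res <- tibble::tibble(t = series$t[seq_along(out)], value = out)
  attr(res, "window") <- w
  res
}

#' Smallest recurrence module of a steady-state series
#'
#' The smallest `p` such that the series repeats with lag `p` everywhere
#' (`|v[t+p] - v[t]| <= tol` for all valid `t`). For an ensemble average
#' over several attractors this is the least common multiple of the
#' contributing periods; for a flat series it is 1. Ensemble averages of a
#' fixed set of deterministic trajectories are exactly periodic in steady
#' state, so the default tolerance is essentially machine precision.
#'
#' @inheritParams power_spectrum
#' @param tol maximum allowed pointwise deviation between the series and its
#'   lag-`p` shift.
#' @param max_module largest module searched (default: half the series
#'   length).
#' @return integer `p`, or `NA` (aperiodic at this scale) if no module up to
#'   `max_module` fits.
#' @export
recurrent_module_length <- function(series, tol = 1e-9, max_module = NULL) {
  v <- series_values(series)
  n <- length(v)
  if (is.null(max_module)) max_module <- n %/% 2
  for (p in seq_len(max_module)) {
    if (max(abs(v[(p + 1):n] - v[1:(n - p)])) <= tol) return(as.integer(p))
  }
  NA_integer_
}
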