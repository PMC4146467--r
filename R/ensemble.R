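#' Ensemble-averaged node trace over many initial conditions
#'
#' Evolves a large set of initial conditions in parallel under a (possibly
#' clamped) network and records, at every time step after a discarded
#' transient, the mean value of one node across the ensemble. For the
#' calcium node of the SASP network this is the modelled counterpart of a
#' fluorescence trace: a real-valued series in `[0, 2]` whose oscillations
#' superpose the contributions of all attractors weighted by their basins.
#' All initial conditions start in phase at time 0 (speract switched on
#' simultaneously), which is what makes the ensemble mean oscillate rather
#' than wash out.
#'
#' @inheritParams basin_statistics
#' @param node node whose value is averaged (default `"Ca"`).
#' @param n_ic ensemble size (sample mode).
#' @param t_max number of recorded steps after the transient; the series has
#'   `t_max + 1` values.
#' @param transient steps discarded before recording begins.
#' @return an `ensemble_series`: tibble with columns `t` (0-based, counted
#'   from the end of the discarded transient) and `value`, with attributes
#'   `node`, `n_ic`, `seed`, `transient`, `clamps`.
#' @export
ensemble_average <- function(net, clamps = NULL, node = "Ca", n_ic = 1e5,
                             seed = NULL, t_max = 1100, transient = 150,
                             ic_policy = NULL, mode = c("sample", "exhaustive")) {
  mode <- match.arg(mode)
  i <- node_index(net, node)
  cn <- compile_network(net)
  cl <- resolve_clamps(net, clamps)
  if (mode == "sample") {
    if (is.null(seed)) stop("sample mode requires a seed", call. = FALSE)
    set.seed(seed)
  }
  S <- make_ics(net, ic_policy, mode, n_ic)
  vals <- engine_mean_series(S, cn$tables, cn$reg_idx, cn$weights, cl$idx, cl$val,
                             as.integer(transient), as.integer(t_max),
                             as.integer(i))$series
  out <- tibble::tibble(t = 0:t_max, value = vals)
  attr(out, "node") <- node
  attr(out, "n_ic") <- nrow(S)
  attr(out, "seed") <- if (mode == "sample") seed else NA_integer_
  attr(out, "transient") <- transient
  attr(out, "clamps") <- clamps
  class(out) <- c("ensemble_series", class(out))
  out
}

#' @export
print.ensemble_series <- function(x, ...) {
  cat(sprintf("<ensemble_series> node %s, %d ICs, %d steps after a %d-step transient [%s]\n",
              attr(x, "node"), attr(x, "n_ic"), nrow(x) - 1, attr(x, "transient"),
              if (is.null(attr(x, "clamps"))) "WT" else perturbation_label(attr(x, "clamps"))))
  NextMethod()
}

#' Summary metrics of an ensemble series
#'
#' Over the first `window` steady-state steps: the arithmetic mean, the
#' peak (maximum), and the amplitude (full swing, maximum minus minimum).
#' The characteristic oscillation period is reported two ways — as the
#' reciprocal of the dominant periodogram frequency and as the mean spacing
#' between successive local maxima — because for superpositions of several
#' attractor periods the two need not agree.
#'
#' @param series an [ensemble_average()] result (or any tibble with `t`,
#'   `value`).
#' @param window number of leading steps summarized (default 50).
#' @return a one-row tibble of class `series_summary`: `mean`, `amplitude`,
#'   `peak`, `interpeak_interval` (spectral), `interpeak_interval_p2p`,
#'   `window`.
#' @export
summarize_series <- function(series, window = 50) {
  if (nrow(series) < window) stop("series shorter than the summary window", call. = FALSE)
  v <- series$value[seq_len(window)]
  spec_int <- tryCatch({
    ps <- power_spectrum(series, n_steps = window)
    if (max(ps$power) <= 0) NA_real_ else 1 / ps$frequency[which.max(ps$power)]
  }, error = function(e) NA_real_)
  out <- tibble::tibble(
    mean = mean(v),
    amplitude = max(v) - min(v),
    peak = max(v),
    interpeak_interval = spec_int,
    interpeak_interval_p2p = peak_to_peak_interval(v),
    window = as.integer(window)
  )
  class(out) <- c("series_summary", class(out))
  out
}

# mean spacing of strict local maxima; NA when fewer than two
peak_to_peak_interval <- function(v) {
  n <- length(v)
  if (n < 3) return(NA_real_)
  pk <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(pk) < 2) return(NA_real_)
  mean(diff(pk))
}

#' Direction-of-change comparison against the wild type
#'
#' Classifies each metric of a treated scenario relative to the wild type as
#' `"up"`, `"down"` or `"equal"`, using a tolerance expressed as a fraction
#' of the wild-type value (default 1%): differences within the tolerance
#' band count as equal.
#'
#' @param wt,treated [summarize_series()] results with the same window.
#' @param tol_frac half-width of the "equal" band, as a fraction of the
#'   wild-type metric value.
#' @return a tibble with columns `metric`, `wt`, `treated`, `arrow`.
#' @export
compare_to_wt <- function(wt, treated, tol_frac = 0.01) {
  if (wt$window != treated$window) stop("mismatched summary windows", call. = FALSE)
  metrics <- c("mean", "amplitude", "peak")
  purrr::map_dfr(metrics, function(m) {
    a <- wt[[m]]
    b <- treated[[m]]
    tol <- abs(a) * tol_frac
    tibble::tibble(metric = m, wt = a, treated = b,
                   arrow = if (b - a > tol) "up" else if (a - b > tol) "down" else "equal")
  })
}

#' Basin-weighted steady-state mean of a node
#'
#' The exact long-run time average of a node over an initial-condition
#' space: each attractor contributes the time mean of the node over its
#' cycle, weighted by its basin fraction. Under exhaustive enumeration this
#' equals the time average of the exhaustive ensemble series over one full
#' recurrence module (the lcm of the attractor periods).
#'
#' @param catalogue a [basin_statistics()] result.
#' @param node node name.
#' @return a single number.
#' @export
steady_state_mean <- function(catalogue, node) {
  cycles <- attr(catalogue, "cycles")
  contrib <- vapply(seq_len(nrow(catalogue)), function(r) {
    mean(cycles[[r]][, node])
  }, numeric(1))
  sum(catalogue$basin_fraction * contrib)
}
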