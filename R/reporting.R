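#' Run the full perturbation suite on a network
#'
#' Computes, for every scenario in [scenario_suite()] (or any named list of
#' perturbations), the attractor catalogue, the ensemble-averaged node
#' trace, its summary metrics, the periodogram and the recurrence module,
#' all under identical ensemble settings.
#'
#' @inheritParams ensemble_average
#' @param scenarios named list of [perturbation()] objects; `WT` (an empty
#'   perturbation) must be present for comparisons.
#' @param window summary window passed to [summarize_series()].
#' @param spectrum_steps steady-state points used by [power_spectrum()].
#' @param basin_n initial conditions used for the attractor catalogue
#'   (defaults to `n_ic`).
#' @return a named list of class `suite_result`, one element per scenario,
#'   each holding `spec`, `catalogue`, `series`, `stats`, `spectrum`,
#'   `module`; ensemble settings are stored as attributes.
#' @export
run_scenario_suite <- function(net, scenarios = scenario_suite(), node = "Ca",
                               n_ic = 1e5, seed = 1, transient = 150,
                               t_max = NULL, window = 50, spectrum_steps = 1000,
                               ic_policy = speract_policy(), basin_n = NULL) {
  if (is.null(t_max)) t_max <- spectrum_steps + window
  if (is.null(basin_n)) basin_n <- n_ic
  out <- purrr::imap(scenarios, function(sp, nm) {
    catalogue <- basin_statistics(net, clamps = sp, ic_policy = ic_policy,
                                  mode = "sample", n = basin_n, seed = seed)
    series <- ensemble_average(net, clamps = sp, node = node, n_ic = n_ic,
                               seed = seed, t_max = t_max, transient = transient,
                               ic_policy = ic_policy)
    list(spec = sp,
         catalogue = catalogue,
         series = series,
         stats = summarize_series(series, window = window),
         spectrum = power_spectrum(series, n_steps = spectrum_steps),
         module = recurrent_module_length(series$value))
  })
  attr(out, "settings") <- list(node = node, n_ic = n_ic, seed = seed,
                                transient = transient, window = window,
                                spectrum_steps = spectrum_steps)
  class(out) <- c("suite_result", class(out))
  out
}

#' Arrow (effect) matrix of a perturbation suite
#'
#' Condenses a [run_scenario_suite()] result into the qualitative effect
#' matrix: for each non-WT scenario, the direction of change versus the wild
#' type of the ensemble mean, amplitude, peak, and the Fourier-mode
#' diversity. Numeric metrics use the relative tolerance band of
#' [compare_to_wt()]; the integer diversity metric compares exactly.
#' CaKC-activated scenarios are flagged `scenario = 2`.
#'
#' @param suite a [run_scenario_suite()] result containing a `WT` element.
#' @param tol_frac tolerance band for "equal", as a fraction of the WT
#'   metric.
#' @param threshold_frac spectral-line retention threshold for the
#'   diversity metric.
#' @return a tibble of class `arrow_table`: `scenario_label`, `scenario`,
#'   `metric`, `wt`, `treated`, `arrow`.
#' @export
build_arrow_table <- function(suite, tol_frac = 0.01, threshold_frac = 0.05) {
  if (!"WT" %in% names(suite)) stop("suite must contain a WT scenario", call. = FALSE)
  wt <- suite$WT
  wt_div <- mode_diversity(wt$spectrum, threshold_frac)
  rows <- purrr::imap(suite, function(sc, nm) {
    if (nm == "WT") return(NULL)
    num <- compare_to_wt(wt$stats, sc$stats, tol_frac = tol_frac)
    div <- mode_diversity(sc$spectrum, threshold_frac)
    dplyr::bind_rows(
      num,
      tibble::tibble(metric = "fourier_mode_diversity",
                     wt = as.numeric(wt_div), treated = as.numeric(div),
                     arrow = if (div > wt_div) "up" else if (div < wt_div) "down" else "equal")
    ) |>
      dplyr::mutate(scenario_label = nm,
                    scenario = attr(sc$spec, "scenario") %||% 1L,
                    .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("arrow_table", class(out))
  out
}

#' @export
print.arrow_table <- function(x, ...) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(x)[, c("scenario_label", "metric", "arrow")],
                             names_from = "scenario_label", values_from = "arrow")
  cat("<arrow_table> direction of change vs WT\n")
  print(as.data.frame(wide), right = FALSE)
  invisible(x)
}

#' Per-scenario report
#'
#' A self-contained textual summary of one scenario of a suite run: its
#' clamps, attractor periods and basin fractions, transient statistics,
#' summary metrics of the averaged trace, dominant spectral lines, the
#' recurrence module of the raw series, and the modules that survive
#' running averages over selected windows.
#'
#' @param suite a [run_scenario_suite()] result.
#' @param scenario scenario name (an element of `names(suite)`).
#' @param avg_windows running-average windows whose surviving module is
#'   reported.
#' @return a list of class `scenario_report` with fields `label`,
#'   `attractors`, `stats`, `lines`, `module`, `envelope_modules`; printed
#'   as a compact report.
#' @export
scenario_report <- function(suite, scenario, avg_windows = c(3, 4, 8)) {
  if (!scenario %in% names(suite)) stop("unknown scenario: ", scenario, call. = FALSE)
  sc <- suite[[scenario]]
  env_mod <- purrr::map_int(avg_windows, function(w) {
    recurrent_module_length(running_average(sc$series, w)$value)
  })
  out <- list(
    label = scenario,
    attractors = tibble::as_tibble(sc$catalogue),
    stats = sc$stats,
    lines = dominant_periods(sc$spectrum),
    module = sc$module,
    envelope_modules = tibble::tibble(window = as.integer(avg_windows),
                                      module = env_mod)
  )
  class(out) <- "scenario_report"
  out
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("== scenario: %s ==\n", x$label))
  cat(sprintf("attractors (period | basin): %s\n",
              paste(sprintf("%d | %.3f", x$attractors$period, x$attractors$basin_fraction),
                    collapse = ", ")))
  cat(sprintf("trace: mean %.3f, amplitude %.3f, peak %.3f\n",
              x$stats$mean, x$stats$amplitude, x$stats$peak))
  cat(sprintf("recurrence module: %s; dominant lines: %s\n",
              x$module, paste(sprintf("1/%d", x$lines$period), collapse = ", ")))
  for (i in seq_len(nrow(x$envelope_modules))) {
    cat(sprintf("running average w=%d -> surviving module %s\n",
                x$envelope_modules$window[i], x$envelope_modules$module[i]))
  }
  invisible(x)
}
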