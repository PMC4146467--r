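#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an attractor catalogue
#'
#' @param x a [basin_statistics()] result.
#' @param ... unused.
#' @return a plain tibble, one row per attractor.
#' @exportS3Method generics::tidy
tidy.attractor_catalogue <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.attractor_catalogue
#' @exportS3Method generics::glance
glance.attractor_catalogue <- function(x, ...) {
  s <- attr(x, "sampling")
  tibble::tibble(
    n_attractors = nrow(x),
    periods = paste(x$period, collapse = "/"),
    dominant_fraction = max(x$basin_fraction),
    max_transient = max_transient(x),
    mean_transient = mean_transient(x),
    mode = s$mode,
    n_ic = s$n
  )
}

#' Tidy / glance an ensemble series
#'
#' @param x an [ensemble_average()] result.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.ensemble_series <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.ensemble_series
#' @param window summary window (see [summarize_series()]).
#' @exportS3Method generics::glance
glance.ensemble_series <- function(x, window = 50, ...) {
  st <- summarize_series(x, window = window)
  dplyr::mutate(tibble::as_tibble(st),
                node = attr(x, "node"), n_ic = attr(x, "n_ic"),
                transient = attr(x, "transient"),
                scenario = if (is.null(attr(x, "clamps"))) "WT"
                           else perturbation_label(attr(x, "clamps")))
}

#' Tidy a suite run into one row of metrics per scenario
#'
#' @param x a [run_scenario_suite()] result.
#' @param ... unused.
#' @return tibble with one row per scenario: summary metrics, attractor
#'   periods, recurrence module and mode diversity.
#' @exportS3Method generics::tidy
tidy.suite_result <- function(x, ...) {
  purrr::imap_dfr(x, function(sc, nm) {
    tibble::tibble(
      scenario_label = nm,
      scenario = attr(sc$spec, "scenario") %||% 1L,
      mean = sc$stats$mean,
      amplitude = sc$stats$amplitude,
      peak = sc$stats$peak,
      interpeak_interval = sc$stats$interpeak_interval,
      periods = paste(sc$catalogue$period, collapse = "/"),
      module = sc$module,
      mode_diversity = mode_diversity(sc$spectrum),
      max_transient = max_transient(sc$catalogue)
    )
  })
}
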