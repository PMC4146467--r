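#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ensemble-averaged trace
#'
#' @param object an [ensemble_average()] result.
#' @param window optional: overlay the running average over this window.
#' @param t_range time range shown (default: first 100 steps).
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_series <- function(object, window = NULL,
                                     t_range = c(0, 100), ...) {
  df <- dplyr::filter(tidy(object), .data$t >= t_range[1], .data$t <= t_range[2])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "simulation step (after discarded transient)",
      y = sprintf("ensemble-averaged %s", attr(object, "node")),
      title = if (is.null(attr(object, "clamps"))) "WT"
              else perturbation_label(attr(object, "clamps"))
    )
  if (!is.null(window)) {
    ra <- running_average(object, window)
    ra <- dplyr::filter(ra, .data$t >= t_range[1], .data$t <= t_range[2])
    p <- p + ggplot2::geom_line(data = ra, colour = "firebrick", linewidth = 0.6)
  }
  p
}

#' Plot a periodogram as spectral lines
#'
#' @param object a [power_spectrum()] result.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.power_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$frequency, yend = 0)) +
    ggplot2::labs(x = "frequency (cycles per simulation step)", y = "power")
}

#' Plot basin fractions of an attractor catalogue
#'
#' @param object a [basin_statistics()] result.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.attractor_catalogue <- function(object, ...) {
  df <- tidy(object)
  df$label <- sprintf("period %d", df$period)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, -.data$basin_fraction),
                                   y = .data$basin_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "basin fraction")
}

#' Plot an effect matrix
#'
#' Tile view of a [build_arrow_table()]: metrics by scenario, cells showing
#' the direction of change versus the wild type.
#'
#' @param object an `arrow_table`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.arrow_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$glyph <- c(up = "↑", down = "↓", equal = "=")[df$arrow]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario_label, y = .data$metric)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$arrow), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$glyph)) +
    ggplot2::scale_fill_manual(values = c(up = "#d7795f", down = "#7aa6c2",
                                          equal = "grey90")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}
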