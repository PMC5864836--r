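#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an LMMSE artifact decomposition
#'
#' Raw and cleaned traces stacked on a shared time axis, with the artifact
#' estimate in between. The mV-scale bursts dominate the raw panel and
#' should be absent from the cleaned one.
#'
#' @param object An `egg_lmmse` from [remove_artifacts()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.egg_lmmse <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("observed", "artifact", "egg"),
                        names_to = "component", values_to = "uv") |>
    dplyr::mutate(component = factor(.data$component,
                                     c("observed", "artifact", "egg"),
                                     c("observed", "artifact estimate",
                                       "cleaned EGG")))
  ggplot2::ggplot(d, ggplot2::aes(.data$time / 60, .data$uv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram
#'
#' Time-frequency heat map of dB power, restricted to the EGG analysis
#' band by default. The gastric slow wave appears as a horizontal band
#' near 0.05 Hz; motion artifacts as broadband vertical stripes.
#'
#' @param object An `egg_spectrogram`.
#' @param freq_range Frequency range in Hz to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.egg_spectrogram <- function(object, freq_range = c(0.0, 0.20), ...) {
  d <- tidy(object) |>
    dplyr::filter(.data$freq >= freq_range[1], .data$freq <= freq_range[2])
  ggplot2::ggplot(d, ggplot2::aes(.data$time / 3600, .data$freq,
                                  fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "power (dB)") +
    ggplot2::labs(x = "time (h)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot an event-aligned feature average
#'
#' Per-event traces in grey with the across-event mean and a +/- 1 SD
#' ribbon, relative to the anchor event at time zero.
#'
#' @param object An `egg_alignment` from [align_by_event()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.egg_alignment <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$rel_time / 3600, .data$mean)) +
    ggplot2::geom_line(data = object$aligned,
                       ggplot2::aes(y = .data$value,
                                    group = .data$event),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event (h)", y = object$feature) +
    ggplot2::theme_minimal()
}

#' Plot an EGG-manometry correlation
#'
#' Scatter of motility index against EGG band power with the least-squares
#' fit, annotated with r and the adjusted p-value.
#'
#' @param object An `egg_correlation` from [correlate_egg_manometry()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.egg_correlation <- function(object, ...) {
  d <- tibble::tibble(x = object$fit$model$x, y = object$fit$model$y)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = "EGG band power (dB)", y = "motility index",
      subtitle = sprintf("r = %.2f, adjusted p = %.2g",
                         object$r, object$p_adjusted)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a per-window feature series
#'
#' @param features Tibble from [egg_features()].
#' @param value Feature column to plot (tidyselect; default
#'   `normalized_power_db`).
#' @param events Optional event tibble to mark as vertical lines.
#' @return A ggplot.
#' @export
plot_features <- function(features, value = NULL, events = NULL) {
  quo <- rlang::enquo(value)
  col <- if (rlang::quo_is_null(quo)) "normalized_power_db"
         else rlang::as_name(quo)
  p <- ggplot2::ggplot(features,
                       ggplot2::aes(.data$time / 3600, .data[[col]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = col) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(data = events,
                                 ggplot2::aes(xintercept = .data$time / 3600),
                                 linetype = "dashed", colour = "red")
  }
  p
}
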