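#' Plot a time-frequency map
#'
#' Raster plot of coefficient magnitudes (time on x, frequency on y).
#' Optionally overlays detected events as rectangles with centroid marks.
#'
#' @param object A `tf_map`.
#' @param events Optional events tibble from [detect_hfos()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_map <- function(object, events = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t_s, .data$f_hz)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$amplitude_au)) +
    ggplot2::scale_fill_viridis_c(option = "magma", name = "|coef| (au)") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p +
      ggplot2::geom_rect(
        data = as_tibble(events),
        ggplot2::aes(xmin = .data$t_start_s, xmax = .data$t_end_s,
                     ymin = .data$f_low_hz, ymax = .data$f_high_hz),
        inherit.aes = FALSE, colour = "green", fill = NA,
        linewidth = 0.4) +
      ggplot2::geom_point(
        data = as_tibble(events),
        ggplot2::aes(.data$t_center_s, .data$f_center_hz),
        inherit.aes = FALSE, colour = "green", shape = 1, size = 2)
  }
  p
}

#' Plot detected events on the time-frequency plane
#'
#' @param object An `hfo_events` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hfo_events <- function(object, ...) {
  ev <- as_tibble(object)
  ggplot2::ggplot(ev, ggplot2::aes(.data$t_center_s, .data$f_center_hz)) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$t_start_s, xmax = .data$t_end_s,
                   ymin = .data$f_low_hz, ymax = .data$f_high_hz),
      colour = "grey40", fill = NA, linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$amplitude_au)) +
    ggplot2::scale_colour_viridis_c(name = "amplitude (au)") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot benchmark metrics across SNRs
#'
#' Line plot of sensitivity, PPV and F-measure against SNR from a
#' [benchmark_detector()] result table.
#'
#' @param results The `results` tibble of [benchmark_detector()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results) {
  df <- results %>%
    filter(grepl("dB", .data$condition)) %>%
    mutate(snr_db = as.numeric(sub(" dB", "", .data$condition)))
  long <- tibble(
    snr_db = rep(df$snr_db, 3),
    metric = rep(c("sensitivity", "PPV", "F-measure"), each = nrow(df)),
    value = c(df$sensitivity, df$ppv, df$f_measure)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$snr_db, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNR (dB)", y = NULL, colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
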