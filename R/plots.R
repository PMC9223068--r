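#' Plot an IMU trace
#'
#' Acceleration components and signal vector magnitude over time, with the
#' fall threshold drawn as a reference line and any supplied events marked.
#'
#' @param stream An `imu_stream` tibble.
#' @param events Optional event tibble; event times are drawn as vertical
#'   lines labelled by kind.
#' @param fall_threshold_g Threshold reference line (default 2.5 g).
#' @return A ggplot object.
#' @export
plot_imu_trace <- function(stream, events = NULL, fall_threshold_g = 2.5) {
  stream <- validate_imu_stream(stream)
  df <- tidyr::pivot_longer(
    dplyr::mutate(stream, svm = signal_magnitude(.data$ax, .data$ay, .data$az)),
    cols = c("ax", "ay", "az", "svm"),
    names_to = "component", values_to = "value"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms / 1000, y = .data$value,
                                        colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = fall_threshold_g, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "time [s]", y = "acceleration [g]", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(
      data = events, ggplot2::aes(xintercept = .data$t_ms / 1000),
      linetype = "dotted", colour = "red"
    )
  }
  p
}

#' Plot a pressure-strip trace
#'
#' The three strip readings over time, optionally annotated with stable
#' presence events.
#'
#' @param stream A `pressure_stream` tibble.
#' @param events Optional `PRESENCE` event tibble.
#' @return A ggplot object.
#' @export
plot_pressure_trace <- function(stream, events = NULL) {
  stream <- validate_pressure_stream(stream)
  df <- tidyr::pivot_longer(stream, cols = c("left", "middle", "right"),
                            names_to = "strip", values_to = "counts")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms / 1000, y = .data$counts,
                                        colour = .data$strip)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time [s]", y = "pressure [counts]", colour = "strip") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(
      data = events, ggplot2::aes(xintercept = .data$t_ms / 1000),
      linetype = "dotted", colour = "grey30"
    )
  }
  p
}

#' Plot a confusion matrix as a heat map
#'
#' @param m A confusion matrix, entry `[predicted, actual]`.
#' @return A ggplot object.
#' @export
plot_confusion <- function(m) {
  df <- as.data.frame(as.table(m))
  names(df) <- c("predicted", "actual", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "actual", y = "predicted", fill = "trials") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Autoplot methods for stream tibbles
#'
#' Dispatches [plot_imu_trace()] / [plot_pressure_trace()] for the
#' respective stream classes.
#'
#' @param object An `imu_stream` or `pressure_stream`.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.imu_stream <- function(object, ...) plot_imu_trace(object, ...)

#' @rdname autoplot.imu_stream
#' @export
autoplot.pressure_stream <- function(object, ...) plot_pressure_trace(object, ...)
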