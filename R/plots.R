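#' Plot a breathing signal
#'
#' @param object a `breathing_signal` tibble (`t`, `value`).
#' @param annotations optional annotation tibble; events are shaded.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot breathing_signal
#' @export
autoplot.breathing_signal <- function(object, annotations = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = "motion [depth units]",
                  title = "Breathing signal") +
    ggplot2::theme_minimal()
  if (!is.null(annotations) && nrow(annotations) > 0) {
    ann <- as_annotations(annotations)
    p <- p + ggplot2::geom_rect(
      data = ann, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$type),
      alpha = 0.2)
  }
  p
}

#' Plot an amplitude spectrum
#'
#' @param object a [amplitude_spectrum()] tibble.
#' @param band optional band (Hz) to highlight, e.g. the breathing band.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot resp_spectrum
#' @export
autoplot.resp_spectrum <- function(object, band = c(0.05, 1), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$magnitude)) +
    ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "blue") +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 2)) +
    ggplot2::labs(x = "frequency [Hz]", y = "amplitude",
                  title = "Breathing spectrum") +
    ggplot2::theme_minimal()
}

#' Plot window features coloured by label
#'
#' @param features a [extract_features()] tibble.
#' @param labels optional per-window labels (`"apnea"`/`"normal"`).
#' @return A ggplot of the (dominant frequency, standard deviation) plane.
#' @export
plot_features <- function(features, labels = NULL) {
  df <- tibble::as_tibble(features)
  if (!is.null(labels)) df$label <- labels
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$domfreq, y = .data$std)) +
    ggplot2::labs(x = "dominant frequency [Hz]", y = "window sd [depth units]",
                  title = "Window features") +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::geom_point(alpha = 0.3, size = 0.7)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$label),
                               alpha = 0.4, size = 0.7)
}

#' Plot a classified record
#'
#' Signal trace with predicted apnea samples highlighted and annotated
#' events shaded.
#'
#' @param labeled output of [classify_signal()] (columns `t`, `value`,
#'   `label`).
#' @param annotations optional annotation tibble.
#' @return A ggplot.
#' @export
plot_classification <- function(labeled, annotations = NULL) {
  p <- ggplot2::ggplot(labeled, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(data = dplyr::filter(labeled, .data$label == "apnea"),
                        colour = "red", size = 0.3) +
    ggplot2::labs(x = "time [s]", y = "motion [depth units]",
                  title = "Apnea classification (red = apnea-labelled samples)") +
    ggplot2::theme_minimal()
  if (!is.null(annotations) && nrow(annotations) > 0) {
    ann <- as_annotations(annotations)
    p <- p + ggplot2::geom_rect(
      data = ann, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.15, fill = "orange")
  }
  p
}
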