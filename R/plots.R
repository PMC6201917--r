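#' Plot a reading scanpath
#'
#' Draws detected fixations as dots sized by duration and saccades as
#' segments, forward in red and backward (regressions and return sweeps)
#' in yellow, on screen coordinates (y axis pointing down).
#'
#' @param events A `gaze_events` object from [detect_events()].
#' @param samples Optional raw sample tibble drawn as a faint trace.
#' @return A ggplot object.
#' @export
plot_scanpath <- function(events, samples = NULL) {
  stopifnot(inherits(events, "gaze_events"))
  fix <- events$fixations
  seg <- NULL
  if (nrow(fix) >= 2) {
    seg <- tibble::tibble(
      x = fix$cx[-nrow(fix)], y = fix$cy[-nrow(fix)],
      xend = fix$cx[-1], yend = fix$cy[-1],
      direction = events$saccades$direction
    )
  }
  p <- ggplot2::ggplot()
  if (!is.null(samples)) {
    p <- p + ggplot2::geom_path(
      data = samples[samples$valid, ],
      ggplot2::aes(x = .data$x_px, y = .data$y_px),
      colour = "grey80", linewidth = 0.2
    )
  }
  if (!is.null(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$direction),
      linewidth = 0.4
    )
  }
  p +
    ggplot2::geom_point(
      data = fix,
      ggplot2::aes(x = .data$cx, y = .data$cy, size = .data$duration),
      colour = "steelblue", alpha = 0.6
    ) +
    ggplot2::scale_colour_manual(values = c(forward = "firebrick",
                                            backward = "goldenrod")) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", size = "duration (ms)",
                  colour = "saccade") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.understanding_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$participant_id)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$abs_error), fill = "steelblue") +
    ggplot2::labs(
      x = "participant", y = "absolute error |U - U_E|",
      title = sprintf("Understanding estimation error (%s estimator, MAE = %.3f)",
                      object$estimator, object$mae)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.text_count_eval <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_texts, y = .data$mae,
                               colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of texts per participant",
                  y = "mean absolute error",
                  colour = "estimator") +
    ggplot2::theme_minimal()
}
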