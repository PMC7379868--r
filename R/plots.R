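#' Grand-average epoch traces
#'
#' Mean HbO/HbR time course per class, averaged over trials and the selected
#' channels, with the task interval shaded.
#'
#' @param object A `nirs_epochs` object.
#' @param channels Channels to average over (default all).
#' @param task_duration Task length in s for the shaded interval.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nirs_epochs <- function(object, channels = NULL, task_duration = 10,
                                 ...) {
  channels <- channels %||% object$channels
  avg <- object$data %>%
    filter(.data$channel %in% channels) %>%
    group_by(.data$label, .data$chromophore, .data$time) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(.data$time, .data$value,
                                    colour = .data$chromophore)) +
    ggplot2::annotate("rect", xmin = 0, xmax = task_duration,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~label) +
    ggplot2::scale_colour_manual(values = c(HbO = "#c03030",
                                            HbR = "#3050c0")) +
    ggplot2::labs(x = "time from task onset (s)",
                  y = expression(Delta * "[Hb] (mM" %.% "cm)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Accuracy along the learner-count curve
#'
#' Ensemble cross-validated accuracy as a function of the number of weak
#' learners, the strong learner's accuracy as a dotted reference line, and
#' dots marking counts where the FDR-adjusted comparison is significant.
#'
#' @param object A `learner_curve` tibble from
#'   [compare_over_learner_counts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.learner_curve <- function(object, ...) {
  strong <- attr(object, "strong_accuracy")
  sig <- filter(object, .data$significant)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$n, .data$accuracy)) +
    ggplot2::geom_hline(yintercept = strong, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8)
  if (nrow(sig)) {
    p <- p + ggplot2::geom_point(data = mutate(sig, y = max(object$accuracy) + 0.02),
                                 ggplot2::aes(.data$n, .data$y),
                                 colour = "red", size = 1)
  }
  p + ggplot2::labs(x = "number of weak learners",
                    y = "cross-validated accuracy",
                    subtitle = paste0("dotted: ", attr(object, "strong_kind"),
                                      " strong learner; red: FDR-significant difference")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.learner_curve
#' @export
plot_learner_curve <- function(object, ...) autoplot.learner_curve(object, ...)
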