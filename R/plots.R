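# ggplot2 displays for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-subject LOSO accuracies
#'
#' Bar chart of per-target-subject accuracy with the across-subject mean as a
#' dashed line and the chance level as a dotted line.
#'
#' @param object A `cvep_loso`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cvep_loso <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1 / object$n_targets, linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("%s: leave-one-subject-out accuracy", object$config$algorithm),
      subtitle = sprintf("mean %.3f (dashed), chance %.3f (dotted)",
                         object$mean_accuracy, 1 / object$n_targets),
      x = "target subject", y = "accuracy"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' Mean LOSO accuracy (with standard-error ribbon) against the swept parameter.
#'
#' @param object A `cvep_sweep` from [sweep_loso()].
#' @param y `"mean_accuracy"` or `"itr_bits_min"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cvep_sweep <- function(object, y = c("mean_accuracy", "itr_bits_min"), ...) {
  y <- match.arg(y)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$value, y = .data[[y]],
                                    colour = .data$algorithm, group = .data$algorithm))
  if (y == "mean_accuracy") {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$se,
                   ymax = .data$mean_accuracy + .data$se,
                   fill = .data$algorithm),
      alpha = 0.15, colour = NA)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = object$parameter[1],
                  y = if (y == "mean_accuracy") "mean LOSO accuracy" else "ITR (bits/min)") +
    ggplot2::theme_minimal()
}

#' Plot the per-source accuracies behind a TSS selection
#'
#' @param object A `cvep_tss`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cvep_tss <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$source, .data$rank),
                                   y = .data$accuracy, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "source subject (ranked)",
                  y = "accuracy on target training set",
                  fill = "selected") +
    ggplot2::theme_minimal()
}
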