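#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' Standard ROC trace (sensitivity against 1 - specificity) with the
#' Youden-optimal operating point highlighted.
#'
#' @param object A `roc_curve` from [roc_with_youden()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  opt <- object[object$cutoff == attr(object, "optimal_cutoff"), ]
  ggplot2::ggplot(object, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = opt, colour = "red", size = 2) +
    ggplot2::annotate("text", x = 1 - opt$specificity, y = opt$sensitivity,
                      label = sprintf("  Youden = %.2f", opt$youden),
                      hjust = 0, vjust = 1, size = 3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "ROC of posterior risk scores") +
    ggplot2::theme_minimal()
}

#' Plot posterior risk scores by group
#'
#' Jittered posterior probabilities of the high-risk class per sample,
#' grouped by risk class and coloured by subclass — homozygous carriers are
#' expected to sit above heterozygous ones.
#'
#' @param scores Tibble from `predict()` (`sample_id`, `posterior_high`).
#' @param metadata Sample metadata tibble.
#' @param cutoff Optional horizontal reference line (e.g. the Youden-optimal
#'   cutoff).
#' @return A ggplot object.
#' @export
plot_risk_scores <- function(scores, metadata, cutoff = NULL) {
  df <- dplyr::left_join(scores, metadata, by = "sample_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$risk_class,
                                        y = .data$posterior_high,
                                        colour = .data$subclass)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Risk class", y = "Posterior probability (high risk)",
                  colour = "Subclass") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}
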