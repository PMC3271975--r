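#' Two-sample t-test on predicted risk scores
#'
#' First-line check of a predictor on a test set: does the posterior score
#' separate the high-risk group from controls? Pooled-variance Student test,
#' as in the per-probe discovery stage.
#'
#' @param scores Tibble from `predict()` (`sample_id`, `posterior_high`).
#' @param metadata Sample metadata tibble.
#' @return A one-row tibble `statistic`, `p_value`, `df`, `mean_high`,
#'   `mean_low`.
#' @export
score_group_ttest <- function(scores, metadata) {
  rc <- metadata$risk_class[match(scores$sample_id, metadata$sample_id)]
  if (anyNA(rc)) stop("metadata missing scored sample(s)", call. = FALSE)
  if (length(unique(rc)) < 2) stop("both risk classes must be present", call. = FALSE)
  hi <- scores$posterior_high[rc == "high"]
  lo <- scores$posterior_high[rc == "low"]
  tt <- two_sample_t(hi, lo)
  tt$mean_high <- mean(hi)
  tt$mean_low <- mean(lo)
  tt
}

score_labels <- function(scores, metadata) {
  rc <- metadata$risk_class[match(scores$sample_id, metadata$sample_id)]
  if (anyNA(rc)) stop("metadata missing scored sample(s)", call. = FALSE)
  rc
}

#' ROC curve with Youden-optimal cutoff
#'
#' Scans every achievable operating point: candidate cutoffs are the unique
#' observed scores plus a +Inf sentinel (predict-nobody), classifying a
#' sample high-risk when `score >= cutoff`. The optimal cutoff maximizes the
#' Youden index (sensitivity + specificity - 1); ties are broken toward the
#' cutoff with higher specificity (fewer false positives).
#'
#' @inheritParams score_group_ttest
#' @return A `roc_curve`: tibble `cutoff`, `sensitivity`, `specificity`,
#'   `youden`, with attributes `optimal_cutoff` and `optimal_youden`.
#' @export
roc_with_youden <- function(scores, metadata) {
  rc <- score_labels(scores, metadata)
  if (length(unique(rc)) < 2) stop("both risk classes must be present", call. = FALSE)
  s <- scores$posterior_high
  if (any(!is.finite(s))) stop("scores must be finite", call. = FALSE)
  if (length(unique(s)) == 1) {
    warning("all scores identical; degenerate ROC with Youden 0", call. = FALSE)
  }
  cutoffs <- c(sort(unique(s)), Inf)
  pos <- rc == "high"
  sens <- vapply(cutoffs, function(ct) mean(s[pos] >= ct), numeric(1))
  spec <- vapply(cutoffs, function(ct) mean(s[!pos] < ct), numeric(1))
  youden <- sens + spec - 1
  # max Youden; among ties prefer higher specificity
  best <- which(youden == max(youden))
  best <- best[which.max(spec[best])]
  out <- tibble::tibble(cutoff = cutoffs, sensitivity = sens,
                        specificity = spec, youden = youden)
  class(out) <- c("roc_curve", class(out))
  attr(out, "optimal_cutoff") <- cutoffs[best]
  attr(out, "optimal_youden") <- youden[best]
  out
}

#' Confusion metrics at a fixed score cutoff
#'
#' Counts by the `score >= cutoff -> high` rule and the standard rates:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), Youden = sensitivity + specificity - 1. A rate with a
#' zero denominator is reported as `NA` with a warning.
#'
#' @inheritParams score_group_ttest
#' @param cutoff Classification threshold.
#' @return A one-row tibble `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `youden`.
#' @export
confusion_at_cutoff <- function(scores, metadata, cutoff) {
  rc <- score_labels(scores, metadata)
  if (length(unique(rc)) < 2) stop("both risk classes must be present", call. = FALSE)
  pred_high <- scores$posterior_high >= cutoff
  pos <- rc == "high"
  confusion_from_counts(tp = sum(pred_high & pos), fp = sum(pred_high & !pos),
                        tn = sum(!pred_high & !pos), fn = sum(!pred_high & pos))
}

confusion_from_counts <- function(tp, fp, tn, fn) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  tibble::tibble(
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    sensitivity = sens, specificity = spec,
    ppv = safe_div(tp, tp + fp, "PPV"),
    npv = safe_div(tn, tn + fn, "NPV"),
    youden = sens + spec - 1
  )
}

#' Reconstruct confusion metrics from published rates
#'
#' Published evaluations often report only sensitivity, specificity and the
#' group sizes; the underlying integer confusion table follows by rounding
#' `sensitivity * n_pos` and `specificity * n_neg`, and PPV/NPV/Youden then
#' follow from the counts. Useful to audit a reported table for internal
#' consistency.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @param n_pos,n_neg Group sizes (positives = high risk).
#' @return A one-row tibble as [confusion_at_cutoff()].
#' @export
#' @examples
#' metrics_from_rates(0.700, 0.846, 10, 13)  # PPV 0.778, NPV 0.786, Youden 0.546
metrics_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0, specificity <= 1,
            n_pos >= 1, n_neg >= 1)
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  fn <- n_pos - tp
  fp <- n_neg - tn
  if (min(tp, tn, fn, fp) < 0) stop("rates inconsistent with group sizes", call. = FALSE)
  confusion_from_counts(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' WPGMA (McQuitty) hierarchical clustering of an expression set
#'
#' Agglomerative clustering with McQuitty/WPGMA linkage — the distance from
#' a merged cluster to any other is the plain average of its two members'
#' distances, which is robust to very uneven cluster sizes — on Euclidean
#' distances between standardized probe rows or sample columns.
#'
#' @param std_matrix A (typically standardized) [expr_matrix].
#' @param axis Cluster `"probes"` (rows) or `"samples"` (columns).
#' @return An [stats::hclust] object.
#' @export
wpgma_cluster <- function(std_matrix, axis = c("probes", "samples")) {
  stopifnot(is_expr_matrix(std_matrix))
  axis <- match.arg(axis)
  m <- unclass(std_matrix)
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 2) stop("need at least 2 items to cluster", call. = FALSE)
  stats::hclust(stats::dist(m, method = "euclidean"), method = "mcquitty")
}
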