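#' Pooled-variance two-sample t-test
#'
#' The classical Student test with pooled variance and
#' \eqn{n_a + n_b - 2} degrees of freedom — the historical default for
#' two-group microarray comparisons. Welch's unequal-variance variant is
#' available as a toggle.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return A one-row tibble with columns `statistic`, `p_value`, `df`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(11, 12, 13))
two_sample_t <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(group_a) + stats::var(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    # degenerate equal-constant case: no evidence of difference
    return(tibble::tibble(statistic = 0, p_value = 1,
                          df = length(group_a) + length(group_b) - 2))
  }
  if (var_equal && pooled_var(group_a, group_b) == 0) {
    stop("zero pooled variance", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 df = unname(ht$parameter))
}

pooled_var <- function(a, b) {
  na <- length(a); nb <- length(b)
  ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
}

# vectorised pooled t over matrix rows; returns list(t, p, df, zero_var)
row_t_test <- function(mat, is_high) {
  a <- mat[, is_high, drop = FALSE]
  b <- mat[, !is_high, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  df <- na + nb - 2
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, p = p, df = df, mean_high = ma, mean_low = mb, zero_var = sp2 == 0)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjusted p-values with the null proportion
#' fixed at 1 (the conservative, deterministic choice): the q-value of the
#' rank-i p-value is \eqn{\min_{j \ge i} p_{(j)} m / j}, mapped back to input
#' order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values aligned with the input.
#' @export
fdr_qvalues <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Signed linear-scale fold change
#'
#' Converts a log2 mean difference (high-risk minus low-risk) to the signed
#' linear fold-change convention used in differential-expression tables:
#' ratio \eqn{r = 2^{d}} reported as \eqn{r} when up-regulated and
#' \eqn{-1/r} when down-regulated, so \eqn{|FC| \ge 1} and the sign encodes
#' direction.
#'
#' @param mean_high,mean_low Log2-scale group means (vectorised).
#' @return Signed fold change(s).
#' @export
#' @examples
#' signed_fold_change(8.556, 8.0)   #  1.47
#' signed_fold_change(7.415, 8.0)   # -1.50
signed_fold_change <- function(mean_high, mean_low) {
  r <- 2^(mean_high - mean_low)
  ifelse(r >= 1, r, -1 / r)
}

#' Discover differentially expressed biomarkers
#'
#' Stage 1 of the pipeline: per-probe pooled t-tests of high-risk versus
#' low-risk samples, BH q-values, and signed fold changes. All probes are
#' returned, ordered by ascending p-value, with a `flagged` column marking
#' the q-value threshold (inclusive, `q <= q_threshold`). Probes with zero
#' pooled variance are skipped with a warning.
#'
#' @param x An [expr_matrix].
#' @param metadata Sample metadata tibble covering all samples of `x`.
#' @param q_threshold Inclusive q-value cutoff (default 0.01).
#' @param var_equal Pool variances (default `TRUE`).
#' @return A tibble with columns `probe_id`, `t_stat`, `p_value`, `q_value`,
#'   `fold_change`, `flagged`, sorted by `p_value`.
#' @export
discover_biomarkers <- function(x, metadata, q_threshold = 0.01, var_equal = TRUE) {
  stopifnot(is_expr_matrix(x))
  metadata <- validate_metadata(as.data.frame(metadata))
  missing_meta <- setdiff(sample_ids(x), metadata$sample_id)
  if (length(missing_meta)) {
    stop("metadata missing sample(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  rc <- metadata$risk_class[match(sample_ids(x), metadata$sample_id)]
  if (length(unique(rc)) < 2) stop("both risk classes must be present", call. = FALSE)
  is_high <- rc == "high"

  if (var_equal) {
    tt <- row_t_test(unclass(x), is_high)
  } else {
    res <- apply(unclass(x), 1, function(v) {
      ht <- stats::t.test(v[is_high], v[!is_high], var.equal = FALSE)
      c(unname(ht$statistic), ht$p.value)
    })
    tt <- list(t = res[1, ], p = res[2, ],
               mean_high = rowMeans(x[, is_high, drop = FALSE]),
               mean_low = rowMeans(x[, !is_high, drop = FALSE]),
               zero_var = apply(unclass(x), 1, function(v) stats::var(v) == 0))
  }
  keep <- !tt$zero_var & is.finite(tt$t)
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance probe(s) skipped", call. = FALSE)
  }
  q <- rep(NA_real_, nrow(x))
  q[keep] <- fdr_qvalues(tt$p[keep])
  out <- tibble::tibble(
    probe_id = probe_ids(x),
    t_stat = tt$t,
    p_value = tt$p,
    q_value = q,
    fold_change = signed_fold_change(tt$mean_high, tt$mean_low)
  )[keep, ]
  out <- dplyr::arrange(out, .data$p_value)
  out$flagged <- out$q_value <= q_threshold
  out
}
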