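#' Spearman co-expression matrix of a biomarker panel
#'
#' Entry (i, j) is the Spearman rank correlation of probes i and j across
#' all samples of the dataset — one row of this matrix is the probe's
#' co-expression "fingerprint" within the panel. Constant probes cannot be
#' ranked; their correlations are set to 0 with a warning.
#'
#' @param x An [expr_matrix].
#' @param panel A [biomarker_panel()] (or character vector of probe IDs); all
#'   probes must be present in `x`.
#' @return A symmetric |panel| x |panel| matrix with unit diagonal,
#'   dimnames = panel probes.
#' @export
coexpression_matrix <- function(x, panel) {
  stopifnot(is_expr_matrix(x))
  probes <- if (inherits(panel, "biomarker_panel")) panel$probe_ids else as.character(panel)
  missing_p <- setdiff(probes, probe_ids(x))
  if (length(missing_p)) {
    stop("panel probe(s) absent from matrix: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  if (ncol(x) < 3) stop("need at least 3 samples for co-expression", call. = FALSE)
  sub <- unclass(x)[probes, , drop = FALSE]
  const <- apply(sub, 1, function(v) stats::var(v) == 0)
  cc <- suppressWarnings(stats::cor(t(sub), method = "spearman"))
  if (any(const)) {
    warning(sum(const), " constant probe(s); their correlations set to 0",
            call. = FALSE)
    cc[const, ] <- 0
    cc[, const] <- 0
  }
  diag(cc) <- 1
  cc
}

#' COXEN concordance of co-expression patterns between two datasets
#'
#' The co-expression extrapolation (COXEN) statistic: for each probe i, the
#' Pearson correlation between its co-expression fingerprint in dataset A
#' and in dataset B (row i of each Spearman matrix with the self-correlation
#' removed, vectors of length g - 1). A probe whose within-panel
#' co-expression pattern is preserved across cell types scores near 1.
#' Significance uses the t transform on n = g - 1 paired values, df = g - 3,
#' with an upper-tail (one-sided) p: only positive association counts as
#' concordance — an anti-correlated fingerprint is a reversed pattern, not a
#' preserved one. Selection is strict: `concordance_p < alpha`.
#'
#' @param cor_a,cor_b Co-expression matrices from [coexpression_matrix()]
#'   with identical probe ordering, dimension g >= 4.
#' @param alpha Per-probe significance threshold (default 0.001).
#' @return A tibble: `probe_id`, `concordance_r`, `concordance_p`,
#'   `selected`, with `alpha` stored as an attribute.
#' @export
concordance_scores <- function(cor_a, cor_b, alpha = 0.001) {
  if (!identical(dim(cor_a), dim(cor_b))) stop("dimension mismatch", call. = FALSE)
  g <- nrow(cor_a)
  if (g < 4) stop("need at least 4 probes (p-value undefined below)", call. = FALSE)
  if (!is.null(rownames(cor_a)) && !is.null(rownames(cor_b)) &&
      !identical(rownames(cor_a), rownames(cor_b))) {
    stop("probe ordering differs between the two matrices", call. = FALSE)
  }
  ids <- rownames(cor_a) %||% paste0("probe", seq_len(g))
  r <- vapply(seq_len(g), function(i) {
    va <- cor_a[i, -i]
    vb <- cor_b[i, -i]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(0)
    stats::cor(va, vb)
  }, numeric(1))
  df <- g - 3                        # (g - 1) paired values, minus 2
  r_c <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r_c * sqrt(df / (1 - r_c^2))
  p <- stats::pt(tval, df, lower.tail = FALSE)
  p[r >= 1] <- 0
  out <- tibble::tibble(probe_id = ids, concordance_r = r,
                        concordance_p = p, selected = p < alpha)
  attr(out, "alpha") <- alpha
  out
}

#' Select the COXEN sub-panel for one test cell type
#'
#' Restricts a biomarker panel to the probes whose co-expression pattern is
#' concordant between the training and test datasets at the given per-probe
#' threshold. Probes are first intersected across the two matrices; the
#' panel's original ordering is preserved.
#'
#' @param train,test [expr_matrix] objects.
#' @param panel The [biomarker_panel()] to filter.
#' @param alpha Strict p-value threshold (default 0.001).
#' @return A [biomarker_panel()] with `source = "coxen"`. An empty selection
#'   is an error suggesting a larger alpha.
#' @export
select_coxen_panel <- function(train, test, panel, alpha = 0.001) {
  stopifnot(inherits(panel, "biomarker_panel"))
  common <- intersect_probes(train, test)
  probes <- panel$probe_ids[panel$probe_ids %in% probe_ids(common$a)]
  if (length(probes) < 4) {
    stop("fewer than 4 panel probes shared between train and test", call. = FALSE)
  }
  ca <- coexpression_matrix(common$a, probes)
  cb <- coexpression_matrix(common$b, probes)
  sc <- concordance_scores(ca, cb, alpha = alpha)
  sel <- sc$probe_id[sc$selected]
  if (!length(sel)) {
    stop("COXEN selected no probes at alpha = ", alpha,
         "; consider a larger alpha", call. = FALSE)
  }
  biomarker_panel(probes[probes %in% sel], source = "coxen",
                  training_dataset_id = panel$training_dataset_id,
                  description = sprintf("COXEN %s -> %s, alpha = %g (%d of %d kept)",
                                        attr(train, "dataset_id"),
                                        attr(test, "dataset_id"),
                                        alpha, length(sel), length(probes)))
}
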