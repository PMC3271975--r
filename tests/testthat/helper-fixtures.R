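# shared fixtures: everything is generated in code, no stored data

# small expression matrix with explicit values
tiny_expr <- function(values, probes = NULL, samples = NULL,
                      id = "TOY", ct = "monocyte") {
  if (!is.matrix(values)) values <- matrix(values, nrow = length(probes))
  rownames(values) <- probes %||% rownames(values) %||%
    sprintf("p%02d", seq_len(nrow(values)))
  colnames(values) <- samples %||% colnames(values) %||%
    sprintf("S%02d", seq_len(ncol(values)))
  expr_matrix(values, id, ct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# metadata for n_high high-risk + n_low control samples named S01..
meta_for <- function(sample_ids, n_high, subclass_high = "heterozygous_FH") {
  n <- length(sample_ids)
  tibble::tibble(
    sample_id = sample_ids,
    risk_class = rep(c("high", "low"), c(n_high, n - n_high)),
    subclass = rep(c(subclass_high, "control"), c(n_high, n - n_high))
  )
}

# a small two-cell-type cohort config for fast end-to-end tests
small_config <- function(seed, n_probes = 400, n_de = 40, ...) {
  fh <- data.frame(subclass = c("homozygous_FH", "heterozygous_FH", "control"),
                   n = c(3L, 7L, 13L))
  cohort_config(
    n_probes = n_probes, n_de = n_de,
    cohort_design = list(
      monocyte = list(dataset_id = "FH1", design = fh),
      t_cell = list(dataset_id = "FH2", design = fh, same_subjects_as = "monocyte")
    ),
    seed = seed, ...
  )
}

# design with only the training cell type (for null-calibration loops)
mono_only_config <- function(seed, n_probes = 2000, n_de = 0, ...) {
  fh <- data.frame(subclass = c("homozygous_FH", "heterozygous_FH", "control"),
                   n = c(3L, 7L, 13L))
  cohort_config(n_probes = n_probes, n_de = n_de,
                cohort_design = list(monocyte = list(dataset_id = "FH1", design = fh)),
                seed = seed, ...)
}

# independent brute-force BH step-up q-values (test oracle)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(p[ord][i:m] * m / (i:m))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# brute-force Spearman: rank within probe, then Pearson (test oracle)
spearman_oracle <- function(mat) {
  rk <- t(apply(mat, 1, rank))
  g <- nrow(mat)
  out <- diag(1, g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i != j) out[i, j] <- stats::cor(rk[i, ], rk[j, ])
  }
  dimnames(out) <- list(rownames(mat), rownames(mat))
  out
}

# brute-force WPGMA recursion on a distance matrix (test oracle):
# returns sorted merge heights
wpgma_oracle_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- active[ij[1]]; b <- active[ij[2]]
    heights <- c(heights, d[a, b])
    # McQuitty update: distance to merged cluster = mean of members' distances
    newd <- (d[a, ] + d[b, ]) / 2
    d[a, ] <- newd; d[, a] <- newd; d[a, a] <- 0
    active <- setdiff(active, b)
  }
  sort(heights)
}

# closed-form two-class Gaussian Bayes posterior with shared covariance
bayes_posterior_oracle <- function(x, mu_low, mu_high, sigma, prior_high = 0.5) {
  logdens <- function(mu) {
    d <- length(mu)
    si <- solve(sigma)
    -0.5 * (log(det(sigma)) + d * log(2 * pi)) -
      0.5 * drop(t(x - mu) %*% si %*% (x - mu))
  }
  lh <- logdens(mu_high) + log(prior_high)
  ll <- logdens(mu_low) + log(1 - prior_high)
  1 / (1 + exp(ll - lh))
}
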