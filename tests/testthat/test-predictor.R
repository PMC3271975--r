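test_that("within-gene standardization yields mean 0 / sd 1 rows, idempotently", {
  set.seed(14)
  x <- tiny_expr(matrix(rnorm(50, 8, 3), 10, 5))
  std <- standardize_within_genes(x)
  expect_equal(rowMeans(std), rep(0, 10), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(apply(unclass(std), 1, sd), rep(1, 10), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unclass(standardize_within_genes(std)), unclass(std),
               tolerance = 1e-12)

  v <- unclass(x); v[3, ] <- 7
  expect_warning(stdc <- standardize_within_genes(tiny_expr(v)), "constant")
  expect_true(all(unclass(stdc)[3, ] == 0))

  expect_error(standardize_within_genes(tiny_expr(matrix(1:3, 3, 1))),
               "at least 2 samples")
})

test_that("PCA keeps 3 components with orthonormal, sign-fixed loadings", {
  set.seed(15)
  x <- standardize_within_genes(tiny_expr(matrix(rnorm(20 * 12), 20, 12)))
  # pure-noise data: the top-3 coverage warning is expected here
  expect_warning(pca <- fit_pca(x), "70%")
  expect_identical(pca$n_components, 3L)
  expect_identical(dim(pca$loadings), c(20L, 3L))
  expect_equal(crossprod(pca$loadings), diag(3), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_true(all(diff(pca$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(pca$explained_variance_fraction), 1 + 1e-12)
  # sign convention: largest-magnitude loading positive per component
  for (j in 1:3) {
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
  # determinism: repeated fits bit-identical
  expect_identical(suppressWarnings(fit_pca(x))$loadings, pca$loadings)

  expect_error(fit_pca(x, panel = c("p01", "p02")), "at least 3 probes")
})

test_that("PCA recovers a planted one-factor structure", {
  set.seed(16)
  f <- rnorm(30)
  load <- rnorm(15, sd = 1)
  vals <- outer(load, f) + matrix(rnorm(15 * 30, sd = 0.05), 15, 30)
  x <- standardize_within_genes(tiny_expr(vals))
  pca <- fit_pca(x)
  expect_gt(pca$explained_variance_fraction[1], 0.9)
  expect_lt(pca$explained_variance_fraction[2], 0.05)
})

test_that("LDA posteriors follow the Gaussian Bayes rule", {
  # 1-D closed form: class means +/-1, pooled unit variance, x = 0.5
  a <- 1 / sqrt(2)
  pc <- matrix(c(-1 - a, -1 + a, 1 - a, 1 + a), ncol = 1)
  rownames(pc) <- paste0("S", 1:4)
  fit <- fit_lda(pc, c("low", "low", "high", "high"))
  expect_equal(unname(fit$class_means$low), -1, tolerance = 1e-12)
  expect_equal(unname(fit$pooled_covariance[1, 1]), 1, tolerance = 1e-12)
  post <- predict(fit, matrix(0.5, 1, 1))
  expect_equal(post$posterior_high, 1 / (1 + exp(-1)), tolerance = 1e-12)

  # identical class means: posterior 0.5 everywhere
  set.seed(17)
  sym <- matrix(rnorm(20), 10, 2)
  sym <- rbind(sym, sym)  # same points in both classes -> equal means/cov
  labs <- rep(c("low", "high"), each = 10)
  fs <- fit_lda(sym, labs)
  ps <- predict(fs, matrix(rnorm(10), 5, 2))
  expect_equal(ps$posterior_high, rep(0.5, 5), tolerance = 1e-10)

  # well-separated clouds score >= 0.99 for their own class
  cloud <- rbind(matrix(rnorm(40, -4, 0.5), 20, 2),
                 matrix(rnorm(40, 4, 0.5), 20, 2))
  labc <- rep(c("low", "high"), each = 20)
  fc <- fit_lda(cloud, labc)
  pc2 <- predict(fc, cloud)$posterior_high
  expect_true(all(pc2[1:20] <= 0.01) && all(pc2[21:40] >= 0.99))

  expect_error(fit_lda(cloud, rep("high", 40)), "both classes")
})

test_that("LDA posteriors agree with an independent reference implementation", {
  set.seed(18)
  pc <- rbind(matrix(rnorm(60, -1, 1), 20, 3), matrix(rnorm(60, 1, 1), 20, 3))
  rownames(pc) <- paste0("S", 1:40)
  labs <- rep(c("low", "high"), each = 20)
  fit <- fit_lda(pc, labs)
  ref <- MASS::lda(pc, grouping = labs, prior = c(high = 0.5, low = 0.5))
  ref_post <- predict(ref, pc)$posterior[, "high"]
  expect_equal(predict(fit, pc)$posterior_high, unname(ref_post),
               tolerance = 1e-8)
})

test_that("singular pooled covariance is ridge-regularized with a warning", {
  pc <- cbind(c(0, 1, 2, 3), c(0, 2, 4, 6))  # perfectly collinear columns
  rownames(pc) <- paste0("S", 1:4)
  expect_warning(fit <- fit_lda(pc, c("low", "low", "high", "high")), "ridge")
  expect_silent(predict(fit, pc))
})

test_that("the trained predictor is self-consistent and affine-invariant", {
  coh <- simulate_cohort(small_config(seed = 19))
  de <- discover_biomarkers(coh$expression$monocyte, coh$metadata)
  panel <- filter_by_function(de, coh$annotations, training_dataset_id = "FH1")
  fit <- train_risk_predictor(coh$expression$monocyte, coh$metadata, panel)

  # predicting the training set reproduces the stored training posteriors
  back <- predict(fit, coh$expression$monocyte)
  expect_equal(back, fit$training_scores, tolerance = 1e-12)

  # gene-wise affine rescaling of the test set is absorbed by standardization
  test <- coh$expression$t_cell
  set.seed(1)
  gains <- runif(nrow(test), 0.5, 2)
  offsets <- rnorm(nrow(test), 0, 5)
  rescaled <- expr_matrix(unclass(test) * gains + offsets, "FH2", "t_cell")
  expect_equal(predict(fit, rescaled), predict(fit, test), tolerance = 1e-9)

  sub <- test[setdiff(rownames(test), panel$probe_ids[1]), ]
  expect_error(predict(fit, sub), panel$probe_ids[1])
})

test_that("tidy/glance summarise the fit and JSON serialization round-trips", {
  coh <- simulate_cohort(small_config(seed = 23))
  de <- discover_biomarkers(coh$expression$monocyte, coh$metadata)
  panel <- filter_by_function(de, coh$annotations, training_dataset_id = "FH1")
  fit <- train_risk_predictor(coh$expression$monocyte, coh$metadata, panel)

  td <- tidy(fit)
  expect_identical(nrow(td), length(panel) * 3L)
  expect_named(td, c("probe_id", "component", "loading"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_probes, length(panel))
  expect_equal(gl$cum_var_top3, sum(fit$pca$explained_variance_fraction))

  path <- withr::local_tempfile(fileext = ".json")
  write_predictor(fit, path)
  fit2 <- read_predictor(path)
  expect_equal(predict(fit2, coh$expression$t_cell),
               predict(fit, coh$expression$t_cell), tolerance = 1e-12)
  expect_identical(fit2$panel$probe_ids, fit$panel$probe_ids)
})
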