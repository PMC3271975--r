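scores_of <- function(s, ids = sprintf("S%02d", seq_along(s))) {
  tibble::tibble(sample_id = ids, posterior_high = s)
}

test_that("score t-test matches the discovery-stage pooled test", {
  set.seed(24)
  sc <- scores_of(runif(12))
  meta <- meta_for(sc$sample_id, n_high = 5)
  got <- score_group_ttest(sc, meta)
  ref <- two_sample_t(sc$posterior_high[1:5], sc$posterior_high[6:12])
  expect_equal(got$statistic, ref$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, ref$p_value, tolerance = 1e-12)

  same <- scores_of(rep(c(0.4, 0.6), 4))
  meta2 <- meta_for(same$sample_id, n_high = 4)
  # identical score multisets in both groups -> p = 1
  expect_equal(score_group_ttest(same, meta2)$p_value, 1)

  lone <- meta2; lone$risk_class <- "low"; lone$subclass <- "control"
  expect_error(score_group_ttest(same, lone), "both risk classes")
})

test_that("ROC/Youden picks the documented optimal operating points", {
  # perfect separation
  sc <- scores_of(c(0.9, 0.8, 0.2, 0.1))
  meta <- meta_for(sc$sample_id, n_high = 2)
  roc <- roc_with_youden(sc, meta)
  expect_equal(attr(roc, "optimal_youden"), 1)
  expect_true(all(roc$youden == roc$sensitivity + roc$specificity - 1))

  # worked example: cutoff lands between 0.4 (exclusive) and 0.8 (inclusive)
  sc2 <- scores_of(c(0.9, 0.8, 0.4, 0.3))
  roc2 <- roc_with_youden(sc2, meta_for(sc2$sample_id, 2))
  opt <- attr(roc2, "optimal_cutoff")
  expect_gt(opt, 0.4)
  expect_lte(opt, 0.8)
  cm <- confusion_at_cutoff(sc2, meta_for(sc2$sample_id, 2), opt)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)

  # one mislabeled sample among 10: best achievable Youden is 0.8
  sc3 <- scores_of(c(0.95, 0.9, 0.85, 0.8, 0.45, 0.5, 0.3, 0.2, 0.15, 0.1))
  roc3 <- roc_with_youden(sc3, meta_for(sc3$sample_id, 5))
  expect_equal(attr(roc3, "optimal_youden"), 0.8, tolerance = 1e-12)

  # degenerate: identical scores
  flat <- scores_of(rep(0.5, 6))
  expect_warning(rocf <- roc_with_youden(flat, meta_for(flat$sample_id, 3)),
                 "identical")
  expect_equal(attr(rocf, "optimal_youden"), 0)
})

test_that("Youden ties break toward the higher-specificity cutoff", {
  # cutoffs 0.6 and 0.8 both give Youden 0.5: (sens 1, spec 0.5) vs (0.5, 1)
  sc <- scores_of(c(0.9, 0.7, 0.7, 0.5))
  meta <- meta_for(sc$sample_id, 2)
  roc <- roc_with_youden(sc, meta)
  opt <- attr(roc, "optimal_cutoff")
  cm <- confusion_at_cutoff(sc, meta, opt)
  expect_equal(cm$youden, 0.5)
  expect_equal(cm$specificity, 1)
})

test_that("confusion metrics reproduce their defining formulas", {
  # construct scores realising tp=7 fp=2 tn=11 fn=3 at cutoff 0.5
  s_high <- c(rep(0.8, 7), rep(0.2, 3))
  s_low <- c(rep(0.7, 2), rep(0.1, 11))
  sc <- scores_of(c(s_high, s_low))
  meta <- meta_for(sc$sample_id, n_high = 10)
  cm <- confusion_at_cutoff(sc, meta, 0.5)
  expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn), c(7L, 2L, 11L, 3L))
  expect_equal(cm$sensitivity, 0.700)
  expect_equal(cm$specificity, 11 / 13)
  expect_equal(cm$ppv, 7 / 9)
  expect_equal(cm$npv, 11 / 14)
  expect_equal(cm$youden, 0.7 + 11 / 13 - 1)

  all_right <- confusion_at_cutoff(scores_of(c(0.9, 0.1)),
                                   meta_for(c("S01", "S02"), 1), 0.5)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$npv, 1)

  expect_warning(none <- confusion_at_cutoff(scores_of(c(0.2, 0.1)),
                                             meta_for(c("S01", "S02"), 1), 0.5),
                 "PPV")
  expect_true(is.na(none$ppv))
})

test_that("metrics_from_rates inverts confusion rates on exact fractions", {
  m <- metrics_from_rates(1, 1, 5, 5)
  expect_equal(c(m$sensitivity, m$specificity, m$ppv, m$npv, m$youden),
               c(1, 1, 1, 1, 1))
  m2 <- metrics_from_rates(0.80, 1.00, 5, 5)
  expect_equal(m2$ppv, 1)
  expect_equal(m2$npv, 5 / 6, tolerance = 1e-12)

  # round trip: rates of a confusion table regenerate its counts
  set.seed(25)
  for (i in 1:10) {
    tp <- sample(1:9, 1); fn <- sample(1:9, 1)
    tn <- sample(1:9, 1); fp <- sample(1:9, 1)
    cm <- metrics_from_rates(tp / (tp + fn), tn / (tn + fp), tp + fn, tn + fp)
    expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn),
                     c(as.integer(tp), as.integer(fp), as.integer(tn), as.integer(fn)))
  }
})

test_that("WPGMA clustering matches the hand recursion and brute-force oracle", {
  # two identical profiles merge first at height 0
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  colnames(m) <- paste0("S", 1:3)
  hc <- wpgma_cluster(tiny_expr(m), axis = "probes")
  expect_equal(hc$height[1], 0)

  # three points on a line at 0, 1, 10: pair merges at 1, then (10+9)/2 = 9.5
  line <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("x", "y", "z"), "S1"))
  hl <- wpgma_cluster(tiny_expr(line), axis = "probes")
  expect_equal(hl$height, c(1, 9.5))

  # random 6-item instances against the brute-force WPGMA recursion
  set.seed(26)
  for (i in 1:5) {
    r <- matrix(rnorm(6 * 4), 6, 4,
                dimnames = list(paste0("g", 1:6), paste0("S", 1:4)))
    hr <- wpgma_cluster(tiny_expr(r), axis = "probes")
    expect_equal(sort(hr$height), wpgma_oracle_heights(dist(r)), tolerance = 1e-10)
  }

  # sample axis works and respects the minimum size
  hs <- wpgma_cluster(tiny_expr(m), axis = "samples")
  expect_identical(hs$labels, colnames(m))
  expect_error(wpgma_cluster(tiny_expr(matrix(1:2, 1, 2)), axis = "probes"),
               "at least 2")
})
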