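test_that("MAE and MSE match hand-computed values", {
  expect_equal(regression_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(mae = 0, mse = 0))
  m <- regression_metrics(c(0, 0, 0), c(1, -1, 2))
  expect_equal(m$mae, 4 / 3)
  expect_equal(m$mse, 2)
  expect_error(regression_metrics(1:3, 1:4), "length mismatch")
  expect_error(regression_metrics(numeric(0), numeric(0)), "insufficient")
})

test_that("mae never exceeds the root of mse", {
  set.seed(3)
  for (i in 1:20) {
    icp <- rnorm(50, 12, 4)
    eicp <- icp + rnorm(50, 0, 3)
    m <- regression_metrics(icp, eicp)
    expect_lte(m$mae, sqrt(m$mse) + 1e-12)
  }
})

test_that("Bland-Altman bias, SD and limits follow their definitions", {
  icp <- c(10, 12, 14, 9)
  ba <- bland_altman(icp, icp + 3)
  expect_equal(ba$bias, 3)
  expect_equal(ba$sd, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(3, 3))

  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(40, 12, 5)
    b <- a + rnorm(40, -0.2, 3)
    ba <- bland_altman(a, b)
    d <- b - a
    # brute-force recomputation
    expect_equal(ba$bias, sum(d) / length(d), tolerance = 1e-12)
    expect_equal(ba$sd, sqrt(sum((d - mean(d))^2) / (length(d) - 1)),
                 tolerance = 1e-12)
    expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd,
                 tolerance = 1e-12)
    # linearity: bias equals difference of the means exactly
    expect_equal(ba$bias, mean(b) - mean(a), tolerance = 1e-12)
  }
  expect_error(bland_altman(1, 2), "insufficient")
})

test_that("Spearman correlation respects monotone invariance and ties", {
  icp <- c(5, 9, 11, 14, 20)
  expect_equal(spearman_correlation(icp, exp(icp / 5))$rho, 1)
  expect_equal(spearman_correlation(icp, -icp)$rho, -1)

  # tied vectors against an exhaustive mid-rank oracle
  a <- c(1, 2, 2, 3, 5, 5, 5, 8)
  b <- c(2, 1, 4, 4, 6, 7, 6, 9)
  mid_rank <- function(x) {
    vapply(x, function(v) {
      less <- sum(x < v)
      eq <- sum(x == v)
      less + (eq + 1) / 2
    }, numeric(1))
  }
  ra <- mid_rank(a)
  rb <- mid_rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(spearman_correlation(a, b)$rho, oracle, tolerance = 1e-12)

  expect_error(spearman_correlation(rep(3, 5), 1:5), "degenerate")
  expect_error(spearman_correlation(1:2, 2:3), "insufficient")
})

test_that("error histogram bins absolute differences", {
  icp <- rep(0, 4)
  eicp <- c(1, 3, 5, 7)
  h <- error_histogram(icp, eicp)
  expect_equal(as.numeric(h), rep(0.25, 4))
  expect_equal(sum(h), 1, tolerance = 1e-9)

  h0 <- error_histogram(c(4, 8), c(4, 8))
  expect_equal(as.numeric(h0), c(1, 0, 0, 0))

  # permutation invariance
  set.seed(5)
  a <- rnorm(30, 12, 4)
  b <- a + rnorm(30, 0, 3)
  p <- sample(30)
  expect_equal(error_histogram(a, b), error_histogram(a[p], b[p]))
})

test_that("predictive values at 20 mmHg count the confusion table", {
  # perfect prediction with both classes present
  icp <- c(10, 15, 25, 30)
  t1 <- threshold_predictive_values(icp, icp)
  expect_equal(t1$npv, 1)
  expect_equal(t1$ppv, 1)

  # hand-built confusion: tn = 9, fn = 1, tp = 1, fp = 6
  icp2 <- c(rep(10, 9), 25, 25, rep(10, 6))
  eicp2 <- c(rep(10, 9), 10, 25, rep(25, 6))
  t2 <- threshold_predictive_values(icp2, eicp2)
  expect_equal(c(t2$tn, t2$fn, t2$tp, t2$fp), c(9, 1, 1, 6))
  expect_equal(t2$npv, 0.9)
  expect_equal(t2$ppv, 1 / 7)
  expect_equal(t2$threshold, 20)
  expect_equal(t2$tp + t2$fp + t2$tn + t2$fn, length(icp2))

  # degenerate denominators flagged, not raised
  t3 <- threshold_predictive_values(c(10, 12), c(11, 13))
  expect_true(is.nan(t3$ppv))
  expect_true(t3$degenerate[["ppv"]])
})

test_that("per-patient summary reproduces the published difference column", {
  tab <- published_patient_table()
  preds <- data.frame(patient_id = tab$patient,
                      reference_icp_mmHg = tab$icp,
                      eicp_mmHg = tab$eicp)
  s <- per_patient_summary(preds)
  s <- s[match(tab$patient, s$patient_id), ]
  expect_equal(s$difference, tab$diff, tolerance = 0.005)

  # single window per patient: means equal that window's values
  expect_equal(s$mean_icp, tab$icp)
  expect_equal(s$mean_eicp, tab$eicp)

  # per-patient MAE always dominates the absolute mean difference
  set.seed(8)
  many <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:5), each = 20),
    reference_icp_mmHg = rnorm(100, 12, 4),
    eicp_mmHg = rnorm(100, 12, 4))
  sm <- per_patient_summary(many)
  expect_true(all(sm$mae >= abs(sm$difference) - 1e-12))
})

test_that("fold aggregation reproduces the published summary row", {
  folds <- published_fold_table()
  agg <- aggregate_folds(folds[, -1])
  expect_equal(round(agg$mean[["test_mae"]], 2), 1.23)
  expect_equal(round(agg$mean[["test_mse"]], 2), 3.68)
  expect_equal(round(agg$mean[["train_mae"]], 2), 0.91)
  expect_equal(round(agg$mean[["train_mse"]], 2), 1.88)
  expect_equal(round(agg$sd[["test_mse"]], 2), 0.34)

  # identical folds: zero SD
  same <- data.frame(a = rep(1.5, 4), b = rep(2, 4))
  agg0 <- aggregate_folds(same)
  expect_equal(unname(agg0$sd), c(0, 0))

  expect_error(aggregate_folds(data.frame(a = 1)), "2 folds")
  expect_error(aggregate_folds(data.frame(a = c(1, NA))), "non-finite")
})

test_that("the metrics report bundles consistent statistics", {
  set.seed(11)
  icp <- rnorm(200, 12, 5)
  eicp <- icp + rnorm(200, -0.2, 3)
  rep <- metrics_report(icp, eicp)
  expect_equal(rep$mae_mmHg, mean(abs(eicp - icp)), tolerance = 1e-12)
  expect_lte(rep$mae_mmHg, sqrt(rep$mse_mmHg2))
  expect_lte(rep$loa_low, rep$bias_mmHg)
  expect_gte(rep$loa_high, rep$bias_mmHg)
  expect_gte(rep$spearman_rho, -1)
  expect_lte(rep$spearman_rho, 1)
  expect_equal(sum(rep$error_bands), 1, tolerance = 1e-9)
  expect_equal(sum(rep$threshold_counts), rep$n_windows)
})
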