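#' Mean absolute and mean squared error
#'
#' @param icp Reference ICP values, mmHg.
#' @param eicp Estimated ICP values, mmHg.
#' @return List with `mae` and `mse`.
#' @export
regression_metrics <- function(icp, eicp) {
  check_pairs(icp, eicp, min_n = 1)
  d <- eicp - icp
  list(mae = mean(abs(d)), mse = mean(d^2))
}

check_pairs <- function(icp, eicp, min_n = 1) {
  if (length(icp) != length(eicp)) stop("length mismatch")
  if (length(icp) < min_n) stop("insufficient data: need at least ", min_n)
  if (any(!is.finite(icp)) || any(!is.finite(eicp))) {
    stop("non-finite values")
  }
  invisible(TRUE)
}

#' Bland-Altman agreement statistics
#'
#' Differences are `eicp - icp`; bias is their mean, `sd` the sample
#' (n-1) standard deviation, and the 95% limits of agreement are
#' `bias +/- 1.96 * sd`.
#'
#' @inheritParams regression_metrics
#' @return List with `bias`, `sd`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(icp, eicp) {
  check_pairs(icp, eicp, min_n = 2)
  d <- eicp - icp
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Spearman rank correlation with mid-rank ties
#'
#' @inheritParams regression_metrics
#' @return List with `rho` and two-sided `p`.
#' @export
spearman_correlation <- function(icp, eicp) {
  check_pairs(icp, eicp, min_n = 3)
  if (stats::var(icp) == 0 || stats::var(eicp) == 0) {
    stop("degenerate input: constant vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(icp, eicp, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Error-band histogram of absolute differences
#'
#' Proportions of `|eicp - icp|` in the bins bounded by `edges` (default
#' `[0,2), [2,4), [4,6), [6, Inf)` mmHg). Proportions sum to one.
#'
#' @inheritParams regression_metrics
#' @param edges Increasing interior bin edges, mmHg (default `c(2, 4, 6)`).
#' @return Named numeric vector of proportions.
#' @export
error_histogram <- function(icp, eicp, edges = c(2, 4, 6)) {
  check_pairs(icp, eicp, min_n = 1)
  stopifnot(all(diff(edges) > 0))
  a <- abs(eicp - icp)
  breaks <- c(0, edges, Inf)
  counts <- table(cut(a, breaks = breaks, right = FALSE,
                      include.lowest = TRUE))
  props <- as.numeric(counts) / length(a)
  names(props) <- c(paste0("lt", edges), paste0("ge", edges[length(edges)]))
  props
}

#' Predictive values at an intracranial hypertension threshold
#'
#' A window is positive when its value is at or above `threshold` (default
#' 20 mmHg), for both the reference (`icp`) and the prediction (`eicp`).
#' Degenerate denominators yield `NaN` and are flagged, not raised.
#'
#' @inheritParams regression_metrics
#' @param threshold Class boundary, mmHg (default 20).
#' @return List of class `threshold_report`: `threshold`, counts `tp`,
#'   `fp`, `tn`, `fn`, `npv`, `ppv`, and `degenerate` flags.
#' @export
threshold_predictive_values <- function(icp, eicp, threshold = 20) {
  check_pairs(icp, eicp, min_n = 1)
  truth <- icp >= threshold
  pred <- eicp >= threshold
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  tn <- sum(!truth & !pred)
  fn <- sum(truth & !pred)
  npv <- if (tn + fn > 0) tn / (tn + fn) else NaN
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NaN
  structure(list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
                 npv = npv, ppv = ppv,
                 degenerate = c(npv = tn + fn == 0, ppv = tp + fp == 0)),
            class = "threshold_report")
}

#' Per-patient agreement summary
#'
#' One row per patient: window-level MAE, mean reference ICP, mean eICP and
#' the difference of the means (`mean eICP - mean ICP`), mirroring the
#' per-patient validation table layout.
#'
#' @param predictions Data frame with `patient_id`, `reference_icp_mmHg`
#'   and `eicp_mmHg`.
#' @return Data frame: `patient_id`, `mae`, `mean_icp`, `mean_eicp`,
#'   `difference`.
#' @export
per_patient_summary <- function(predictions) {
  req <- c("patient_id", "reference_icp_mmHg", "eicp_mmHg")
  if (!all(req %in% names(predictions))) {
    stop("predictions must carry ", paste(req, collapse = ", "))
  }
  if (nrow(predictions) < 1) stop("need at least one prediction record")
  sp <- split(predictions, predictions$patient_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(
      patient_id = g$patient_id[1],
      mae = mean(abs(g$eicp_mmHg - g$reference_icp_mmHg)),
      mean_icp = mean(g$reference_icp_mmHg),
      mean_eicp = mean(g$eicp_mmHg),
      stringsAsFactors = FALSE)
  }))
  out$difference <- out$mean_eicp - out$mean_icp
  rownames(out) <- NULL
  out
}

#' Aggregate per-fold error columns
#'
#' Column-wise mean and sample SD of a per-fold error table (e.g. train/test
#' MAE and MSE rows); `display` carries the values rounded to two decimals.
#'
#' @param per_fold Data frame or matrix of numeric per-fold error columns.
#' @return List with `mean`, `sd` (named numeric) and `display` (data frame
#'   rounded to 2 decimals).
#' @export
aggregate_folds <- function(per_fold) {
  x <- as.data.frame(per_fold)
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 folds")
  if (any(vapply(x, function(cc) any(!is.finite(cc)), logical(1)))) {
    stop("validation error: non-finite fold values")
  }
  m <- vapply(x, mean, numeric(1))
  s <- vapply(x, stats::sd, numeric(1))
  display <- data.frame(column = names(m), mean = round(m, 2),
                        sd = round(s, 2), row.names = NULL)
  list(mean = m, sd = s, display = display)
}

#' Full agreement metrics report
#'
#' Bundles MAE/MSE, Bland-Altman statistics, Spearman correlation, the
#' error-band histogram and threshold predictive values for one set of
#' paired reference/estimated ICP windows.
#'
#' @inheritParams regression_metrics
#' @param threshold Intracranial hypertension boundary, mmHg.
#' @return List of class `metrics_report`.
#' @export
metrics_report <- function(icp, eicp, threshold = 20) {
  check_pairs(icp, eicp, min_n = 3)
  rm_ <- regression_metrics(icp, eicp)
  ba <- bland_altman(icp, eicp)
  sp <- spearman_correlation(icp, eicp)
  tr <- threshold_predictive_values(icp, eicp, threshold)
  structure(list(
    n_windows = length(icp),
    mae_mmHg = rm_$mae, mse_mmHg2 = rm_$mse,
    bias_mmHg = ba$bias, sd_mmHg = ba$sd,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    spearman_rho = sp$rho, spearman_p = sp$p,
    error_bands = error_histogram(icp, eicp),
    npv = tr$npv, ppv = tr$ppv,
    threshold_counts = c(tp = tr$tp, fp = tr$fp, tn = tr$tn, fn = tr$fn)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (n = %d windows)\n", x$n_windows))
  cat(sprintf("  MAE %.2f mmHg, MSE %.2f mmHg^2\n", x$mae_mmHg, x$mse_mmHg2))
  cat(sprintf("  Bland-Altman bias %.2f mmHg, SD %.2f, LoA [%.2f, %.2f]\n",
              x$bias_mmHg, x$sd_mmHg, x$loa_low, x$loa_high))
  cat(sprintf("  Spearman rho %.3f (p = %.3g)\n", x$spearman_rho, x$spearman_p))
  cat(sprintf("  NPV %.2f, PPV %.2f at 20 mmHg\n", x$npv, x$ppv))
  invisible(x)
}
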