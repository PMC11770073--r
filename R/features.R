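#' Assemble the per-window feature vector
#'
#' Deterministic mapping from a window's mean pulse, pulse parameters,
#' quality report and beat set to a named numeric feature vector. Categories:
#' landmark features (p2p1, p3p1, p3p2, t_p1, t_p2, ttp, auc, amplitude,
#' width at 50% amplitude, maximum upstroke slope, mean decay slope),
#' spectral features (relative harmonic powers h1..h5, spectral centroid,
#' snr) taken from the quality report's spectrum, and statistical features
#' (mean/sd/skewness/kurtosis of the mean pulse, beat-to-beat SD of period
#' and amplitude, heart rate). Isomap embedding coordinates are appended
#' separately at training time (see [fit_embedding()]).
#'
#' @param pulse A `mean_pulse`.
#' @param params A `pulse_params`.
#' @param qc A `quality_report` from [quality_gate()]; must be accepted.
#' @param beats A `beat_set`.
#' @return Named numeric vector; all entries finite.
#' @export
build_feature_vector <- function(pulse, params, qc, beats) {
  if (!isTRUE(qc$accepted)) {
    stop("not accepted: feature extraction requires a quality-accepted window")
  }
  v <- pulse$values
  L <- length(v)
  tfrac <- (seq_len(L) - 1) / (L - 1)
  vmax <- max(v)
  imax <- which.max(v)

  lm_feats <- c(
    p2p1 = params$p2p1_ratio,
    p3p1 = NA_real_, p3p2 = NA_real_,
    t_p1 = NA_real_, t_p2 = NA_real_,
    ttp = params$ttp, auc = params$auc,
    amplitude = pulse$amplitude,
    width50 = mean(v >= 0.5 * vmax),
    upstroke_max = max(diff(v[1:imax])) * (L - 1),
    decay_slope = if (imax < L) (v[L] - vmax) / (1 - tfrac[imax]) else 0)

  spec <- qc$spectrum
  total <- band_power(spec, 0.1, 25)
  h <- vapply(1:5, function(k) {
    band_power(spec, k * qc$f0_hz - 0.3, k * qc$f0_hz + 0.3) / total
  }, numeric(1))
  in_band <- spec$freqs_hz >= 0.1 & spec$freqs_hz <= 25
  centroid <- sum(spec$freqs_hz[in_band] * spec$psd[in_band]) /
    sum(spec$psd[in_band])
  sp_feats <- c(h1 = h[1], h2 = h[2], h3 = h[3], h4 = h[4], h5 = h[5],
                spectral_centroid = centroid, snr = qc$snr)

  st_feats <- c(
    pulse_mean = mean(v), pulse_sd = stats::sd(v),
    pulse_skewness = e1071::skewness(v), pulse_kurtosis = e1071::kurtosis(v),
    period_sd = stats::sd(beats$durations_s),
    beat_amp_sd = stats::sd(beats$p2p_amplitudes),
    heart_rate_bpm = 60 / mean(beats$durations_s))

  out <- c(lm_feats, sp_feats, st_feats)
  # landmark times/ratios from the landmark attribute when carried
  lm <- attr(params, "landmarks")
  if (!is.null(lm)) {
    out["t_p1"] <- lm$t_p1
    out["t_p2"] <- lm$t_p2
    out["p3p1"] <- if (isTRUE(lm$p3_present)) lm$a_p3 / lm$a_p1 else 0
    out["p3p2"] <- if (isTRUE(lm$p3_present)) lm$a_p3 / lm$a_p2 else 0
  } else {
    out["t_p1"] <- 0
    out["t_p2"] <- 0
    out["p3p1"] <- 0
    out["p3p2"] <- 0
  }
  if (any(!is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite features: ", paste(bad, collapse = ", "))
  }
  out
}

#' Fit an Isomap embedding of mean-pulse waveforms
#'
#' Classical Isomap on amplitude-normalized pulses: a k-nearest-neighbour
#' Euclidean graph, geodesic (shortest-path) distances, double centering and
#' eigendecomposition. For cohorts larger than `n_landmarks`, a deterministic
#' evenly spaced subset of pulses serves as landmarks and all other points
#' are embedded by the same Nystrom out-of-sample rule used by
#' [apply_embedding()].
#'
#' @param train_pulses Numeric matrix, one pulse per row (length `L` each);
#'   at least 50 rows.
#' @param n_neighbors Neighbourhood size of the graph (default 10).
#' @param n_components Output dimensionality (default 25).
#' @param n_landmarks Maximum number of landmark pulses (default 500).
#' @return An object of class `icp_embedding` with the landmark data,
#'   geodesic distances, spectral decomposition, and `training_coords` (the
#'   embedding of every input row).
#' @export
fit_embedding <- function(train_pulses, n_neighbors = 10, n_components = 25,
                          n_landmarks = 500) {
  x <- as.matrix(train_pulses)
  if (nrow(x) < 50) stop("need at least 50 training pulses")
  xn <- normalize_pulses(x)
  n <- nrow(xn)
  land_idx <- if (n > n_landmarks) {
    unique(round(seq(1, n, length.out = n_landmarks)))
  } else seq_len(n)
  lm <- xn[land_idx, , drop = FALSE]
  m <- nrow(lm)

  d <- as.matrix(stats::dist(lm))
  # symmetric (union) kNN graph
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    nb <- order(d[i, ])[2:(n_neighbors + 1)]
    adj[i, nb] <- TRUE
    adj[nb, i] <- TRUE
  }
  w <- d
  w[!adj] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    stop("disconnected neighbour graph: increase n_neighbors (currently ",
         n_neighbors, ")")
  }
  D <- igraph::distances(g)
  D2 <- D^2
  J <- diag(m) - matrix(1 / m, m, m)
  B <- -0.5 * J %*% D2 %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  k <- n_components
  lambda <- eig$values[seq_len(k)]
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  scale <- ifelse(lambda > 1e-12, sqrt(pmax(lambda, 0)), 0)
  coords <- sweep(vec, 2, scale, `*`)
  colnames(coords) <- paste0("iso_", seq_len(k))

  model <- structure(list(
    landmarks = lm, land_idx = land_idx, D = D,
    col_mean_D2 = colMeans(D2), eigvals = lambda, eigvecs = vec,
    n_neighbors = n_neighbors, n_components = k,
    landmark_coords = coords, L = ncol(xn)),
    class = "icp_embedding")
  model$training_coords <- apply_embedding(model, x)
  model
}

normalize_pulses <- function(x) {
  mx <- apply(x, 1, max)
  mx[mx == 0] <- 1
  x / mx
}

#' @export
print.icp_embedding <- function(x, ...) {
  cat(sprintf("icp_embedding: %d landmarks, k=%d neighbours, %d components\n",
              nrow(x$landmarks), x$n_neighbors, x$n_components))
  invisible(x)
}

#' Embed new pulses with a fitted Isomap model
#'
#' Nystrom out-of-sample extension: the geodesic distance from a new pulse to
#' each landmark is approximated through its `n_neighbors` nearest landmarks
#' (Euclidean hop plus in-graph geodesic); the embedding follows from the
#' model's spectral decomposition. A training landmark maps exactly to its
#' fitted coordinates.
#'
#' @param model An `icp_embedding`.
#' @param pulses Numeric matrix (or single vector) of pulses, length `L`.
#' @return Matrix of embedding coordinates, `n_components` columns.
#' @export
apply_embedding <- function(model, pulses) {
  stopifnot(inherits(model, "icp_embedding"))
  x <- if (is.null(dim(pulses))) matrix(pulses, nrow = 1) else as.matrix(pulses)
  if (ncol(x) != model$L) {
    stop("dimension error: pulses must have length ", model$L)
  }
  xn <- normalize_pulses(x)
  m <- nrow(model$landmarks)
  k <- model$n_components
  inv2s <- ifelse(model$eigvals > 1e-12, 1 / (2 * sqrt(model$eigvals)), 0)
  out <- matrix(0, nrow(xn), k)
  for (i in seq_len(nrow(xn))) {
    de <- sqrt(colSums((t(model$landmarks) - xn[i, ])^2))
    nb <- order(de)[seq_len(min(model$n_neighbors, m))]
    geo <- apply(de[nb] + model$D[nb, , drop = FALSE], 2, min)
    out[i, ] <- as.numeric((model$col_mean_D2 - geo^2) %*% model$eigvecs) * inv2s
  }
  colnames(out) <- paste0("iso_", seq_len(k))
  out
}

#' Rank and select features by Spearman correlation with the target
#'
#' Candidates are ranked by the absolute Spearman correlation with the
#' regression target; those with `|rho| < min_target_rho` are dropped as
#' uninformative; the rest are accepted greedily unless their absolute
#' Spearman correlation with an already-selected feature reaches
#' `redundancy_threshold`; selection stops at `k` features.
#'
#' @param features Numeric matrix or data frame of candidate features with
#'   column names.
#' @param target Numeric target (ICP values), non-constant.
#' @param k Maximum number of selected features (default 15).
#' @param redundancy_threshold Pairwise `|rho|` exclusion bound (default 0.9).
#' @param min_target_rho Minimum `|rho|` with the target (default 0.05).
#' @return An object of class `feature_selection`: `selected_names` (ordered
#'   by decreasing `|rho|`), `rho` (named, all candidates),
#'   `redundancy_threshold`.
#' @export
select_features <- function(features, target, k = 15,
                            redundancy_threshold = 0.9,
                            min_target_rho = 0.05) {
  x <- as.matrix(features)
  if (ncol(x) < 2) stop("need at least 2 candidate features")
  if (length(target) != nrow(x)) stop("target length must match feature rows")
  if (stats::var(target) == 0) stop("degenerate target: constant ICP values")
  rho <- suppressWarnings(
    as.numeric(stats::cor(x, target, method = "spearman")))
  rho[!is.finite(rho)] <- 0
  names(rho) <- colnames(x)
  ord <- order(abs(rho), decreasing = TRUE)
  selected <- character(0)
  for (j in ord) {
    if (length(selected) >= k) break
    if (abs(rho[j]) < min_target_rho) next
    if (length(selected) > 0) {
      r_sel <- suppressWarnings(abs(stats::cor(
        x[, j], x[, selected, drop = FALSE], method = "spearman")))
      r_sel[!is.finite(r_sel)] <- 1
      if (any(r_sel >= redundancy_threshold)) next
    }
    selected <- c(selected, colnames(x)[j])
  }
  structure(list(selected_names = selected, rho = rho,
                 redundancy_threshold = redundancy_threshold),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("feature_selection: %d features (redundancy < %.2f)\n",
              length(x$selected_names), x$redundancy_threshold))
  for (nm in x$selected_names) {
    cat(sprintf("  %-18s rho = %+.3f\n", nm, x$rho[nm]))
  }
  invisible(x)
}
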