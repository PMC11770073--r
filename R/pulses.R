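#' Segment a recording into consecutive 10-s windows
#'
#' Non-overlapping windows; a trailing partial window is dropped. The
#' reference ICP of a window is the arithmetic mean of the ICP channel inside
#' it (no waveform processing is applied to the reference channel).
#'
#' @param rec A `raw_recording`.
#' @param window_s Window length in seconds (default 10).
#' @return List of `window` objects: `window_id`, `patient_id`, `start_s`,
#'   `fs_hz`, `samples`, and `reference_icp_mmHg` (NA when unmonitored).
#' @export
segment_windows <- function(rec, window_s = 10) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs_hz
  nw <- floor(rec$n_samples / (window_s * fs))
  if (nw < 1) stop("too short: recording shorter than one window")
  sig <- rec$channels$cranial_expansion
  icp <- rec$channels$icp_mmHg
  lapply(seq_len(nw), function(w) {
    i0 <- round((w - 1) * window_s * fs) + 1
    i1 <- round(w * window_s * fs)
    structure(list(
      window_id = sprintf("%s_w%04d", rec$patient_id, w),
      patient_id = rec$patient_id,
      start_s = (w - 1) * window_s,
      fs_hz = fs,
      samples = sig[i0:i1],
      reference_icp_mmHg = if (is.null(icp)) NA_real_ else mean(icp[i0:i1])),
      class = "icp_window")
  })
}

# local maxima with a refractory spacing (samples); greedy by height
find_peaks_refractory <- function(x, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(i - keep) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detrend and polarity-correct a cranial-expansion signal
#'
#' Zero-phase second-order Butterworth band-pass (0.3-20 Hz), then an
#' inversion check: over detected beats the systolic upstroke (onset to
#' maximum) should be the fast limb; if the median onset-to-max time exceeds
#' the median max-to-next-onset time, the signal is negated.
#'
#' @param samples Raw window or recording samples (finite).
#' @param fs_hz Sampling rate, Hz.
#' @param band Pass band in Hz, default `c(0.3, 20)`.
#' @return Filtered (and possibly negated) samples.
#' @export
preprocess_signal <- function(samples, fs_hz, band = c(0.3, 20)) {
  if (length(samples) == 0) stop("degenerate signal: empty input")
  if (any(!is.finite(samples))) stop("degenerate signal: non-finite samples")
  bf <- signal::butter(2, band / (fs_hz / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, samples))
  f0 <- tryCatch(
    fundamental_frequency(estimate_psd(y, fs_hz)),
    error = function(e) NULL)
  if (!is.null(f0)) {
    frac <- upstroke_fraction(y, fs_hz, f0)
    if (is.finite(frac) && frac > 0.5) y <- -y
  }
  y
}

# Beat onsets: complexes located on a fundamental-band moving-average
# envelope (so prominent P2 waves are not split into separate beats), each
# onset refined to the pulse foot on the raw samples.
detect_feet <- function(samples, fs_hz, f0_hz) {
  kern <- max(round(0.3 / f0_hz * fs_hz), 1)
  env <- stats::filter(samples, rep(1 / kern, kern), sides = 2)
  env[is.na(env)] <- samples[is.na(env)]
  peaks <- find_peaks_refractory(as.numeric(env),
                                 round(0.7 / f0_hz * fs_hz))
  if (length(peaks) < 2) return(integer(0))
  onsets <- integer(0)
  for (k in seq_len(length(peaks) - 1)) {
    seg_idx <- peaks[k]:peaks[k + 1]
    onsets <- c(onsets, pulse_foot(samples, seg_idx))
  }
  onsets <- unique(onsets)
  if (length(onsets) > 1) {
    keep <- c(TRUE, diff(onsets) >= 0.5 / f0_hz * fs_hz)
    onsets <- onsets[keep]
  }
  onsets
}

# median fraction of the beat spent on the onset-to-maximum limb; the
# systolic upstroke should be the fast limb (fraction < 0.5)
upstroke_fraction <- function(y, fs_hz, f0_hz) {
  feet <- detect_feet(y, fs_hz, f0_hz)
  if (length(feet) < 4) return(NA_real_)
  fr <- numeric(0)
  for (k in seq_len(length(feet) - 1)) {
    seg <- y[feet[k]:(feet[k + 1] - 1)]
    fr <- c(fr, which.max(seg) / length(seg))
  }
  stats::median(fr)
}

#' Identify beats and reject artifact-contaminated ones
#'
#' Onsets are the local minima preceding systolic upstrokes, with a
#' refractory period of half the expected cardiac cycle. A beat is rejected
#' when (i) its duration falls outside `[0.5, 1.8] / f0`, (ii) its
#' peak-to-peak amplitude falls outside the window median +/- 3 MAD, or
#' (iii) its correlation with the running (median) beat template is below
#' `template_corr_min`.
#'
#' @param samples Preprocessed window samples.
#' @param fs_hz Sampling rate, Hz.
#' @param f0_hz Fundamental (cardiac) frequency, Hz.
#' @param template_corr_min Template-correlation rejection threshold (0.7).
#' @return An object of class `beat_set`: `onset_indices`, `beats` (list of
#'   sample slices), `durations_s`, `p2p_amplitudes`, `n_rejected`, `fs_hz`.
#' @export
extract_beats <- function(samples, fs_hz, f0_hz, template_corr_min = 0.7) {
  onsets <- detect_feet(samples, fs_hz, f0_hz)
  if (length(onsets) < 4) stop("insufficient beats: fewer than 3 complete beats")

  beats <- lapply(seq_len(length(onsets) - 1), function(k) {
    samples[onsets[k]:(onsets[k + 1] - 1)]
  })
  ons <- onsets[-length(onsets)]
  dur <- vapply(beats, length, integer(1)) / fs_hz
  p2p <- vapply(beats, function(b) max(b) - min(b), numeric(1))

  ok <- dur >= 0.5 / f0_hz & dur <= 1.8 / f0_hz
  med <- stats::median(p2p[ok])
  madv <- stats::mad(p2p[ok])
  if (is.finite(madv) && madv > 0) {
    ok <- ok & abs(p2p - med) <= 3 * madv
  }
  # correlation against the running (pointwise-median) template, two passes
  for (pass in 1:2) {
    if (sum(ok) < 3) break
    rs <- vapply(beats, resample_beat, numeric(100), L = 100)
    templ <- apply(rs[, ok, drop = FALSE], 1, stats::median)
    cors <- suppressWarnings(as.numeric(stats::cor(rs, templ)))
    cors[!is.finite(cors)] <- -1
    ok_new <- ok & cors >= template_corr_min
    if (identical(ok_new, ok)) break
    ok <- ok_new
  }
  if (sum(ok) < 3) stop("insufficient beats: fewer than 3 beats survive curation")
  structure(list(
    onset_indices = ons[ok], beats = beats[ok],
    durations_s = dur[ok], p2p_amplitudes = p2p[ok],
    n_rejected = sum(!ok), fs_hz = fs_hz),
    class = "beat_set")
}

# Pulse foot within an inter-peak segment: the last sample before the next
# systolic peak still within `frac` of the upstroke amplitude above the
# segment minimum. Robust to flat diastolic tails, unlike a plain argmin.
pulse_foot <- function(x, seg_idx, frac = 0.05) {
  seg <- x[seg_idx]
  minv <- min(seg)
  thr <- minv + frac * (seg[length(seg)] - minv)
  below <- which(seg <= thr)
  below <- below[below < length(seg)]
  if (length(below) == 0) return(seg_idx[which.min(seg)])
  seg_idx[max(below)]
}

resample_beat <- function(b, L = 100) {
  stats::approx(seq(0, 1, length.out = length(b)), b,
                xout = seq(0, 1, length.out = L))$y
}

#' Aligned, length-normalized average pulse
#'
#' Each beat is linearly resampled to `L` points from its onset and its
#' onset (first-sample) value subtracted. Residual onset jitter is then
#' removed by aligning every beat to the point-wise median template at its
#' best circular lag (within `max_lag` points) before taking the point-wise
#' mean.
#'
#' @param beats A `beat_set` with at least 3 beats.
#' @param L Number of resample points (default 100).
#' @param max_lag Maximum alignment shift in resampled points (default 8).
#' @return An object of class `mean_pulse`: `values` (length `L`, onset at
#'   zero), `n_beats_averaged` and `amplitude` (max minus onset value).
#' @export
average_pulse <- function(beats, L = 100, max_lag = 8) {
  stopifnot(inherits(beats, "beat_set"))
  if (length(beats$beats) < 3) stop("insufficient beats: need at least 3")
  rs <- vapply(beats$beats, function(b) {
    v <- resample_beat(b, L)
    v - v[1]
  }, numeric(L))
  if (max_lag > 0 && ncol(rs) >= 3) {
    templ <- apply(rs, 1, stats::median)
    lags <- -max_lag:max_lag
    rs <- vapply(seq_len(ncol(rs)), function(j) {
      cors <- vapply(lags, function(s) {
        stats::cor(rs[((seq_len(L) - 1 + s) %% L) + 1, j], templ)
      }, numeric(1))
      s <- lags[which.max(cors)]
      rs[((seq_len(L) - 1 + s) %% L) + 1, j]
    }, numeric(L))
  }
  values <- rowMeans(rs)
  values <- values - values[1]
  structure(list(values = values,
                 n_beats_averaged = length(beats$beats),
                 amplitude = max(values) - values[1]),
            class = "mean_pulse")
}

#' @export
print.mean_pulse <- function(x, ...) {
  cat(sprintf("mean_pulse: L=%d, %d beats averaged, amplitude=%.4g\n",
              length(x$values), x$n_beats_averaged, x$amplitude))
  invisible(x)
}

#' Locate the P1, P2 and P3 landmarks on a mean pulse
#'
#' The pulse is smoothed with a Savitzky-Golay filter (window 11, order 3).
#' Candidates are the local maxima; if fewer than two exist, shoulder
#' candidates are added at local minima of the second derivative (points of
#' strongest concavity) on the rising and falling limbs of the main peak.
#' P1 is the earliest candidate at or before `p1_max_t` (default 0.45 of the
#' pulse), P2 the next candidate up to `p2_max_t` (default 0.7), and P3
#' (optional) the first candidate after P2.
#'
#' @param pulse A `mean_pulse`.
#' @param p1_max_t,p2_max_t Fractional-time region boundaries for P1 and P2.
#' @return An object of class `pulse_landmarks`: fractional times `t_p1`,
#'   `t_p2`, `t_p3`, amplitudes `a_p1`, `a_p2`, `a_p3` above the pulse
#'   baseline (the minimum of the smoothed pulse), and `p3_present`.
#' @export
detect_landmarks <- function(pulse, p1_max_t = 0.45, p2_max_t = 0.7) {
  stopifnot(inherits(pulse, "mean_pulse"))
  v <- pulse$values
  L <- length(v)
  sm <- as.numeric(signal::sgolayfilt(v, p = 3, n = 11))
  tfrac <- (seq_len(L) - 1) / (L - 1)

  maxima <- find_peaks_refractory(sm, 3)
  cand <- maxima
  if (length(maxima) < 2) {
    d2 <- c(NA, diff(sm, differences = 2), NA)
    gmax <- which.max(sm)
    # genuine concavity only: guards against numerical noise on ramps
    d2_tol <- 1e-6 * diff(range(sm))
    conc <- which(!is.na(d2) & d2 < -d2_tol)
    sh <- conc[conc %in% local_minima(d2)]
    sh <- sh[sh > 3 & sh < L - 2]
    sh <- sh[vapply(sh, function(i) all(abs(i - maxima) > 3), logical(1))]
    cand <- sort(unique(c(maxima, sh)))
  }
  if (length(cand) == 0) stop("landmark failure: no pulse peak candidates")

  p1_cand <- cand[tfrac[cand] <= p1_max_t]
  if (length(p1_cand) == 0) {
    stop("landmark failure: no candidate in the P1 region")
  }
  i1 <- p1_cand[1]
  p2_cand <- cand[tfrac[cand] > tfrac[i1] & tfrac[cand] <= p2_max_t]
  if (length(p2_cand) == 0) {
    stop("landmark failure: no candidate in the P2 region")
  }
  i2 <- p2_cand[1]
  p3_cand <- cand[tfrac[cand] > tfrac[i2]]
  i3 <- if (length(p3_cand) > 0) p3_cand[1] else NA_integer_
  # amplitude baseline: the pulse minimum, robust to foot-threshold offset
  base <- min(sm)
  structure(list(
    t_p1 = tfrac[i1], t_p2 = tfrac[i2],
    t_p3 = if (is.na(i3)) NA_real_ else tfrac[i3],
    a_p1 = sm[i1] - base, a_p2 = sm[i2] - base,
    a_p3 = if (is.na(i3)) NA_real_ else sm[i3] - base,
    p3_present = !is.na(i3)),
    class = "pulse_landmarks")
}

local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  ok <- !is.na(x)
  idx <- which(ok[2:(n - 1)] & ok[1:(n - 2)] & ok[3:n] &
                 x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1
  idx
}

#' Morphological parameters of a mean pulse
#'
#' `p2p1` is the P2/P1 amplitude ratio; `ttp` the normalized time of the
#' global maximum (onset = 0, end of pulse = 1); `auc` the trapezoidal area
#' of the amplitude-normalized pulse over unit time; `icc_class` an ordinal
#' intracranial-compliance stand-in scale (1: P2/P1 < 1, 2: 1 <= P2/P1 <=
#' 1.2, 3: P2/P1 > 1.2).
#'
#' @param pulse A `mean_pulse`.
#' @param lm A `pulse_landmarks`.
#' @return An object of class `pulse_params`.
#' @export
pulse_parameters <- function(pulse, lm) {
  stopifnot(inherits(pulse, "mean_pulse"), inherits(lm, "pulse_landmarks"))
  if (lm$a_p1 <= 0) stop("division error: a_p1 must be positive")
  v <- pulse$values
  L <- length(v)
  tfrac <- (seq_len(L) - 1) / (L - 1)
  p2p1 <- lm$a_p2 / lm$a_p1
  ttp <- tfrac[which.max(v)]
  auc <- pracma::trapz(tfrac, v / max(v))
  icc <- if (p2p1 < 1.0) 1L else if (p2p1 <= 1.2) 2L else 3L
  structure(list(p2p1_ratio = p2p1, ttp = ttp, auc = auc, icc_class = icc),
            class = "pulse_params")
}
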