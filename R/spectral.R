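#' Welch power spectral density estimate
#'
#' Mean of modified periodograms over Hann-windowed 4-s segments with 50%
#' overlap, each segment mean-removed. One-sided density scaling, so the
#' discrete integral `sum(psd) * df` matches the signal variance (Parseval).
#'
#' @param x Detrended window samples (numeric, finite, >= 4 s).
#' @param fs_hz Sampling rate, Hz.
#' @param segment_s Segment length in seconds (default 4).
#' @return An object of class `spectrum_estimate`: list with `freqs_hz`,
#'   `psd` (power per Hz) and `df` (bin width, Hz).
#' @export
estimate_psd <- function(x, fs_hz, segment_s = 4) {
  if (length(x) == 0 || any(!is.finite(x))) {
    stop("degenerate signal: empty or non-finite samples")
  }
  nseg <- round(segment_s * fs_hz)
  if (length(x) < nseg) {
    stop("degenerate signal: need at least ", segment_s, " s of samples")
  }
  step <- floor(nseg / 2)
  starts <- seq(1, length(x) - nseg + 1, by = step)
  k <- seq_len(nseg) - 1
  w <- 0.5 - 0.5 * cos(2 * pi * k / nseg)  # periodic Hann
  u <- sum(w^2)
  n_half <- floor(nseg / 2)
  acc <- numeric(n_half + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (fs_hz * u)
    ps <- p[1:(n_half + 1)]
    # fold two-sided density into one-sided (DC and Nyquist not doubled)
    if (nseg %% 2 == 0) {
      ps[2:n_half] <- 2 * ps[2:n_half]
    } else {
      ps[2:(n_half + 1)] <- 2 * ps[2:(n_half + 1)]
    }
    acc <- acc + ps
  }
  psd <- acc / length(starts)
  df <- fs_hz / nseg
  structure(list(freqs_hz = (0:n_half) * df, psd = psd, df = df),
            class = "spectrum_estimate")
}

#' Fundamental (cardiac) frequency from a spectrum
#'
#' Frequency of maximum power density within the cardiac search band.
#'
#' @param spec A `spectrum_estimate`.
#' @param search_band Two-element band in Hz, default `c(0.5, 3)`.
#' @return Fundamental frequency `f0` in Hz.
#' @export
fundamental_frequency <- function(spec, search_band = c(0.5, 3.0)) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  if (search_band[1] < min(spec$freqs_hz) || search_band[2] > max(spec$freqs_hz)) {
    stop("search band outside spectrum range")
  }
  in_band <- spec$freqs_hz >= search_band[1] & spec$freqs_hz <= search_band[2]
  if (!any(in_band) || all(spec$psd[in_band] == 0)) {
    stop("no fundamental: no power in the cardiac band")
  }
  spec$freqs_hz[in_band][which.max(spec$psd[in_band])]
}

# Discrete band power: Riemann sum (bin width df) over the bins whose
# centres fall inside [lo, hi]. Consistent with the Parseval normalization
# of estimate_psd, and exact for line spectra where a trapezoid on the bin
# grid would lose the half-bin mass at band edges.
band_power <- function(spec, lo, hi) {
  idx <- which(spec$freqs_hz >= lo & spec$freqs_hz <= hi)
  if (length(idx) == 0) return(0)
  sum(spec$psd[idx]) * spec$df
}

# Merge overlapping [lo, hi] intervals, clipped to `clip`.
merge_bands <- function(bands, clip) {
  bands <- lapply(bands, function(b) c(max(b[1], clip[1]), min(b[2], clip[2])))
  bands <- Filter(function(b) b[2] > b[1], bands)
  if (length(bands) == 0) return(list())
  ord <- order(vapply(bands, `[`, numeric(1), 1))
  bands <- bands[ord]
  out <- list(bands[[1]])
  for (b in bands[-1]) {
    last <- out[[length(out)]]
    if (b[1] <= last[2]) {
      out[[length(out)]] <- c(last[1], max(last[2], b[2]))
    } else {
      out[[length(out) + 1]] <- b
    }
  }
  out
}

#' Spectral signal-to-noise ratio
#'
#' Ratio of the power within the fundamental frequency band and its first
#' three harmonics (bands `k * f0 +/- harmonic_halfwidth`, `k = 1..4`,
#' overlapping bands merged) to the power over the full 0.1-25 Hz range.
#' Lies in `[0, 1]` whenever the harmonic bands are inside the full range.
#'
#' @param spec A `spectrum_estimate`.
#' @param f0_hz Fundamental frequency in `[0.5, 3]` Hz.
#' @param harmonic_halfwidth Band half-width, Hz (default 0.3).
#' @param n_harmonics Number of bands including the fundamental (default 4,
#'   i.e. the fundamental plus three harmonics; set 3 for a stricter read).
#' @param total_band The reference band, default `c(0.1, 25)` Hz.
#' @return SNR in `[0, 1]`.
#' @export
compute_snr <- function(spec, f0_hz, harmonic_halfwidth = 0.3,
                        n_harmonics = 4, total_band = c(0.1, 25)) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  if (f0_hz < 0.5 || f0_hz > 3.0) stop("f0 outside the cardiac band [0.5, 3] Hz")
  bands <- lapply(seq_len(n_harmonics), function(k) {
    c(k * f0_hz - harmonic_halfwidth, k * f0_hz + harmonic_halfwidth)
  })
  bands <- merge_bands(bands, total_band)
  num <- sum(vapply(bands, function(b) band_power(spec, b[1], b[2]), numeric(1)))
  den <- band_power(spec, total_band[1], total_band[2])
  if (den <= 0) stop("degenerate signal: no power in the reference band")
  min(num / den, 1)
}

#' Canonical triphasic mean-pulse template
#'
#' A reference pulse shape used by the morphology stage of the quality gate,
#' parameterized by its P2/P1 ratio so the gate can score a window against
#' the physiological range from P1-dominant to markedly elevated P2. The
#' template is rotated to start at its pulse foot, matching how extracted
#' beats are onset-aligned.
#'
#' @param L Number of points (default 100).
#' @param p2p1 P2/P1 amplitude ratio of the template (default 0.9).
#' @return Numeric vector of length `L`, onset value subtracted.
#' @export
canonical_pulse_template <- function(L = 100, p2p1 = 0.9) {
  y <- simulate_pulse_template(pulse_morph_params(amp = c(1, p2p1, 0.55)),
                               4 * L)
  n <- length(y)
  peak <- which.max(y)
  thr <- min(y) + 0.05 * (max(y) - min(y))
  # walk backwards (cyclically) from the P1 peak to the pulse foot
  back <- ((peak - 1 - seq_len(n)) %% n) + 1
  onset <- back[which(y[back] <= thr)[1]]
  y <- c(y[onset:n], y[seq_len(onset - 1)])
  v <- resample_beat(y, L)
  v - v[1]
}

#' Two-stage window quality gate
#'
#' Stage one: the spectral SNR must exceed `snr_threshold` (default 0.35).
#' Stage two (when a mean pulse is supplied): the Pearson correlation of the
#' length-normalized mean pulse with the canonical triphasic template must
#' reach `morph_threshold` and the pulse onset value must lie below its
#' maximum. A window is accepted only if all applied stages pass. Flat or
#' non-finite windows are rejected with a degenerate flag rather than an
#' error.
#'
#' @param window_signal 10-s window of (preprocessed) samples.
#' @param fs_hz Sampling rate, Hz.
#' @param mean_pulse Optional [average_pulse()] result for stage two.
#' @param snr_threshold SNR gate (default 0.35).
#' @param morph_threshold Template-correlation gate (default 0.8).
#' @return An object of class `quality_report`: `snr`, `f0_hz`, `snr_pass`,
#'   `morphology_score`, `morphology_pass`, `accepted`, `degenerate`, and the
#'   underlying `spectrum`.
#' @export
quality_gate <- function(window_signal, fs_hz, mean_pulse = NULL,
                         snr_threshold = 0.35, morph_threshold = 0.8) {
  rep0 <- structure(
    list(snr = NA_real_, f0_hz = NA_real_, snr_pass = FALSE,
         morphology_score = NA_real_, morphology_pass = NA,
         accepted = FALSE, degenerate = TRUE, spectrum = NULL),
    class = "quality_report")
  if (length(window_signal) == 0 || any(!is.finite(window_signal)) ||
      stats::sd(window_signal) == 0) {
    return(rep0)
  }
  spec <- tryCatch(estimate_psd(window_signal, fs_hz), error = function(e) NULL)
  if (is.null(spec)) return(rep0)
  f0 <- tryCatch(fundamental_frequency(spec), error = function(e) NULL)
  if (is.null(f0)) return(rep0)
  snr <- compute_snr(spec, f0)
  snr_pass <- snr > snr_threshold

  morph_score <- NA_real_
  morph_pass <- NA
  if (!is.null(mean_pulse)) {
    v <- mean_pulse$values
    # best correlation over the physiological template bank (normal to
    # markedly elevated P2/P1) and over small circular onset lags, so
    # high-pressure morphologies and minor foot-detection offsets are not
    # systematically rejected
    L <- length(v)
    lags <- -10:10
    morph_score <- max(vapply(c(0.7, 1.0, 1.4, 2.0), function(r) {
      tpl <- canonical_pulse_template(L, p2p1 = r)
      max(vapply(lags, function(s) {
        stats::cor(v, tpl[((seq_len(L) - 1 + s) %% L) + 1])
      }, numeric(1)))
    }, numeric(1)))
    morph_pass <- is.finite(morph_score) && morph_score >= morph_threshold &&
      v[1] < max(v)
  }
  accepted <- snr_pass && (is.na(morph_pass) || isTRUE(morph_pass))
  structure(
    list(snr = snr, f0_hz = f0, snr_pass = snr_pass,
         morphology_score = morph_score, morphology_pass = morph_pass,
         accepted = accepted, degenerate = FALSE, spectrum = spec),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "quality_report: snr=%.3f (pass=%s), f0=%.2f Hz, morphology=%.3f (pass=%s), accepted=%s\n",
    x$snr, x$snr_pass, x$f0_hz,
    ifelse(is.na(x$morphology_score), NA, x$morphology_score),
    x$morphology_pass, x$accepted))
  invisible(x)
}
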