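#' Pulse morphology parameters
#'
#' Describes one cardiac-gated cranial-expansion pulse as the sum of three
#' Gaussian bumps standing for the P1 (percussion), P2 (tidal) and P3 waves.
#' Times are fractions of the cardiac period, amplitudes are in arbitrary
#' sensor units, widths are Gaussian standard deviations as fractions of the
#' period.
#'
#' @param tau numeric(3), strictly increasing fractional peak times in (0,1).
#' @param amp numeric(3), nonnegative peak amplitudes; `amp[1] > 0`.
#' @param width numeric(3), bump widths in (0, 0.5).
#' @return An object of class `pulse_morph_params`.
#' @examples
#' m <- pulse_morph_params()
#' simulate_pulse_template(m, 100)
#' @export
pulse_morph_params <- function(tau = c(0.15, 0.40, 0.62),
                               amp = c(1.0, 0.9, 0.55),
                               width = c(0.055, 0.075, 0.080)) {
  stopifnot(length(tau) == 3, length(amp) == 3, length(width) == 3)
  if (any(!is.finite(c(tau, amp, width)))) {
    stop("invalid morphology: non-finite parameter")
  }
  if (any(diff(tau) <= 0) || any(tau <= 0) || any(tau >= 1)) {
    stop("invalid morphology: tau must be strictly increasing within (0,1)")
  }
  if (amp[1] <= 0 || any(amp < 0)) {
    stop("invalid morphology: amplitudes must be nonnegative with amp[1] > 0")
  }
  if (any(width <= 0) || any(width >= 0.5)) {
    stop("invalid morphology: widths must lie in (0, 0.5)")
  }
  structure(list(tau = tau, amp = amp, width = width),
            class = "pulse_morph_params")
}

#' Evaluate a pulse template over one cardiac period
#'
#' Sum of the three Gaussian bumps on a uniform grid over `[0, 1)`.
#' Deterministic in its inputs.
#'
#' @param morph A [pulse_morph_params()] object.
#' @param n_points Number of grid points (positive integer).
#' @return Numeric vector of `n_points` amplitudes.
#' @export
simulate_pulse_template <- function(morph, n_points) {
  if (!inherits(morph, "pulse_morph_params")) morph <- do.call(pulse_morph_params, morph)
  stopifnot(is.numeric(n_points), length(n_points) == 1, n_points >= 2)
  t <- seq(0, 1, length.out = n_points + 1)[seq_len(n_points)]
  y <- numeric(n_points)
  for (i in 1:3) {
    y <- y + morph$amp[i] * exp(-0.5 * ((t - morph$tau[i]) / morph$width[i])^2)
  }
  y
}

#' Parameters of the synthetic morphology-to-ICP law
#'
#' The simulator's ground truth: window-mean ICP is linear in the P2/P1
#' amplitude ratio and the normalized time-to-peak, plus a patient random
#' intercept and Gaussian window noise. `beta1 > 0` encodes that an elevated
#' P2/P1 ratio accompanies reduced intracranial compliance and higher ICP.
#'
#' Defaults are calibrated so a default cohort yields roughly 5% of 10-s
#' windows at or above 20 mmHg with a sub-20 mean near 9.8 mmHg.
#'
#' @param beta0 Intercept, mmHg.
#' @param beta1 Slope on P2/P1 (mmHg per unit ratio); must be positive.
#' @param beta2 Slope on TTP (mmHg per unit fraction).
#' @param eps_sd SD of the per-window noise, mmHg (nonnegative).
#' @return An object of class `icp_law_params`.
#' @export
icp_law_params <- function(beta0 = -3, beta1 = 11, beta2 = 2, eps_sd = 2) {
  stopifnot(is.numeric(c(beta0, beta1, beta2, eps_sd)))
  if (beta1 <= 0) stop("beta1 must be positive")
  if (eps_sd < 0) stop("eps_sd must be nonnegative")
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, eps_sd = eps_sd),
            class = "icp_law_params")
}

#' Ground-truth window ICP from pulse morphology
#'
#' `beta0 + beta1 * p2p1 + beta2 * ttp + u_patient + eps`, with
#' `eps ~ Normal(0, eps_sd)` drawn from the current RNG stream. Vectorized
#' over `p2p1` and `ttp`.
#'
#' @param p2p1 P2/P1 amplitude ratio(s), positive.
#' @param ttp Normalized time-to-peak in `[0, 1]`.
#' @param law An [icp_law_params()] object.
#' @param u_patient Patient random intercept, mmHg.
#' @return ICP value(s) in mmHg.
#' @export
ground_truth_icp <- function(p2p1, ttp, law = icp_law_params(), u_patient = 0) {
  if (any(p2p1 <= 0)) stop("p2p1 must be positive")
  if (any(ttp < 0 | ttp > 1)) stop("ttp must lie in [0, 1]")
  n <- max(length(p2p1), length(ttp))
  eps <- if (law$eps_sd > 0) stats::rnorm(n, 0, law$eps_sd) else 0
  law$beta0 + law$beta1 * p2p1 + law$beta2 * ttp + u_patient + eps
}

# Normalized time of the template's global maximum, on a fine grid.
template_ttp <- function(morph, n = 2048) {
  y <- simulate_pulse_template(morph, n)
  (which.max(y) - 1) / n
}

#' Per-patient simulation configuration
#'
#' @param patient_id Character identifier.
#' @param heart_rate_bpm Mean heart rate (40-180 bpm).
#' @param heart_rate_sd Beat-to-beat heart-rate SD, bpm.
#' @param resp_freq_hz Respiratory frequency, Hz.
#' @param resp_mod_frac Fractional respiratory amplitude modulation.
#' @param drift_sd Baseline random-walk innovation SD (units/sqrt(s)).
#' @param noise_sd Additive white-noise SD, sensor units.
#' @param artifact_rate_per_min Poisson rate of additive spike artifacts.
#' @param duration_s Recording length, seconds (>= 10).
#' @param morph_drift_ar1_coef AR(1) coefficient of the per-window P2/P1 drift.
#' @param morph_drift_sd Innovation SD of the P2/P1 drift.
#' @param patient_offset_mmHg Patient random intercept added to the ICP law.
#' @param amp_scale Overall pulse amplitude, sensor units (cranial expansions
#'   are fractions of a millimetre).
#' @param fs_hz Sampling rate, Hz.
#' @return An object of class `patient_sim_config`.
#' @export
patient_sim_config <- function(patient_id = "P01",
                               heart_rate_bpm = 75,
                               heart_rate_sd = 2,
                               resp_freq_hz = 0.25,
                               resp_mod_frac = 0.10,
                               drift_sd = 0.02,
                               noise_sd = 0.015,
                               artifact_rate_per_min = 0.5,
                               duration_s = 600,
                               morph_drift_ar1_coef = 0.8,
                               morph_drift_sd = 0.10,
                               patient_offset_mmHg = 0,
                               amp_scale = 0.3,
                               fs_hz = 250) {
  if (duration_s < 10) stop("too short: duration_s must be at least 10 s")
  if (heart_rate_bpm < 40 || heart_rate_bpm > 180) {
    stop("heart_rate_bpm must lie in [40, 180]")
  }
  sds <- c(heart_rate_sd, resp_mod_frac, drift_sd, noise_sd,
           artifact_rate_per_min, morph_drift_sd)
  if (any(sds < 0)) stop("rates and SDs must be nonnegative")
  if (fs_hz <= 0) stop("fs_hz must be positive")
  structure(as.list(environment()), class = "patient_sim_config")
}

#' Simulate one multichannel cranial-expansion recording
#'
#' Concatenates per-beat pulse templates (beat periods follow an AR(1)
#' heart-rate process), applies per-window AR(1) drift of the P2/P1 ratio,
#' respiratory amplitude modulation, a random-walk baseline, additive white
#' noise and Poisson spike artifacts. Coupled channels: `icp_mmHg` is
#' piecewise-constant per 10-s window and follows the ground-truth law from
#' the window's true morphology; `abp_mmHg` is piecewise-constant with window
#' means ~ Normal(90, 10); `fv_cm_s` is a velocity waveform whose window mean
#' is FVm and whose diastolic minimum FVd decreases with ICP
#' (FVd = FVm * (0.55 - 0.01 * (ICP - 10)), clipped to [0.2, 0.9] * FVm).
#'
#' @param cfg A [patient_sim_config()].
#' @param morph_init A [pulse_morph_params()]; its `amp[2]/amp[1]` is the
#'   patient's central P2/P1 ratio.
#' @param law An [icp_law_params()].
#' @param seed Integer seed; the recording is deterministic given it.
#' @return An object of class `raw_recording`: list with `patient_id`,
#'   `fs_hz`, `time_s`, named `channels`, and a `ground_truth` attribute
#'   holding the per-window true morphology and ICP.
#' @export
simulate_recording <- function(cfg, morph_init = pulse_morph_params(),
                               law = icp_law_params(), seed = 1) {
  stopifnot(inherits(cfg, "patient_sim_config"))
  if (cfg$duration_s < 10) stop("too short: duration_s must be at least 10 s")
  set.seed(as.integer(seed))
  fs <- cfg$fs_hz
  n <- round(cfg$duration_s * fs)
  window_s <- 10
  n_win <- floor(cfg$duration_s / window_s)

  # per-window P2/P1 drift: AR(1) around the patient's central ratio
  r0 <- morph_init$amp[2] / morph_init$amp[1]
  phi <- cfg$morph_drift_ar1_coef
  dev <- numeric(n_win)
  if (n_win > 0) {
    innov_sd <- cfg$morph_drift_sd
    dev[1] <- stats::rnorm(1, 0, innov_sd)
    if (n_win > 1) {
      for (w in 2:n_win) dev[w] <- phi * dev[w - 1] + stats::rnorm(1, 0, innov_sd)
    }
  }
  p2p1_w <- pmin(pmax(r0 + dev, 0.4), 2.4)

  win_morphs <- lapply(p2p1_w, function(r) {
    pulse_morph_params(tau = morph_init$tau,
                       amp = c(morph_init$amp[1], morph_init$amp[1] * r,
                               morph_init$amp[3]),
                       width = morph_init$width)
  })
  ttp_w <- vapply(win_morphs, template_ttp, numeric(1))
  icp_w <- ground_truth_icp(p2p1_w, ttp_w, law, cfg$patient_offset_mmHg)

  # coupled hemodynamic window values
  abp_w <- stats::rnorm(n_win, 90, 10)
  fvm_w <- stats::rnorm(n_win, 60, 8)
  ratio_w <- pmin(pmax(0.55 - 0.01 * (icp_w - 10), 0.2), 0.9)
  fvd_w <- fvm_w * ratio_w

  # beat-by-beat synthesis
  sig <- numeric(n)
  onset_times <- numeric(0)
  t_cur <- 0
  hr_dev <- 0
  while (t_cur < cfg$duration_s) {
    hr_dev <- 0.9 * hr_dev + stats::rnorm(1, 0, cfg$heart_rate_sd)
    hr <- min(max(cfg$heart_rate_bpm + hr_dev, 40), 180)
    period <- 60 / hr
    nb <- max(round(period * fs), 4)
    w_idx <- min(floor(t_cur / window_s) + 1, max(n_win, 1))
    morph <- if (n_win > 0) win_morphs[[w_idx]] else morph_init
    beat <- simulate_pulse_template(morph, nb) * cfg$amp_scale
    i0 <- round(t_cur * fs) + 1
    i1 <- min(i0 + nb - 1, n)
    if (i1 >= i0) sig[i0:i1] <- beat[seq_len(i1 - i0 + 1)]
    onset_times <- c(onset_times, t_cur)
    t_cur <- t_cur + nb / fs
  }

  tt <- (seq_len(n) - 1) / fs
  sig <- sig * (1 + cfg$resp_mod_frac * sin(2 * pi * cfg$resp_freq_hz * tt))
  sig <- sig + cumsum(stats::rnorm(n, 0, cfg$drift_sd / sqrt(fs)))
  sig <- sig + stats::rnorm(n, 0, cfg$noise_sd)

  # additive spike artifacts: 3-10x beat amplitude, 0.1-0.5 s
  n_art <- stats::rpois(1, cfg$artifact_rate_per_min * cfg$duration_s / 60)
  art_idx <- integer(0)
  if (n_art > 0) {
    for (a in seq_len(n_art)) {
      t_a <- stats::runif(1, 0, cfg$duration_s)
      dur_a <- stats::runif(1, 0.1, 0.5)
      amp_a <- sample(c(-1, 1), 1) * stats::runif(1, 3, 10) * cfg$amp_scale
      ia <- round(t_a * fs):round((t_a + dur_a) * fs)
      ia <- ia[ia >= 1 & ia <= n]
      if (length(ia) > 1) {
        shape <- exp(-0.5 * ((seq_along(ia) - length(ia) / 2) /
                               (length(ia) / 4))^2)
        sig[ia] <- sig[ia] + amp_a * shape
        art_idx <- c(art_idx, ia)
      }
    }
  }

  expand_windows <- function(v) {
    out <- rep(v[max(length(v), 1)], n)
    if (n_win > 0) {
      for (w in seq_len(n_win)) {
        i0 <- round((w - 1) * window_s * fs) + 1
        i1 <- if (w == n_win) n else round(w * window_s * fs)
        out[i0:i1] <- v[w]
      }
    }
    out
  }
  icp_ch <- expand_windows(icp_w)
  abp_ch <- expand_windows(abp_w)
  fvm_ch <- expand_windows(fvm_w)
  fvd_ch <- expand_windows(fvd_w)
  # velocity waveform: mean FVm, diastolic minimum FVd, cardiac-gated
  fv_ch <- fvd_ch + (fvm_ch - fvd_ch) *
    (1 - cos(2 * pi * (cfg$heart_rate_bpm / 60) * tt))

  gt <- data.frame(window = seq_len(n_win), p2p1 = p2p1_w, ttp = ttp_w,
                   icp_mmHg = icp_w, abp_mmHg = abp_w, fvm_cm_s = fvm_w,
                   fvd_cm_s = fvd_w)
  rec <- structure(
    list(patient_id = cfg$patient_id, fs_hz = fs, time_s = tt,
         channels = list(cranial_expansion = sig, icp_mmHg = icp_ch,
                         abp_mmHg = abp_ch, fv_cm_s = fv_ch),
         n_samples = n),
    class = "raw_recording")
  attr(rec, "ground_truth") <- gt
  attr(rec, "onset_times") <- onset_times
  attr(rec, "artifact_idx") <- unique(art_idx)
  rec
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: patient %s, %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, x$n_samples, x$fs_hz, x$n_samples / x$fs_hz))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Cohort-level simulation configuration
#'
#' Distributions from which per-patient parameters are drawn. Defaults are
#' calibrated so that around 5% of 10-s windows exceed 20 mmHg and the
#' sub-20 mmHg windows average near 9.8 mmHg.
#'
#' @param duration_s Per-patient recording length, seconds.
#' @param fs_hz Sampling rate, Hz.
#' @param law An [icp_law_params()].
#' @param patient_offset_sd SD of the patient random intercept, mmHg.
#' @param p2p1_mean,p2p1_sd,p2p1_range Truncated-normal distribution of the
#'   patient-level central P2/P1 ratio.
#' @param hr_range Uniform range of patient mean heart rate, bpm.
#' @param artifact_rate_per_min Spike-artifact rate passed to each patient.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(duration_s = 600, fs_hz = 250,
                          law = icp_law_params(),
                          patient_offset_sd = 1.5,
                          p2p1_mean = 1.0, p2p1_sd = 0.55,
                          p2p1_range = c(0.5, 2.2),
                          hr_range = c(55, 95),
                          artifact_rate_per_min = 0.5) {
  structure(as.list(environment()), class = "cohort_config")
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Draw per-patient configurations for a cohort
#'
#' Deterministic given the master seed: patient seeds and parameter draws are
#' derived from it, so the same seed reproduces the same cohort.
#'
#' @param n_patients Number of patients (>= 2).
#' @param cohort A [cohort_config()].
#' @param seed Master integer seed.
#' @return List with one element per patient: `cfg` ([patient_sim_config()]),
#'   `morph` ([pulse_morph_params()]) and `seed`.
#' @export
cohort_patient_configs <- function(n_patients, cohort = cohort_config(),
                                   seed = 1) {
  if (n_patients < 2) stop("n_patients must be at least 2")
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1, n_patients)
  lapply(seq_len(n_patients), function(i) {
    pid <- sprintf("P%03d", i)
    hr <- stats::runif(1, cohort$hr_range[1], cohort$hr_range[2])
    r <- rtruncnorm1(cohort$p2p1_mean, cohort$p2p1_sd,
                     cohort$p2p1_range[1], cohort$p2p1_range[2])
    u <- stats::rnorm(1, 0, cohort$patient_offset_sd)
    cfg <- patient_sim_config(
      patient_id = pid, heart_rate_bpm = hr,
      duration_s = cohort$duration_s, fs_hz = cohort$fs_hz,
      artifact_rate_per_min = cohort$artifact_rate_per_min,
      patient_offset_mmHg = u)
    morph <- pulse_morph_params(amp = c(1.0, r, 0.55))
    list(cfg = cfg, morph = morph, seed = seeds[i])
  })
}

#' Simulate a cohort to disk
#'
#' Writes one delimited text file per patient (`time_s` plus one column per
#' channel) and a `manifest.json` mapping patients to files, sampling rates
#' and the ground-truth law parameters.
#'
#' @param n_patients Number of patients (>= 2).
#' @param out_dir Output directory (created if needed).
#' @param cohort A [cohort_config()].
#' @param seed Master integer seed.
#' @return Invisibly, the manifest as a list.
#' @export
simulate_cohort <- function(n_patients, out_dir, cohort = cohort_config(),
                            seed = 1) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  pats <- cohort_patient_configs(n_patients, cohort, seed)
  entries <- lapply(pats, function(p) {
    rec <- simulate_recording(p$cfg, p$morph, cohort$law, p$seed)
    path <- file.path(out_dir, paste0(p$cfg$patient_id, ".csv"))
    write_timeseries(rec, path)
    list(patient_id = p$cfg$patient_id, file = basename(path),
         fs_hz = cohort$fs_hz)
  })
  manifest <- list(
    seed = seed, fs_hz = cohort$fs_hz,
    law = unclass(cohort$law),
    patients = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
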