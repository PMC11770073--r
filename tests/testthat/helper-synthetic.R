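# Shared fixtures: all synthetic, generated in code at test time.

# One clean 10-s (or longer) recording with controllable P2/P1 and minimal
# nuisance processes; returns the raw_recording.
clean_recording <- function(p2p1 = 1.1, duration_s = 20, seed = 7,
                            hr_bpm = 75, noise_sd = 0.015, ...) {
  cfg <- patient_sim_config(duration_s = duration_s, heart_rate_bpm = hr_bpm,
                            artifact_rate_per_min = 0, morph_drift_sd = 0,
                            noise_sd = noise_sd, ...)
  simulate_recording(cfg, pulse_morph_params(amp = c(1, p2p1, 0.55)),
                     icp_law_params(), seed = seed)
}

# Run the curation chain on the first window of a recording; returns the
# pieces needed by most tests.
curate_first_window <- function(rec) {
  w <- segment_windows(rec)[[1]]
  pre <- preprocess_signal(w$samples, w$fs_hz)
  qc0 <- quality_gate(pre, w$fs_hz)
  beats <- extract_beats(pre, w$fs_hz, qc0$f0_hz)
  pulse <- average_pulse(beats)
  qc <- quality_gate(pre, w$fs_hz, mean_pulse = pulse)
  list(window = w, pre = pre, qc = qc, beats = beats, pulse = pulse)
}

# Mean pulses over a generator P2/P1 sweep, extracted through the full
# curation chain; returns generator and extracted parameters per window.
sweep_extraction <- function(ratios, seed = 7, duration_s = 20) {
  out <- lapply(seq_along(ratios), function(i) {
    rec <- clean_recording(p2p1 = ratios[i], duration_s = duration_s,
                           seed = seed + i)
    cur <- curate_first_window(rec)
    lm <- detect_landmarks(cur$pulse)
    pp <- pulse_parameters(cur$pulse, lm)
    data.frame(gen_p2p1 = ratios[i], est_p2p1 = pp$p2p1_ratio,
               ttp = pp$ttp, auc = pp$auc)
  })
  do.call(rbind, out)
}

# Synthetic mean-pulse matrix lying on a 1-parameter family (P2/P1 sweep),
# bypassing the curation chain; for embedding tests.
sweep_pulse_matrix <- function(ratios, L = 100) {
  t(vapply(ratios, function(r) {
    y <- simulate_pulse_template(pulse_morph_params(amp = c(1, r, 0.55)), L)
    y - y[1]
  }, numeric(L)))
}

# Small feature table + aligned pulse matrix for estimator tests: ICP is a
# known monotone function of p2p1 plus noise; several patients.
toy_training_set <- function(n_patients = 6, windows_per_patient = 40,
                             seed = 42, u_sd = 0, eps_sd = 1,
                             r_range = c(0.6, 1.8)) {
  set.seed(seed)
  rows <- list()
  pulses <- list()
  k <- 0
  for (p in seq_len(n_patients)) {
    r_pat <- runif(1, r_range[1], r_range[2])
    u <- rnorm(1, 0, u_sd)
    for (w in seq_len(windows_per_patient)) {
      k <- k + 1
      r <- min(max(r_pat + rnorm(1, 0, 0.15), 0.45), 2.3)
      icp <- ground_truth_icp(r, 0.4, icp_law_params(eps_sd = eps_sd), u)
      rows[[k]] <- data.frame(
        window_id = sprintf("P%02d_w%03d", p, w),
        patient_id = sprintf("P%02d", p),
        reference_icp_mmHg = icp,
        p2p1 = r + rnorm(1, 0, 0.02),
        ttp = ifelse(r > 1, 0.4, 0.15) + rnorm(1, 0, 0.01),
        auc = 0.4 + 0.05 * r + rnorm(1, 0, 0.01),
        noise1 = rnorm(1), noise2 = rnorm(1),
        stringsAsFactors = FALSE)
      y <- simulate_pulse_template(pulse_morph_params(amp = c(1, r, 0.55)), 100)
      pulses[[k]] <- y - y[1] + rnorm(100, 0, 0.005)
    }
  }
  list(features = do.call(rbind, rows), pulses = do.call(rbind, pulses))
}

# Printed per-fold cross-validation errors (train MAE, test MAE, train MSE,
# test MSE) from the published fold table, used as fixed numeric input.
published_fold_table <- function() {
  data.frame(
    fold = 1:10,
    train_mae = c(0.92, 0.89, 0.90, 0.91, 0.90, 0.91, 0.91, 0.91, 0.91, 0.92),
    test_mae = c(1.24, 1.21, 1.25, 1.25, 1.21, 1.20, 1.25, 1.28, 1.21, 1.23),
    train_mse = c(1.95, 1.82, 1.81, 1.83, 1.83, 1.88, 1.93, 1.90, 1.90, 1.91),
    test_mse = c(3.39, 3.98, 4.12, 4.03, 3.09, 3.63, 3.51, 3.84, 3.87, 3.33))
}

# Published per-patient validation summary (patient, MAE, mean ICP, mean
# eICP, difference), used as fixed numeric input.
published_patient_table <- function() {
  data.frame(
    patient = 1:20,
    mae = c(4.27, 2.06, 3.76, 4.55, 3.5, 3.55, 2.36, 2.11, 1.92, 4.18,
            4.06, 2.39, 5.77, 3.22, 3.79, 0.79, 3.52, 2.42, 4.79, 3.4),
    icp = c(11.4, 11.62, 14.72, 18.25, 11.32, 17.66, 14.34, 7.8, 13.06,
            8.68, 18.23, 7.52, 11.85, 15.73, 11.86, 12.02, 7.66, 11.07,
            14.45, 14.13),
    eicp = c(11.85, 9.74, 10.96, 13.7, 14.18, 16.44, 14.58, 7.95, 11.77,
             12.83, 15.32, 7.07, 13.47, 12.53, 8.26, 11.73, 6.5, 10.18,
             9.73, 10.85),
    diff = c(0.45, -1.88, -3.76, -4.55, 2.86, -1.22, 0.24, 0.15, -1.29,
             4.15, -2.91, -0.45, 1.62, -3.2, -3.6, -0.29, -1.16, -0.89,
             -4.72, -3.28))
}

# Published TCD-baseline comparison rows (patient, ICP, eICP, eICP_TCD and
# the two error columns), used as fixed numeric input.
published_tcd_table <- function() {
  data.frame(
    patient = c(1, 2, 3, 5, 6, 11, 12, 14, 16, 17, 18, 19, 20),
    icp = c(11.40, 11.62, 14.72, 11.32, 17.66, 18.23, 7.52, 15.73, 12.02,
            7.66, 11.07, 14.45, 14.13),
    eicp = c(11.85, 9.74, 10.96, 14.18, 16.44, 15.32, 7.07, 12.53, 11.73,
             6.50, 10.18, 9.73, 10.85),
    eicp_tcd = c(-8.83, -2.67, -10.04, -6.67, -8.65, -7.28, -7.15, -7.40,
                 -2.03, -3.36, -1.03, 2.63, -3.04),
    eicp_error = c(0.45, -1.88, -3.76, 2.86, -1.22, -2.91, -0.45, -3.20,
                   -0.29, -1.16, -0.89, -4.72, -3.28),
    eicp_tcd_error = c(-20.23, -14.29, -24.76, -17.99, -26.31, -25.51,
                       -14.67, -23.13, -14.05, -11.02, -12.10, -11.82,
                       -17.17))
}
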