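test_that("windows are consecutive, non-overlapping, with mean reference ICP", {
  rec <- clean_recording(duration_s = 60, seed = 2)
  wins <- segment_windows(rec)
  expect_length(wins, 6)
  expect_true(all(vapply(wins, function(w) length(w$samples), integer(1))
                  == 2500))

  # trailing partial window is dropped
  rec95 <- clean_recording(duration_s = 95, seed = 2)
  expect_length(segment_windows(rec95), 9)

  # constant ICP channel propagates exactly
  rec$channels$icp_mmHg <- rep(12, rec$n_samples)
  wins12 <- segment_windows(rec)
  expect_true(all(vapply(wins12, `[[`, numeric(1), "reference_icp_mmHg") == 12))

  short <- clean_recording(duration_s = 10, seed = 2)
  short$n_samples <- 2000
  short$channels <- lapply(short$channels, `[`, 1:2000)
  expect_error(segment_windows(short), "too short")
})

test_that("preprocessing removes trends and restores polarity", {
  rec <- clean_recording(duration_s = 20, seed = 13)
  x <- rec$channels$cranial_expansion
  fs <- 250
  tt <- (seq_along(x) - 1) / fs

  y <- preprocess_signal(x + 5 * tt, fs)
  core <- seq(2 * fs, length(y) - 2 * fs)  # central span, away from filter edges
  expect_lt(abs(mean(y[core])), 0.05)
  expect_lt(abs(coef(lm(y[core] ~ tt[core]))[2]), 0.01)  # residual slope ~ 0

  # a negated pulse train is re-inverted: fast limb precedes the peak again
  y_inv <- preprocess_signal(-x, fs)
  f0 <- fundamental_frequency(estimate_psd(y_inv, fs))
  frac <- icpflow:::upstroke_fraction(y_inv, fs, f0)
  expect_lt(frac, 0.5)

  expect_error(preprocess_signal(numeric(0), fs), "degenerate")
})

test_that("beat extraction counts beats and rejects injected artifacts", {
  rec <- clean_recording(duration_s = 10, hr_bpm = 60, heart_rate_sd = 0,
                         seed = 3)
  cur <- curate_first_window(rec)
  expect_gte(length(cur$beats$beats) + 1, 9)   # 10 +/- 1 onsets
  expect_lte(length(cur$beats$beats) + 1, 11)

  # onsets always spaced >= 0.5 / f0
  spacing <- diff(cur$beats$onset_indices) / 250
  expect_true(all(spacing >= 0.5 / cur$qc$f0_hz))

  # inject two large spike artifacts: contaminated beats are rejected while
  # most beats survive
  x <- cur$pre
  for (at in c(2.3, 6.3)) {
    idx <- round(at * 250):round((at + 0.15) * 250)
    x[idx] <- x[idx] + 8 * max(abs(cur$pre)) *
      exp(-0.5 * ((seq_along(idx) - length(idx) / 2) / (length(idx) / 4))^2)
  }
  b2 <- extract_beats(x, 250, cur$qc$f0_hz)
  expect_equal(b2$n_rejected, 2)  # one beat per injected artifact
  expect_gte(length(b2$beats), length(cur$beats$beats) - 2)

  expect_error(extract_beats(rep(0, 2500), 250, 1.2), "insufficient beats")
})

test_that("pulse averaging reproduces identical beats and reduces noise", {
  rec <- clean_recording(duration_s = 20, seed = 4)
  cur <- curate_first_window(rec)
  mp <- average_pulse(cur$beats)
  expect_length(mp$values, 100)
  expect_equal(mp$values[1], 0)

  # N identical beats: mean pulse equals any single resampled beat
  tpl <- simulate_pulse_template(pulse_morph_params(), 200)
  beats <- structure(list(beats = rep(list(tpl), 5),
                          onset_indices = seq(1, 1000, by = 200)[1:5],
                          durations_s = rep(0.8, 5),
                          p2p_amplitudes = rep(max(tpl) - min(tpl), 5),
                          n_rejected = 0L, fs_hz = 250),
                     class = "beat_set")
  mp_id <- average_pulse(beats)
  one <- icpflow:::resample_beat(tpl, 100)
  expect_equal(mp_id$values, one - one[1], tolerance = 1e-12)

  # i.i.d. noise of sd sigma on each of N beats: residual sd ~ sigma/sqrt(N)
  set.seed(8)
  sigma <- 0.05
  N <- 25
  noisy <- lapply(seq_len(N), function(i) tpl + rnorm(200, 0, sigma))
  beats_n <- structure(list(beats = noisy,
                            onset_indices = seq_len(N) * 200,
                            durations_s = rep(0.8, N),
                            p2p_amplitudes = vapply(noisy, function(b)
                              max(b) - min(b), numeric(1)),
                            n_rejected = 0L, fs_hz = 250),
                       class = "beat_set")
  mp_n <- average_pulse(beats_n)
  resid <- mp_n$values - (one - one[1])
  # onset-value subtraction recentres each beat; compare sd of residual
  expect_equal(sd(resid), sigma / sqrt(N), tolerance = 0.5)

  beats$beats <- beats$beats[1:2]
  expect_error(average_pulse(beats), "insufficient beats")
})

test_that("landmark detection finds P1/P2/P3 and shoulder morphologies", {
  # three separated bumps with amplitudes (1.0, 1.2, 0.8)
  y <- simulate_pulse_template(
    pulse_morph_params(tau = c(0.18, 0.45, 0.72), amp = c(1, 1.2, 0.8),
                       width = c(0.05, 0.05, 0.05)), 100)
  mp <- structure(list(values = y - y[1], n_beats_averaged = 10L,
                       amplitude = max(y) - y[1]), class = "mean_pulse")
  lm <- detect_landmarks(mp)
  expect_true(lm$p3_present)
  expect_equal(lm$a_p2 / lm$a_p1, 1.2, tolerance = 0.05)
  expect_lt(lm$t_p1, lm$t_p2)
  expect_lt(lm$t_p2, lm$t_p3)

  # merged P1-P2: single maximum with a shoulder still yields both
  y2 <- simulate_pulse_template(
    pulse_morph_params(tau = c(0.22, 0.42, 0.8), amp = c(0.85, 1.0, 0),
                       width = c(0.10, 0.10, 0.05)), 100)
  mp2 <- structure(list(values = y2 - y2[1], n_beats_averaged = 10L,
                        amplitude = max(y2) - y2[1]), class = "mean_pulse")
  lm2 <- detect_landmarks(mp2)
  expect_lt(lm2$t_p1, lm2$t_p2)

  # strictly increasing ramp: no P1 candidate
  ramp <- structure(list(values = seq(0, 1, length.out = 100),
                         n_beats_averaged = 10L, amplitude = 1),
                    class = "mean_pulse")
  expect_error(detect_landmarks(ramp), "landmark failure")
})

test_that("pulse parameters follow their geometric definitions", {
  # global max at 30% of duration
  y <- simulate_pulse_template(
    pulse_morph_params(tau = c(0.30, 0.55, 0.8), amp = c(1, 0.5, 0.3),
                       width = c(0.05, 0.05, 0.05)), 100)
  mp <- structure(list(values = y - y[1], n_beats_averaged = 5L,
                       amplitude = max(y)), class = "mean_pulse")
  pp <- pulse_parameters(mp, detect_landmarks(mp))
  expect_equal(pp$ttp, 0.30, tolerance = 0.02)

  # symmetric unit triangle over the full window: normalized area 0.5
  tri <- c(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50))
  mp_tri <- structure(list(values = tri, n_beats_averaged = 5L,
                           amplitude = 1), class = "mean_pulse")
  lm_tri <- structure(list(t_p1 = 0.4, t_p2 = 0.6, t_p3 = NA, a_p1 = 1,
                           a_p2 = 0.9, a_p3 = NA, p3_present = FALSE),
                      class = "pulse_landmarks")
  expect_equal(pulse_parameters(mp_tri, lm_tri)$auc, 0.5, tolerance = 0.02)

  # compliance-scale binning on the P2/P1 ratio
  mk <- function(r) {
    lm <- lm_tri
    lm$a_p2 <- r
    pulse_parameters(mp_tri, lm)$icc_class
  }
  expect_equal(mk(0.8), 1L)
  expect_equal(mk(1.1), 2L)
  expect_equal(mk(1.3), 3L)
})

test_that("morphological parameters are invariant to amplitude scaling", {
  rec <- clean_recording(duration_s = 20, seed = 17)
  cur <- curate_first_window(rec)
  pp1 <- pulse_parameters(cur$pulse, detect_landmarks(cur$pulse))

  pre_scaled <- cur$pre * 3.7
  qc <- quality_gate(pre_scaled, 250)
  beats <- extract_beats(pre_scaled, 250, qc$f0_hz)
  mp <- average_pulse(beats)
  pp2 <- pulse_parameters(mp, detect_landmarks(mp))
  expect_equal(pp2$p2p1_ratio, pp1$p2p1_ratio, tolerance = 1e-6)
  expect_equal(pp2$ttp, pp1$ttp, tolerance = 1e-6)
  expect_equal(pp2$auc, pp1$auc, tolerance = 1e-6)
  expect_equal(mp$amplitude, 3.7 * cur$pulse$amplitude, tolerance = 1e-6)
})

test_that("window accounting is conserved with no silent drops", {
  pats <- cohort_patient_configs(3, cohort_config(duration_s = 60), seed = 6)
  proc <- process_cohort(pats, icp_law_params())
  expect_equal(sum(proc$accounting), 3 * 6)
  expect_equal(nrow(proc$qc), 3 * 6)
  expect_equal(sum(proc$qc$accepted), proc$accounting[["accepted"]])
  expect_equal(nrow(proc$features), proc$accounting[["accepted"]])
})

test_that("extracted P2/P1 tracks the generator over a sweep", {
  sw <- sweep_extraction(seq(0.6, 1.6, by = 0.1), seed = 50)
  rho <- cor(sw$gen_p2p1, sw$est_p2p1, method = "spearman")
  expect_gte(rho, 0.9)
  expect_lte(mean(abs(sw$est_p2p1 - sw$gen_p2p1)), 0.06)
})
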