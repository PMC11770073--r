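---
title: "Methods: noninvasive ICP estimation from cranial-expansion waveforms"
author: "icpflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noninvasive ICP estimation from cranial-expansion waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The estimation problem

Intracranial pressure (ICP) is normally measured invasively. A skin-coupled
cranial extensometer instead records micrometric pulsatile skull expansions
each cardiac cycle — a noninvasive ICP waveform (nICPW) whose beat
morphology tracks intracranial compliance: as compliance falls, the P2
(tidal) wave rises relative to the P1 (percussion) wave and the pulse peak
shifts later (longer time-to-peak, TTP). `icpflow` estimates the mean ICP
of each 10-s window from that morphology alone. No arterial-pressure or
Doppler signal enters the estimator; those channels exist only to drive the
transcranial-Doppler (TCD) comparator.

This vignette records the model, its assumptions, the tunable parameters
and the design decisions taken where the problem left genuine freedom.

# Signal-quality model

Windows are gated in two stages before any feature is computed.

**Spectral SNR.** The power spectral density of the detrended window is
estimated by Welch's method — Hann window, 4-s segments, 50 % overlap —
giving 0.25 Hz resolution on a 10-s window; these Welch parameters are a
package choice, selected so that the 0.3 Hz half-width harmonic bands are
resolvable. The SNR is the fraction of 0.1–25 Hz power lying within
`k f0 ± 0.3` Hz for `k = 1..4`, where `f0` is the cardiac fundamental
(spectral argmax in 0.5–3 Hz). "Fundamental plus first three harmonics" is
read as four bands; a three-band variant is available via `n_harmonics`.
The half-width 0.3 Hz absorbs heart-rate drift over the window yet keeps
bands disjoint for `f0 ≥ 0.6` Hz; overlapping bands are merged before
integration so no energy is counted twice. Band power is a Riemann sum
(`psd · df`) over bins inside the band — the discrete integral consistent
with the Parseval normalization of the PSD, and exact for line spectra
where a trapezoid on the bin grid loses the half-bin mass at band edges.
The gate is `SNR > 0.35`.

**Morphology.** The averaged pulse must resemble a physiological triphasic
beat. The original system used a proprietary classifier trained on many
thousands of hand-labelled pulses; that training set does not exist here,
so the stage is an explicitly labelled stand-in with the same
accept/reject contract: Pearson correlation of the 100-point mean pulse
against a bank of canonical triphasic templates with P2/P1 in
{0.7, 1.0, 1.4, 2.0}, maximized over ±10-point circular onset lags, must
reach 0.8, and the pulse onset must lie below its maximum. The bank and the
lag search exist because a single P1-dominant template systematically
rejects elevated-P2/P1 (that is, high-ICP) windows and small
foot-detection offsets otherwise dominate the score — both would bias the
accepted cohort. Flat or non-finite windows are rejected with a
`degenerate` flag rather than an error.

# Pulse curation

The curation chain per window: zero-phase 2nd-order Butterworth band-pass
0.3–20 Hz; polarity verification; beat identification; artifact removal;
alignment; averaging.

*Polarity.* The systolic upstroke must be the fast limb of the beat. The
median fractional position of the intra-beat maximum is computed over
detected beats; if it exceeds 0.5 the signal is negated. The statistic is
computed with the same envelope/foot machinery as beat detection — raw peak
picking is unstable when P1 ≈ P2.

*Beat identification.* Beat complexes are located on a moving-average
envelope (kernel 0.3/f0) with a 0.7/f0 refractory period, so a prominent P2
is never split off as its own beat; each onset is then refined to the pulse
foot: the last sample before the systolic peak still within 5 % of the
upstroke amplitude above the segment minimum. This is robust to the flat
diastolic tail, where a plain argmin jitters.

*Artifact removal.* A beat is rejected if its duration leaves
`[0.5, 1.8]/f0`, its peak-to-peak amplitude leaves the window median
± 3·MAD, or its correlation with the running point-wise-median template
falls below 0.7 (two passes). These cutoffs are package choices, validated
in the tests by injecting labelled spike artifacts into clean simulations:
each artifact removes exactly its own beat. Windows with fewer than three
surviving beats are excluded as `insufficient_beats`.

*Alignment and averaging.* Beats are linearly resampled to L = 100 points
(fixed so the embedding input dimension is constant), onset value
subtracted, aligned to the median template at their best circular lag
(± 8 points), and averaged point-wise. Alignment matters: foot jitter on
the steep upstroke otherwise smears the narrow P1 bump and biases P2/P1
upward by up to 0.1.

*Landmarks.* The mean pulse is smoothed (Savitzky–Golay, window 11, order
3). Candidates are local maxima; if fewer than two exist, shoulder
candidates are added at local minima of the second derivative (regions of
strongest concavity, with a small threshold guarding against numerical
noise on ramps). P1 is the earliest candidate at t ≤ 0.45, P2 the next at
t ≤ 0.7, P3 optionally the first after P2. The region boundaries come from
standard ICP-pulse phenomenology and are configurable arguments. Amplitudes
are measured above the minimum of the smoothed pulse — using the onset
sample instead would inherit the 5 % foot threshold as a systematic
baseline error. TTP is the fractional time of the global maximum (onset 0,
end 1): normalizing by pulse duration makes it heart-rate invariant.
Windows with no P1 or no P2 candidate are excluded as `landmark_failure`.
Every window ends in exactly one of `accepted`, `rejected_quality`,
`insufficient_beats` or `landmark_failure`; the accounting is asserted in
the tests.

# Feature bank and embedding

Per accepted window: eleven landmark features (P2/P1, P3/P1, P3/P2, t_P1,
t_P2, TTP, normalized AUC, amplitude, width at 50 % amplitude, maximum
upstroke slope, mean decay slope), seven spectral features (relative
harmonic powers h1–h5, spectral centroid, SNR), seven statistical features
(mean, SD, skewness, kurtosis of the mean pulse; beat-to-beat SD of period
and amplitude; heart rate), and 25 Isomap coordinates of the
amplitude-normalized mean pulse. The original system extracted on the
order of a thousand features; this bank reconstructs every named category
at ~50 features — the pipeline's contracts nowhere depend on the bank's
cardinality.

The Isomap embedding builds a k = 10 nearest-neighbour Euclidean graph
(k chosen as the smallest value that keeps simulated-cohort graphs
connected; a disconnected graph raises an error suggesting a larger k, and
training retries with k doubled), computes geodesic distances by shortest
paths, double-centres the squared distances and eigendecomposes. For
training sets beyond 500 pulses a deterministic evenly spaced subset serves
as landmarks — all-pairs shortest paths over every pulse of a 10-split run
would dominate the pipeline's runtime, and landmark Isomap is standard
practice. Out-of-sample points are embedded by the Nyström rule through
their nearest landmarks; a training landmark reproduces its fitted
coordinates exactly, which the tests assert to 1e-6.

The embedding is fitted inside each training split, never on held-out
patients. Whether the original work fitted its reduction per fold or once
globally is not documented; per-fold is the leakage-safe reading and is
possibly stricter than the original.

**Selection.** Candidates are ranked by |Spearman ρ| with the window's
reference ICP; candidates with |ρ| < 0.05 are dropped as uninformative;
the rest are accepted greedily unless |ρ| ≥ 0.9 with an already-selected
feature; selection stops at 15. The 0.9 and 0.05 cutoffs are package
choices (the selection *rules* are fixed, their numeric cutoffs were not
documented); both are arguments.

# Estimator

A histogram gradient-boosted tree regressor per split: 4000 trees, maximum
depth 15, L2 leaf regularization 0.5 (the "regularization = 0.5" of the
original recipe is read as the L2 leaf-value penalty of histogram gradient
boosting), at most 50 leaves, at least 80 samples per leaf, learning rate
0.005, 255 histogram bins. The implementation stands on `xgboost` with
`tree_method = "hist"` and `grow_policy = "lossguide"`, the closest
equivalent of the histogram gradient boosting family.

**Class weights.** Windows at or above 20 mmHg are rare (≈ 5 %), so each
sample in class c receives `w_c = N / (2 N_c)` — inverse-frequency
weighting normalized so the mean weight is exactly 1 and the effective
sample size is unchanged. With one represented class all weights are 1
with a warning.

**Splits.** The published protocol states both "10-fold cross-validation"
and "80 % training / 20 % testing", which conflict (10-fold implies 90/10).
The implementation satisfies both statements with 10 seeded
patient-level 80/20 shuffles; a strict group-10-fold mode is available via
`split_method = "group_kfold"`. Random shuffles alone leave each patient a
`0.8^10 ≈ 11 %` chance of never being tested, violating the plan's coverage
contract, so splits are drawn by balanced dealing: each split's test set
takes the patients with the fewest test appearances so far, with random
tie-breaks — identical marginal sizes, guaranteed coverage whenever
`n_splits × n_test ≥ P`, and a warning otherwise. Patients never straddle a
split; this is asserted at run time and in the tests.

**Prediction.** Every fold model predicts each window through its own
embedding and feature subset; eICP is the median of the 10 predictions
(mean of the two central order statistics), hence always inside the fold
range and invariant to fold order.

**Grid search.** Optionally, `(n_trees, max_depth)` pairs from
{1000, 2000, 4000} × {5, 10, 15} are scored by mean held-out MAE over the
same splits and the best pair refitted. Scoring on the same folds used for
reporting is the documented reading of the original protocol and is mildly
optimistic; it is off by default.

# TCD baseline

`nCPP = ABP · FVd/FVm + 14 mmHg` and `eICP_TCD = ABP − nCPP`, with FVd and
FVm supplied as window summaries (beat-level Doppler envelope processing is
out of scope). Negative estimates are deliberately not clamped — the
published per-patient comparison prints negative values, so clamping would
falsify the comparator. The identity `eICP_TCD + nCPP = ABP` holds to
machine precision and is asserted over randomized inputs.

# Agreement statistics

Differences are defined as `eICP − ICP` throughout, so per-patient
difference columns reproduce sign conventions exactly. Bland–Altman uses
the sample (n−1) SD and 1.96 for the 95 % limits; both conventional, the
source not having specified. Spearman uses mid-rank ties. NPV/PPV are
computed at the 20 mmHg boundary with zero-denominator cases flagged as
NaN rather than raised. Window-level computation is primary (the published
bias is a window-level quantity); per-patient summaries are a separate
table. All metric implementations are tested against brute-force
recomputation at 1e-12.

# The synthetic cohort: what it is and is not

No generative description of the real device signal exists publicly, so
the simulator is a documented stand-in built from the signal's described
phenomenology.

One beat is the sum of three Gaussian bumps — the simplest form with
independently controllable P1/P2/P3 times and amplitudes (defaults: times
0.15/0.40/0.62 of the period, widths 0.055/0.075/0.080, amplitudes 1.0 /
patient-specific / 0.55, overall scale 0.3 in sensor units, matching
sub-millimetre cranial expansions). Beats are concatenated with an AR(1)
heart-rate process (default 75 ± 2 bpm within [40, 180]), respiratory
amplitude modulation (0.25 Hz, 10 %), a random-walk baseline, white noise,
and Poisson spike artifacts (0.5/min, 3–10× beat amplitude, 0.1–0.5 s —
emulating the movement artifacts that motivate quality gating).

Ground truth: window ICP = `β0 + β1 · P2P1 + β2 · TTP + u_patient + ε`,
linear with a patient random intercept — the minimal identifiable law that
makes parameter recovery a meaningful test, with β1 > 0 anchored to the
direction "elevated P2/P1 means reduced compliance, higher ICP". The ICP
channel is piecewise-constant per window because the pipeline consumes only
window means of the reference. Defaults β0 = −3, β1 = 11 mmHg per unit
ratio, β2 = 2 mmHg per unit TTP, ε ~ N(0, 2 mmHg), u ~ N(0, 1.5 mmHg),
patient-level P2/P1 ~ N(1.0, 0.55) truncated to [0.5, 2.2] with AR(1)
window drift (coefficient 0.8, innovation 0.10): these were calibrated once,
against the law's marginal distribution directly, so that a default cohort
reproduces the clinical class balance this pipeline is designed around —
≈ 5 % of windows at or above 20 mmHg and a sub-20 mean near 9.8 mmHg — and
were not revisited afterwards. The coupled channels follow
`FVd = FVm · (0.55 − 0.01 (ICP − 10))` clipped to [0.2, 0.9]·FVm (an
arbitrary but monotone coupling, sufficient to exercise the TCD formula)
with ABP ~ N(90, 10) and FVm ~ N(60, 8) per window.

What passing tests establish: the chain recovers known morphology (P2/P1
extraction error ≈ 0.02–0.05 over the 0.6–1.6 sweep, rank correlation
≈ 1), the gates reject labelled artifacts without biasing the accepted
morphology distribution, patient separation is leak-proof, and the
ensemble recovers a *learnable* morphology→ICP law on held-out patients to
≈ 2.2 mmHg MAE at 50 patients × 10 min — about the noise floor implied by
the 2 mmHg window noise plus the 1.5 mmHg unlearnable patient intercept.
What they do not establish: performance on real cranial-expansion
recordings. The simulator's pulses are smoother and more stationary than
real signals; its artifact taxonomy is one spike type; its ICP law is
linear by construction. Clinical accuracy claims require clinical data.

# Numerical choices and degenerate inputs

- PSD needs ≥ 4 s of finite samples; shorter or non-finite input raises a
  degenerate-signal error, while the quality gate converts degeneracy into
  a rejection flag.
- Eigenvalues below 1e-12 in the embedding contribute zero coordinates
  (classical MDS convention for negative/null spectrum directions).
- Landmark ties are broken toward the earlier candidate; equal-height
  maxima are resolved by the refractory greedy peak picker (taller first).
- Feature selection treats all-NA correlations (constant candidates) as
  rank 0 against the target and as redundancy 1 against selected features,
  excluding them.
- `compute_class_weights` on a single-class cohort warns and returns unit
  weights rather than failing a whole training run.
- All randomness flows from explicit integer seeds: cohort → patient seeds
  by `sample.int` from the master seed; splits and landmark choice from
  `model_config(seed)`.

# Problem sizes

The test suite runs the full pipeline at 50 patients × 10 min (≈ 3000
windows) for the recovery check — the scale at which patient-level
variability is well sampled — and smaller cohorts (3–12 patients, 1–6 min)
for the mechanical contracts. The worked example in the README uses 500
trees with learning rate 0.05 — a proportionally identical shrinkage
budget to the full 4000 × 0.005 recipe — purely so the example runs in
seconds; `model_config()` defaults remain the full recipe.

# Known limitations

- The morphology quality stage is a template-correlation stand-in, not the
  original trained classifier.
- The compliance scale is an ordinal P2/P1 binning (< 1.0, 1.0–1.2,
  > 1.2); the cited clinical scale's exact definition was not available.
- The feature bank is a ~50-feature reconstruction of the named
  categories, not the original ~1110-feature inventory.
- EDF input is not supported; delimited text plus a JSON manifest is the
  interface.
- Grid-search model selection shares folds with error reporting when
  enabled.
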