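Package: icpflow
Title: Noninvasive Intracranial Pressure Estimation from Cranial
    Expansion Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for estimating mean intracranial pressure
    (ICP) noninvasively from pulsatile cranial-expansion waveforms. Provides
    spectral signal-to-noise quality gating, cardiac pulse curation
    (detrending, beat detection, artifact rejection, alignment, averaging),
    pulse-morphology landmark extraction (P1/P2/P3, P2/P1 ratio,
    time-to-peak, area under the curve), Isomap waveform embeddings with
    out-of-sample extension, Spearman-plus-redundancy feature selection,
    class-weighted patient-separated gradient-boosting regression with
    median-of-folds ensembling, the transcranial-Doppler closed-form
    baseline, Bland-Altman and threshold agreement statistics, and a seeded
    synthetic-cohort simulator with a known morphology-to-ICP law for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    signal,
    igraph,
    xgboost,
    e1071,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
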