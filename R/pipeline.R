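#' Run the curation chain on one 10-s window
#'
#' Preprocess (band-pass, polarity), SNR gate, beat extraction, pulse
#' averaging, morphology gate, landmark detection and parameter extraction.
#'
#' @param win An `icp_window` from [segment_windows()].
#' @param snr_threshold,morph_threshold Quality-gate thresholds.
#' @return List with `status` (one of `accepted`, `rejected_quality`,
#'   `insufficient_beats`, `landmark_failure`), and when accepted: `qc`,
#'   `beats`, `pulse`, `landmarks`, `params`, `features`.
#' @export
process_window <- function(win, snr_threshold = 0.35, morph_threshold = 0.8) {
  stopifnot(inherits(win, "icp_window"))
  pre <- tryCatch(preprocess_signal(win$samples, win$fs_hz),
                  error = function(e) NULL)
  if (is.null(pre)) return(list(status = "rejected_quality", qc = NULL))
  qc0 <- quality_gate(pre, win$fs_hz, snr_threshold = snr_threshold,
                      morph_threshold = morph_threshold)
  if (!qc0$accepted) return(list(status = "rejected_quality", qc = qc0))

  beats <- tryCatch(extract_beats(pre, win$fs_hz, qc0$f0_hz),
                    error = function(e) NULL)
  if (is.null(beats)) return(list(status = "insufficient_beats", qc = qc0))
  pulse <- tryCatch(average_pulse(beats), error = function(e) NULL)
  if (is.null(pulse)) return(list(status = "insufficient_beats", qc = qc0))

  qc <- quality_gate(pre, win$fs_hz, mean_pulse = pulse,
                     snr_threshold = snr_threshold,
                     morph_threshold = morph_threshold)
  if (!qc$accepted) return(list(status = "rejected_quality", qc = qc))

  lm <- tryCatch(detect_landmarks(pulse), error = function(e) NULL)
  if (is.null(lm)) return(list(status = "landmark_failure", qc = qc))
  params <- tryCatch(pulse_parameters(pulse, lm), error = function(e) NULL)
  if (is.null(params)) return(list(status = "landmark_failure", qc = qc))
  attr(params, "landmarks") <- lm

  feats <- tryCatch(build_feature_vector(pulse, params, qc, beats),
                    error = function(e) NULL)
  if (is.null(feats)) return(list(status = "landmark_failure", qc = qc))
  list(status = "accepted", qc = qc, beats = beats, pulse = pulse,
       landmarks = lm, params = params, features = feats)
}

#' Process a full recording into per-window features
#'
#' Segments the recording, runs [process_window()] on every window, and
#' returns the per-window QC table, pulse-parameter table, feature table and
#' mean-pulse matrix for the accepted windows. Window accounting is
#' conserved: every window is counted exactly once across the `accepted`,
#' `rejected_quality`, `insufficient_beats` and `landmark_failure` bins.
#'
#' @param rec A `raw_recording`.
#' @param window_s Window length, seconds (default 10).
#' @param snr_threshold,morph_threshold Quality-gate thresholds.
#' @return List of class `processed_recording`: `features` (data frame),
#'   `pulses` (matrix, rows aligned with `features`), `pulse_table`, `qc`
#'   and `accounting`.
#' @export
process_recording <- function(rec, window_s = 10, snr_threshold = 0.35,
                              morph_threshold = 0.8) {
  wins <- segment_windows(rec, window_s)
  qc_rows <- list()
  pulse_rows <- list()
  feat_rows <- list()
  pulses <- list()
  counts <- c(accepted = 0L, rejected_quality = 0L,
              insufficient_beats = 0L, landmark_failure = 0L)
  for (win in wins) {
    res <- process_window(win, snr_threshold, morph_threshold)
    counts[res$status] <- counts[res$status] + 1L
    qc_rows[[win$window_id]] <- data.frame(
      window_id = win$window_id, patient_id = win$patient_id,
      snr = if (is.null(res$qc)) NA_real_ else res$qc$snr,
      f0_hz = if (is.null(res$qc)) NA_real_ else res$qc$f0_hz,
      morphology_score = if (is.null(res$qc)) NA_real_
                         else res$qc$morphology_score,
      accepted = res$status == "accepted", status = res$status,
      stringsAsFactors = FALSE)
    if (res$status != "accepted") next
    pulse_rows[[win$window_id]] <- data.frame(
      window_id = win$window_id, patient_id = win$patient_id,
      n_beats = res$pulse$n_beats_averaged,
      p2p1 = res$params$p2p1_ratio, ttp = res$params$ttp,
      auc = res$params$auc, icc_class = res$params$icc_class,
      amplitude = res$pulse$amplitude,
      reference_icp_mmHg = win$reference_icp_mmHg,
      stringsAsFactors = FALSE)
    feat_rows[[win$window_id]] <- data.frame(
      window_id = win$window_id, patient_id = win$patient_id,
      reference_icp_mmHg = win$reference_icp_mmHg,
      as.list(res$features), stringsAsFactors = FALSE)
    pulses[[win$window_id]] <- res$pulse$values
  }
  stopifnot(sum(counts) == length(wins))
  structure(list(
    features = if (length(feat_rows)) do.call(rbind, c(feat_rows,
      list(make.row.names = FALSE))) else NULL,
    pulses = if (length(pulses)) do.call(rbind, pulses) else NULL,
    pulse_table = if (length(pulse_rows)) do.call(rbind, c(pulse_rows,
      list(make.row.names = FALSE))) else NULL,
    qc = do.call(rbind, c(qc_rows, list(make.row.names = FALSE))),
    accounting = counts),
    class = "processed_recording")
}

#' Process every patient of a cohort
#'
#' Streams patients one at a time (recordings are loaded or simulated,
#' processed, then released) and concatenates the per-window tables.
#'
#' @param recordings Either a list of `raw_recording` objects, a manifest
#'   list from [read_manifest()], or a list of patient configurations from
#'   [cohort_patient_configs()] (simulated on the fly with `law`).
#' @param law An [icp_law_params()] used when simulating from configurations.
#' @param window_s,snr_threshold,morph_threshold Passed to
#'   [process_recording()].
#' @param target_fs_hz Common sampling rate; inputs at other rates are
#'   resampled first.
#' @return A `processed_recording`-shaped list pooled over patients.
#' @export
process_cohort <- function(recordings, law = icp_law_params(),
                           window_s = 10, snr_threshold = 0.35,
                           morph_threshold = 0.8, target_fs_hz = 250) {
  get_rec <- function(item) {
    if (inherits(item, "raw_recording")) return(item)
    if (!is.null(item$cfg)) {
      return(simulate_recording(item$cfg, item$morph, law, item$seed))
    }
    if (!is.null(item$file)) {
      return(read_timeseries(item$file, patient_id = item$patient_id,
                             expected_fs_hz = item$fs_hz))
    }
    stop("unrecognized cohort item")
  }
  items <- if (!is.null(recordings$patients)) recordings$patients
           else recordings
  parts <- lapply(items, function(item) {
    rec <- get_rec(item)
    rec <- resample_recording(rec, target_fs_hz)
    process_recording(rec, window_s, snr_threshold, morph_threshold)
  })
  feats <- do.call(rbind, Filter(Negate(is.null),
                                 lapply(parts, `[[`, "features")))
  pulses <- do.call(rbind, Filter(Negate(is.null),
                                  lapply(parts, `[[`, "pulses")))
  structure(list(
    features = feats, pulses = pulses,
    pulse_table = do.call(rbind, Filter(Negate(is.null),
                                        lapply(parts, `[[`, "pulse_table"))),
    qc = do.call(rbind, lapply(parts, `[[`, "qc")),
    accounting = Reduce(`+`, lapply(parts, `[[`, "accounting"))),
    class = "processed_recording")
}

#' Persist a trained model bundle
#'
#' Fold models are saved in the booster's native format, embeddings and
#' selections as RDS, and the configuration as a JSON sidecar.
#'
#' @param bundle An `icp_model_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_model_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "icp_model_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(bundle$fold_models)) {
    xgboost::xgb.save(bundle$fold_models[[s]],
                      file.path(dir, sprintf("fold_%02d.ubj", s)))
  }
  side <- bundle[c("fold_features", "base_feature_names", "cv")]
  side$config <- unclass(bundle$config)
  side$config$split_method <- side$config$split_method[1]
  side$format_version <- 1
  jsonlite::write_json(side, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(bundle$fold_embeddings, file.path(dir, "embeddings.rds"))
  saveRDS(bundle[c("splits", "cv_predictions", "fold_selections",
                   "fold_features", "base_feature_names")],
          file.path(dir, "state.rds"))
  invisible(dir)
}

#' Load a model bundle saved by [save_model_bundle()]
#'
#' @param dir Bundle directory.
#' @return An `icp_model_bundle`.
#' @export
load_model_bundle <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^fold_\\d+\\.ubj$",
                           full.names = TRUE))
  models <- lapply(files, xgboost::xgb.load)
  state <- readRDS(file.path(dir, "state.rds"))
  cfg_args <- side$config
  cfg_args$grid <- lapply(cfg_args$grid, as.numeric)
  structure(list(
    fold_models = models,
    fold_features = state$fold_features,
    fold_embeddings = readRDS(file.path(dir, "embeddings.rds")),
    fold_selections = state$fold_selections,
    splits = state$splits, config = do.call(model_config, cfg_args),
    base_feature_names = state$base_feature_names,
    cv = as.data.frame(side$cv),
    cv_predictions = state$cv_predictions),
    class = "icp_model_bundle")
}

stage_log <- function(stage, n_in, n_out, n_rejected = n_in - n_out) {
  message(sprintf("[%s] in=%d out=%d rejected=%d", stage, n_in, n_out,
                  n_rejected))
}

#' Run the end-to-end pipeline
#'
#' Stages: `simulate` (write a synthetic cohort), `qc`/`pulses`/`features`
#' (curation chain over the manifest's recordings; all three tables are
#' produced together), `train` (fit the ensemble), `predict` (held-out
#' cross-validation predictions plus full-cohort predictions),
#' `baseline-tcd` (per-window TCD estimates), `evaluate` (agreement
#' metrics), or `all`. Each stage writes CSV/JSON artifacts into
#' `config$out_dir` and logs input/output/rejected counts. Deterministic
#' given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param command One of `simulate`, `qc`, `pulses`, `features`, `train`,
#'   `predict`, `baseline-tcd`, `evaluate`, `all`.
#' @return Invisibly, a list of the artifacts produced by the stage(s).
#' @export
run_pipeline <- function(config, command = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  cmds <- c("simulate", "qc", "pulses", "features", "train", "predict",
            "baseline-tcd", "evaluate", "all")
  if (!command %in% cmds) {
    stop("unknown command '", command, "'; expected one of: ",
         paste(cmds, collapse = ", "))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()

  do_simulate <- command %in% c("simulate", "all")
  do_features <- command %in% c("qc", "pulses", "features", "all")
  do_train <- command %in% c("train", "all")
  do_predict <- command %in% c("predict", "all")
  do_baseline <- command %in% c("baseline-tcd", "all")
  do_evaluate <- command %in% c("evaluate", "all")

  manifest_path <- config$manifest
  if (do_simulate) {
    sim_dir <- file.path(out, "cohort")
    simulate_cohort(config$n_patients, sim_dir,
                    cohort_config(duration_s = config$duration_s,
                                  fs_hz = config$target_fs_hz),
                    seed = config$seed)
    manifest_path <- file.path(sim_dir, "manifest.json")
    stage_log("simulate", config$n_patients, config$n_patients, 0)
    artifacts$manifest <- manifest_path
  }
  if (is.null(manifest_path)) manifest_path <- file.path(out, "cohort",
                                                         "manifest.json")

  features_csv <- file.path(out, "features.csv")
  pulses_csv <- file.path(out, "pulses.csv")
  pulse_mat_csv <- file.path(out, "mean_pulses.csv")
  qc_csv <- file.path(out, "qc.csv")

  if (do_features) {
    if (!file.exists(manifest_path)) {
      stop("missing upstream artifact: ", manifest_path,
           " (run the 'simulate' command first or point config$manifest ",
           "at an existing cohort)")
    }
    man <- read_manifest(manifest_path)
    proc <- process_cohort(man, window_s = config$window_s,
                           snr_threshold = config$snr_threshold,
                           morph_threshold = config$morph_threshold,
                           target_fs_hz = config$target_fs_hz)
    hdr <- sprintf("# icpflow %s config_seed=%d",
                   as.character(utils::packageVersion("icpflow")),
                   config$seed)
    for (pair in list(list(qc_csv, proc$qc),
                      list(pulses_csv, proc$pulse_table),
                      list(features_csv, proc$features))) {
      writeLines(hdr, pair[[1]])
      suppressWarnings(utils::write.table(
        pair[[2]], pair[[1]], sep = ",", row.names = FALSE, append = TRUE,
        quote = FALSE))
    }
    data.table::fwrite(data.table::as.data.table(proc$pulses), pulse_mat_csv)
    n_in <- sum(proc$accounting)
    stage_log("qc+pulses+features", n_in, proc$accounting[["accepted"]])
    message(sprintf(
      "[accounting] accepted=%d rejected_quality=%d insufficient_beats=%d landmark_failure=%d",
      proc$accounting[["accepted"]], proc$accounting[["rejected_quality"]],
      proc$accounting[["insufficient_beats"]],
      proc$accounting[["landmark_failure"]]))
    artifacts$features <- proc
  }

  read_features <- function() {
    if (!file.exists(features_csv)) {
      stop("missing upstream artifact: ", features_csv,
           " (run the 'features' command first)")
    }
    feats <- utils::read.csv(features_csv, skip = 1)
    pulses <- as.matrix(data.table::fread(pulse_mat_csv))
    list(features = feats, pulses = pulses)
  }

  bundle_dir <- file.path(out, "model")
  if (do_train) {
    fp <- if (!is.null(artifacts$features)) artifacts$features
          else read_features()
    cfg_m <- config$model
    cfg_m$seed <- config$seed
    bundle <- train_ensemble(fp$features, fp$pulses, cfg_m,
                             do_grid_search = config$do_grid_search)
    save_model_bundle(bundle, bundle_dir)
    utils::write.csv(bundle$cv, file.path(out, "cv_folds.csv"),
                     row.names = FALSE)
    stage_log("train", nrow(fp$features), length(bundle$fold_models), 0)
    artifacts$bundle <- bundle
  }

  predictions_csv <- file.path(out, "predictions.csv")
  if (do_predict) {
    fp <- if (!is.null(artifacts$features)) artifacts$features
          else read_features()
    bundle <- if (!is.null(artifacts$bundle)) artifacts$bundle
              else if (dir.exists(bundle_dir)) load_model_bundle(bundle_dir)
              else stop("missing upstream artifact: ", bundle_dir,
                        " (run the 'train' command first)")
    preds <- predict_eicp(bundle, fp$features, fp$pulses)
    utils::write.csv(preds, predictions_csv, row.names = FALSE)
    utils::write.csv(bundle$cv_predictions,
                     file.path(out, "cv_predictions.csv"), row.names = FALSE)
    stage_log("predict", nrow(fp$features), nrow(preds), 0)
    artifacts$predictions <- preds
  }

  baseline_csv <- file.path(out, "baseline_tcd.csv")
  if (do_baseline) {
    if (!file.exists(manifest_path)) {
      stop("missing upstream artifact: ", manifest_path)
    }
    man <- read_manifest(manifest_path)
    rows <- lapply(man$patients, function(p) {
      rec <- read_timeseries(p$file, patient_id = p$patient_id,
                             expected_fs_hz = p$fs_hz)
      wins <- floor(rec$n_samples / (config$window_s * rec$fs_hz))
      do.call(rbind, lapply(seq_len(wins), function(w) {
        i0 <- round((w - 1) * config$window_s * rec$fs_hz) + 1
        i1 <- round(w * config$window_s * rec$fs_hz)
        abp <- mean(rec$channels$abp_mmHg[i0:i1])
        fv <- rec$channels$fv_cm_s[i0:i1]
        fvm <- mean(fv)
        fvd <- min(fv)
        data.frame(window_id = sprintf("%s_w%04d", rec$patient_id, w),
                   patient_id = rec$patient_id, abp = abp, fvd = fvd,
                   fvm = fvm,
                   ncpp = estimate_ncpp(abp, fvd, fvm),
                   eicp_tcd = estimate_eicp_tcd(abp, fvd, fvm),
                   reference_icp_mmHg =
                     mean(rec$channels$icp_mmHg[i0:i1]),
                   stringsAsFactors = FALSE)
      }))
    })
    base_tab <- do.call(rbind, rows)
    utils::write.csv(base_tab, baseline_csv, row.names = FALSE)
    stage_log("baseline-tcd", nrow(base_tab), nrow(base_tab), 0)
    artifacts$baseline <- base_tab
  }

  if (do_evaluate) {
    cvp_csv <- file.path(out, "cv_predictions.csv")
    cvp <- if (!is.null(artifacts$bundle)) artifacts$bundle$cv_predictions
           else if (file.exists(cvp_csv)) utils::read.csv(cvp_csv)
           else stop("missing upstream artifact: ", cvp_csv,
                     " (run the 'predict' command first)")
    rep <- metrics_report(cvp$reference_icp_mmHg, cvp$eicp_mmHg)
    per_pat <- per_patient_summary(cvp)
    jsonlite::write_json(unclass(rep), file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(per_pat, file.path(out, "per_patient.csv"),
                     row.names = FALSE)
    stage_log("evaluate", nrow(cvp), nrow(per_pat), 0)
    artifacts$metrics <- rep
  }
  invisible(artifacts)
}
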