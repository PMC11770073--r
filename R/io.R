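#' Write a recording as delimited text
#'
#' One header row, a `time_s` column and one column per channel, UTF-8 with
#' "." as the decimal separator.
#'
#' @param rec A `raw_recording`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  dt <- data.table::as.data.table(c(list(time_s = rec$time_s), rec$channels))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a delimited time-series recording
#'
#' Expects a header with a `time_s` column plus at least one channel column.
#' The sampling rate is inferred from the median time step, validated for
#' regularity (at most 1% of steps may deviate by more than 1% from the
#' median) and, when given, checked against the manifest rate.
#'
#' @param path Input file path.
#' @param patient_id Patient identifier to attach (default: file stem).
#' @param expected_fs_hz Optional manifest sampling rate to verify, Hz.
#' @return A `raw_recording`.
#' @export
read_timeseries <- function(path, patient_id = NULL, expected_fs_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, data.table = FALSE)
  if (!"time_s" %in% names(dt)) {
    stop("format error: missing 'time_s' column in ", path)
  }
  chans <- setdiff(names(dt), "time_s")
  if (length(chans) < 1) stop("format error: no channel columns in ", path)
  tt <- dt$time_s
  dts <- diff(tt)
  if (any(dts <= 0)) {
    stop("format error: non-monotone time at line(s) ",
         paste(utils::head(which(dts <= 0) + 1, 5), collapse = ", "))
  }
  dt_med <- stats::median(dts)
  irregular <- abs(dts - dt_med) > 0.01 * dt_med
  if (mean(irregular) > 0.01) {
    stop("format error: > 1% irregular sampling; first offending line(s): ",
         paste(utils::head(which(irregular) + 1, 5), collapse = ", "))
  }
  fs <- 1 / dt_med
  if (!is.null(expected_fs_hz) &&
      abs(fs - expected_fs_hz) > 0.01 * expected_fs_hz) {
    stop("sampling-rate mismatch: manifest says ", expected_fs_hz,
         " Hz, inferred ", signif(fs, 6), " Hz")
  }
  if (is.null(patient_id)) {
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  }
  structure(list(patient_id = patient_id, fs_hz = fs, time_s = tt,
                 channels = as.list(dt[chans]), n_samples = nrow(dt)),
            class = "raw_recording")
}

#' Read a cohort manifest
#'
#' @param path Path to `manifest.json`.
#' @return The manifest list; patient file paths are resolved relative to
#'   the manifest's directory.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(path)
  man$patients <- lapply(man$patients, function(p) {
    p$file <- file.path(base, p$file)
    p
  })
  man
}

#' Resample a recording to a target rate
#'
#' Polyphase rate conversion of the waveform channels; piecewise-constant
#' channels are resampled by nearest-time lookup to avoid ringing at steps.
#'
#' @param rec A `raw_recording`.
#' @param target_fs_hz Target sampling rate, Hz (default 250).
#' @return A `raw_recording` at the target rate.
#' @export
resample_recording <- function(rec, target_fs_hz = 250) {
  stopifnot(inherits(rec, "raw_recording"))
  if (abs(rec$fs_hz - target_fs_hz) < 1e-9) return(rec)
  rat <- ratio_integers(target_fs_hz, rec$fs_hz)
  n_new <- floor(rec$n_samples * target_fs_hz / rec$fs_hz)
  tt_new <- (seq_len(n_new) - 1) / target_fs_hz
  stepwise <- c("icp_mmHg", "abp_mmHg")
  channels <- lapply(names(rec$channels), function(nm) {
    x <- rec$channels[[nm]]
    if (nm %in% stepwise) {
      idx <- pmin(floor(tt_new * rec$fs_hz) + 1, length(x))
      x[idx]
    } else {
      y <- as.numeric(signal::resample(x, rat[1], rat[2]))
      y[seq_len(min(n_new, length(y)))]
    }
  })
  names(channels) <- names(rec$channels)
  n_min <- min(vapply(channels, length, integer(1)), n_new)
  channels <- lapply(channels, `[`, seq_len(n_min))
  structure(list(patient_id = rec$patient_id, fs_hz = target_fs_hz,
                 time_s = tt_new[seq_len(n_min)], channels = channels,
                 n_samples = n_min),
            class = "raw_recording")
}

ratio_integers <- function(p, q, max_den = 1000) {
  r <- p / q
  best <- c(round(r * max_den), max_den)
  g <- gcd2(best[1], best[2])
  best / g
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline in one serializable
#' list: the master seed, window length, quality-gate thresholds, model
#' configuration and I/O paths. Round-trips losslessly through YAML or JSON.
#'
#' @param seed Master seed; all randomness flows from it.
#' @param manifest Path to the cohort `manifest.json` (input).
#' @param out_dir Output directory for stage artifacts.
#' @param window_s Window length, seconds.
#' @param target_fs_hz Common sampling rate to which inputs are resampled.
#' @param snr_threshold Spectral SNR gate.
#' @param morph_threshold Template-correlation morphology gate.
#' @param n_patients,duration_s Cohort size for the `simulate` stage.
#' @param model A [model_config()].
#' @param do_grid_search Logical: tune `(n_trees, max_depth)` by grid search.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, manifest = NULL, out_dir = ".",
                            window_s = 10, target_fs_hz = 250,
                            snr_threshold = 0.35, morph_threshold = 0.8,
                            n_patients = 10, duration_s = 600,
                            model = model_config(seed = seed),
                            do_grid_search = FALSE) {
  stopifnot(window_s > 0, target_fs_hz > 0,
            snr_threshold >= 0, snr_threshold <= 1,
            morph_threshold >= -1, morph_threshold <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file (`.yaml`, `.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  model_args <- raw$model
  raw$model <- NULL
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(model_args)) {
    model_args$grid <- lapply(model_args$grid, as.numeric)
    cfg$model <- do.call(model_config, model_args)
  }
  cfg
}

#' Write a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @param path Output file (`.yaml`, `.yml` or `.json`).
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$model <- unclass(x$model)
  x$model$split_method <- x$model$split_method[1]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
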