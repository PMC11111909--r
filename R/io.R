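# Readers, writers, configuration, and the three pipeline entry points.
# CSV dialect: comma-separated, header row, UTF-8, "." decimal separator.

#' Write and read the scored-trial CSV dialect
#'
#' One row per trial with columns `trial_index`, `stimulus_class`,
#' `concentration_vv`, `intensity_kmh`, `outcome`, `latency_s`,
#' `reinforced`, `start_s`, `end_s`.
#'
#' @param trials A scored-trial data frame (`session_result$trials`).
#' @param path File path.
#' @return `write_trials_csv()` returns `path` invisibly;
#'   `read_trials_csv()` the data frame.
#' @export
write_trials_csv <- function(trials, path) {
  cols <- c("trial_index", "stimulus_class", "concentration_vv",
            "intensity_kmh", "outcome", "latency_s", "reinforced",
            "start_s", "end_s")
  missing <- setdiff(cols, names(trials))
  if (length(missing)) {
    stop_bad_arg("trials is missing columns: %s",
                 paste(missing, collapse = ", "))
  }
  write.csv(trials[, cols], path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  cols <- c("trial_index", "stimulus_class", "concentration_vv",
            "intensity_kmh", "outcome", "latency_s", "reinforced",
            "start_s", "end_s")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_bad_arg("%s is missing columns: %s", path,
                 paste(missing, collapse = ", "))
  }
  bad <- which(!df$outcome %in%
                 c("hit", "miss", "false_alert", "correct_rejection"))
  if (length(bad)) {
    stop_bad_arg("%s row %d: unknown outcome '%s'", path, bad[1],
                 df$outcome[bad[1]])
  }
  df
}

#' Write and read the poke-event CSV dialect
#'
#' Columns `trial_index`, `onset_s`, `duration_s` (onsets relative to each
#' trial's odor onset).
#'
#' @param pokes Poke data frame (`session_result$pokes`).
#' @param path File path.
#' @export
write_pokes_csv <- function(pokes, path) {
  write.csv(pokes[, c("trial_index", "onset_s", "duration_s")], path,
            row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pokes_csv
#' @export
read_pokes_csv <- function(path) {
  read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}

#' Write and read the heart-rate CSV dialect
#'
#' Columns `timestamp_s`, `bpm` (1 Hz samples on the session clock).
#'
#' @param hr Heart-rate data frame.
#' @param path File path.
#' @export
write_hr_csv <- function(hr, path) {
  write.csv(hr[, c("timestamp_s", "bpm")], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_hr_csv
#' @export
read_hr_csv <- function(path) {
  read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}

#' Write and read PID trace CSVs
#'
#' Columns `timestamp_s`, `voltage_v`, `valve_on` (0/1).
#'
#' @param trace A [pid_trace()].
#' @param path File path.
#' @export
write_pid_csv <- function(trace, path) {
  stopifnot(inherits(trace, "pid_trace"))
  n <- length(trace$voltage_v)
  df <- data.frame(timestamp_s = (seq_len(n) - 1) / trace$sample_rate_hz,
                   voltage_v = trace$voltage_v,
                   valve_on = as.integer(trace$valve_on))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pid_csv
#' @param sample_rate_hz Sampling rate; inferred from timestamps when `NULL`.
#' @param distance_cm,dilution_vv Metadata attached to the trace.
#' @export
read_pid_csv <- function(path, sample_rate_hz = NULL,
                         distance_cm = NA_real_, dilution_vv = NA_real_) {
  df <- read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  if (!all(c("voltage_v", "valve_on") %in% names(df))) {
    stop_bad_arg("%s must have voltage_v and valve_on columns", path)
  }
  if (is.null(sample_rate_hz)) {
    if (!"timestamp_s" %in% names(df) || nrow(df) < 2) {
      stop_bad_arg("cannot infer sample rate from %s", path)
    }
    sample_rate_hz <- 1 / mean(diff(df$timestamp_s))
  }
  pid_trace(df$voltage_v, df$valve_on == 1, sample_rate_hz,
            distance_cm = distance_cm, dilution_vv = dilution_vv)
}

#' Study configuration
#'
#' Assembles (or reads from YAML) the full configuration of a simulated
#' study: dog-model parameters, trial parameters, and block structure.
#'
#' @param dog A [dog_model()] or list of its arguments.
#' @param params A [trial_params()] or list of its arguments.
#' @param n_blocks,top_concentration,first_order Passed to
#'   [block_sequence()].
#' @param seed Integer seed recorded with the outputs.
#' @return A `study_config` list.
#' @export
study_config <- function(dog = list(), params = list(), n_blocks = 3L,
                         top_concentration = 1e-2,
                         first_order = "8-4-8-4", seed = 1L) {
  if (!inherits(dog, "dog_model")) dog <- do.call(dog_model, dog)
  if (!inherits(params, "trial_params")) params <- do.call(trial_params, params)
  structure(
    list(dog = dog, params = params, n_blocks = as.integer(n_blocks),
         top_concentration = top_concentration, first_order = first_order,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' @rdname study_config
#' @param path YAML file with optional top-level keys `dog`, `params`,
#'   `n_blocks`, `top_concentration`, `first_order`, `seed`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("dog", "params", "n_blocks", "top_concentration",
             "first_order", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop_bad_arg("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(study_config, y)
}

config_hash <- function(config) {
  rlang::hash(list(dog = unclass(config$dog),
                   params = unclass(config$params),
                   n_blocks = config$n_blocks,
                   top_concentration = config$top_concentration,
                   first_order = config$first_order,
                   seed = config$seed))
}

#' Simulate a study and write its dataset directory
#'
#' Runs [generate_study()] under `config` and writes one trials CSV, poke
#' CSV, and heart-rate CSV per session plus `manifest.json` recording the
#' seed, per-session seeds, configuration hash, and stopping outcome.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return The `study` object, invisibly, with attribute `manifest`.
#' @export
simulate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  blocks <- block_sequence(config$n_blocks, config$top_concentration,
                           config$first_order)
  st <- generate_study(config$dog, blocks, seed = config$seed,
                       params = config$params)
  files <- lapply(seq_along(st$sessions), function(i) {
    sr <- st$sessions[[i]]
    base <- sprintf("session_%02d", i)
    write_trials_csv(sr$trials, file.path(out_dir, paste0(base, ".csv")))
    write_pokes_csv(sr$pokes, file.path(out_dir, paste0(base, "_pokes.csv")))
    write_hr_csv(st$hr[[i]], file.path(out_dir, paste0(base, "_hr.csv")))
    list(session = i, block_index = sr$block_index,
         intensity_kmh = sr$intensity, seed = sr$seed,
         trials = paste0(base, ".csv"), pokes = paste0(base, "_pokes.csv"),
         hr = paste0(base, "_hr.csv"))
  })
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stopped_after_block = st$stopped_after_block,
                   sessions = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(st, "manifest") <- manifest
  invisible(st)
}

#' Analyze a dataset directory
#'
#' Reads every session CSV in a [simulate_study()] directory (or any
#' directory in the same dialect) and computes the full analysis: per-cell
#' rates and signal-detection indices, the threshold report with dilution
#' steps, 25-trial-block and 10-minute-bin summaries, and per-trial heart
#' rate. Summaries are also written as CSVs plus a JSON threshold report
#' when `out_dir` is given.
#'
#' @param data_dir Dataset directory.
#' @param out_dir Optional output directory for summary files.
#' @return A list: `rates` ([outcome_rates()]), `threshold`
#'   ([determine_threshold()]), `by_trial_block`, `by_time_bin`
#'   ([bin_results()]), `latency` ([latency_summary()]), `hr_trials`
#'   (trials with `hr_bpm`), `n_sessions`.
#' @export
analyze_study <- function(data_dir, out_dir = NULL) {
  trial_files <- sort(list.files(data_dir, pattern = "^session_[0-9]+\\.csv$",
                                 full.names = TRUE))
  if (!length(trial_files)) {
    stop_bad_arg("no sessions found in %s", data_dir)
  }
  sessions <- lapply(trial_files, read_trials_csv)
  trials <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    tr <- sessions[[i]]
    tr$session <- i
    tr
  }))
  rates <- outcome_rates(trials)
  threshold <- determine_threshold(rates)
  hr_trials <- do.call(rbind, lapply(seq_along(trial_files), function(i) {
    hr_path <- sub("\\.csv$", "_hr.csv", trial_files[i])
    tr <- sessions[[i]]
    tr$session <- i
    if (file.exists(hr_path)) hr_per_trial(read_hr_csv(hr_path), tr)
    else { tr$hr_bpm <- NA_real_; tr }
  }))
  report <- list(
    rates = rates,
    threshold = threshold,
    by_trial_block = bin_results(trials, "trial_block_25"),
    by_time_bin = bin_results(trials, "time_bin_10min"),
    latency = latency_summary(trials),
    hr_trials = hr_trials,
    n_sessions = length(sessions)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(rates, file.path(out_dir, "rates.csv"), row.names = FALSE)
    write.csv(report$by_trial_block,
              file.path(out_dir, "by_trial_block.csv"), row.names = FALSE)
    write.csv(report$by_time_bin, file.path(out_dir, "by_time_bin.csv"),
              row.names = FALSE)
    write.csv(hr_trials, file.path(out_dir, "hr_trials.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(reached = report$threshold$reached,
           threshold_concentration = report$threshold$threshold_concentration,
           threshold_intensity = report$threshold$threshold_intensity,
           steps = report$threshold$steps),
      file.path(out_dir, "threshold.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  }
  report
}

#' Calibrate PID delivery from trace files
#'
#' Runs the full PID pipeline over a set of trace CSVs: low-pass filtering,
#' per-cycle voltage deltas, the log-distance regression (when distances
#' are present), and the calibration curve over liquid dilutions (when
#' dilutions are present).
#'
#' @param traces List of [pid_trace()] objects, or paths readable by
#'   [read_pid_csv()].
#' @param distances_cm,dilutions_vv Optional metadata vectors matched to
#'   `traces` (used when reading from paths).
#' @param cutoff_scalar,order,settle_s Passed to [lowpass_filter()] and
#'   [cycle_deltas()].
#' @param out_dir Optional directory for `cycle_deltas.csv` and
#'   `calibration_report.json`.
#' @return List with `deltas` (pooled per-cycle deltas), `distance_model`
#'   (or `NULL`), `calibration` (or `NULL`).
#' @export
calibrate_pid <- function(traces, distances_cm = NULL, dilutions_vv = NULL,
                          cutoff_scalar = 0.01, order = 2, settle_s = 5,
                          out_dir = NULL) {
  if (is.character(traces)) {
    paths <- traces
    traces <- lapply(seq_along(paths), function(i) {
      read_pid_csv(paths[i],
                   distance_cm = if (is.null(distances_cm)) NA_real_
                                 else distances_cm[i],
                   dilution_vv = if (is.null(dilutions_vv)) NA_real_
                                 else dilutions_vv[i])
    })
  }
  deltas <- do.call(rbind, lapply(traces, function(tr) {
    cycle_deltas(lowpass_filter(tr, cutoff_scalar, order), settle_s)
  }))
  dist_model <- if (length(unique(deltas$distance_cm[
    !is.na(deltas$distance_cm)])) >= 3) fit_distance_model(deltas) else NULL
  calib <- if (length(unique(deltas$dilution_vv[
    !is.na(deltas$dilution_vv)])) >= 3) fit_calibration(deltas) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(deltas, file.path(out_dir, "cycle_deltas.csv"),
              row.names = FALSE)
    rep <- list(
      distance_model = if (is.null(dist_model)) NULL else
        dist_model[c("slope", "intercept", "r_squared", "n_points")],
      calibration = if (is.null(calib)) NULL else
        calib[c("slope", "intercept", "r_squared")]
    )
    jsonlite::write_json(rep, file.path(out_dir, "calibration_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(deltas = deltas, distance_model = dist_model, calibration = calib)
}
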