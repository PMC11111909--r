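#' Per-cell outcome rates and signal-detection indices
#'
#' Summarizes scored trials by concentration and exercise intensity. The
#' hit rate of a cell is hits over target-present trials in that cell.
#' Diluent trials are not concentration-specific, so every concentration
#' cell at a given intensity shares the false-alert rate pooled over that
#' intensity's diluent trials. A' and B'' are computed per cell, after the
#' optional 1/(2N) extreme-rate correction (on by default, since low
#' concentrations late in a session readily produce cells with no hits).
#'
#' @param trials A scored-trial data frame ([study_trials()] /
#'   `session_result$trials`): needs `stimulus_class`, `concentration_vv`,
#'   `intensity_kmh`, `outcome`, `latency_s`.
#' @param correction Apply the extreme-rate correction before the SDT
#'   formulas? Default `TRUE`.
#' @return Data frame with one row per concentration x intensity:
#'   `concentration_vv`, `intensity_kmh`, `n_trials`, `n_hits`, `hit_rate`,
#'   `mean_latency_s`, `n_noise`, `n_false_alerts`, `fa_rate`, `cr_rate`,
#'   `a_prime`, `b_double_prime`, sorted by descending concentration.
#' @examples
#' st <- generate_study(dog_model(), seed = 1)
#' head(outcome_rates(study_trials(st)))
#' @export
outcome_rates <- function(trials, correction = TRUE) {
  if (any(!trials$outcome %in%
            c("hit", "miss", "false_alert", "correct_rejection"))) {
    stop_bad_arg("every trial must carry a scored outcome")
  }
  tg <- trials[trials$stimulus_class == "target", ]
  dl <- trials[trials$stimulus_class == "diluent", ]
  if (nrow(tg) == 0) stop_bad_arg("no target trials to summarize")

  # Shared false-alert rate per intensity (diluent trials pool across
  # concentrations).
  fa <- aggregate(cbind(n_false_alerts = outcome == "false_alert",
                        n_noise = 1) ~ intensity_kmh, data = dl, FUN = sum)
  fa$fa_rate <- fa$n_false_alerts / fa$n_noise

  cells <- aggregate(cbind(n_hits = outcome == "hit", n_trials = 1) ~
                       concentration_vv + intensity_kmh, data = tg,
                     FUN = sum)
  lat <- aggregate(latency_s ~ concentration_vv + intensity_kmh, data = tg,
                   FUN = mean)
  names(lat)[3] <- "mean_latency_s"
  out <- merge(cells, lat, by = c("concentration_vv", "intensity_kmh"))
  out <- merge(out, fa, by = "intensity_kmh", all.x = TRUE)
  out$hit_rate <- out$n_hits / out$n_trials
  out$cr_rate <- 1 - out$fa_rate

  H <- out$hit_rate
  F <- out$fa_rate
  if (correction) {
    H <- correct_extreme_rate(H, out$n_trials)
    F <- correct_extreme_rate(F, out$n_noise)
  }
  out$a_prime <- a_prime(H, F)
  out$b_double_prime <- b_double_prime(H, F, out$n_trials, out$n_noise)
  out <- out[order(-out$concentration_vv, out$intensity_kmh),
             c("concentration_vv", "intensity_kmh", "n_trials", "n_hits",
               "hit_rate", "mean_latency_s", "n_noise", "n_false_alerts",
               "fa_rate", "cr_rate", "a_prime", "b_double_prime")]
  rownames(out) <- NULL
  out
}

#' Determine the detection threshold from per-concentration hit rates
#'
#' The detection threshold is the first concentration, scanning from the
#' highest tested downward, whose hit rate is at or below 0.5. By default
#' the criterion may be met at either exercise intensity (matching the
#' block stopping rule; in practice the moderate intensity meets it first);
#' restrict with `intensity`.
#'
#' @param rates Data frame with `concentration_vv`, `intensity_kmh`,
#'   `hit_rate` (e.g. [outcome_rates()] or [block_hit_rates()] output).
#' @param intensity `"either"` (default), `4`, or `8`: which intensity's
#'   hit rates may determine the threshold.
#' @param inclusive Use `<= 0.5` (default) rather than `< 0.5`.
#' @return A `threshold_result`: list with `reached` (logical),
#'   `threshold_concentration` (v/v, `NA` if not reached),
#'   `threshold_intensity` (intensity of the qualifying cell), and `steps`
#'   (data frame mapping each tested concentration to its dilution step,
#'   `NA` steps when not reached).
#' @examples
#' rates <- data.frame(concentration_vv = 10^c(-2, -2.5, -3, -3.5),
#'                     intensity_kmh = 8,
#'                     hit_rate = c(1, 0.9, 0.8, 0.45))
#' determine_threshold(rates)$threshold_concentration # 10^-3.5
#' @export
determine_threshold <- function(rates, intensity = "either",
                                inclusive = TRUE) {
  needed <- c("concentration_vv", "intensity_kmh", "hit_rate")
  if (!all(needed %in% names(rates))) {
    stop_bad_arg("rates needs columns %s", paste(needed, collapse = ", "))
  }
  sel <- if (identical(intensity, "either")) rates
         else rates[rates$intensity_kmh == as.numeric(intensity), ]
  sel <- sel[order(-sel$concentration_vv), ]
  qualifies <- if (inclusive) sel$hit_rate <= 0.5 else sel$hit_rate < 0.5
  conc <- sort(unique(rates$concentration_vv), decreasing = TRUE)
  if (!any(qualifies)) {
    res <- list(reached = FALSE,
                threshold_concentration = NA_real_,
                threshold_intensity = NA_real_,
                steps = data.frame(concentration_vv = conc,
                                   dilution_step = NA_real_))
  } else {
    first <- which(qualifies)[1]
    thr <- sel$concentration_vv[[first]]
    res <- list(reached = TRUE,
                threshold_concentration = thr,
                threshold_intensity = sel$intensity_kmh[[first]],
                steps = data.frame(concentration_vv = conc,
                                   dilution_step = dilution_steps(conc, thr)))
  }
  structure(res, class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$reached) {
    cat(sprintf(
      "<threshold_result> threshold %.3g v/v (determined at %g km/h)\n",
      x$threshold_concentration, x$threshold_intensity))
  } else {
    cat("<threshold_result> threshold not reached\n")
  }
  invisible(x)
}

#' Dilution steps relative to an individual threshold
#'
#' Rescales a concentration to log10 units above an individual's detection
#' threshold: `log10(concentration / threshold)`. A concentration equal to
#' the threshold is 0 steps; each half-log increase adds 0.5 steps (so
#' 0.00316 v/v against a 0.001 v/v threshold is 0.5 steps, and 0.01 is 1
#' step).
#'
#' @param concentration v/v concentration(s), > 0.
#' @param threshold The individual's threshold concentration (v/v), > 0.
#' @return Numeric vector of dilution steps.
#' @examples
#' dilution_steps(0.00316, 0.001) # ~0.5
#' dilution_steps(0.01, 0.001)    # 1
#' @export
dilution_steps <- function(concentration, threshold) {
  if (any(concentration <= 0) || any(threshold <= 0)) {
    stop_bad_arg("concentration and threshold must be > 0")
  }
  log10(concentration / threshold)
}

#' Bin trials into 25-trial blocks or 10-minute time bins
#'
#' Computes per-bin, per-concentration hit rates and mean latencies within
#' sessions. Trial-block bins partition trial indices 1–100 into four
#' 25-trial blocks; time bins partition session time into half-open
#' 10-minute intervals \[0, 10), \[10, 20), \[20, ...) by each trial's
#' start time.
#'
#' @param trials A scored-trial data frame (needs `trial_index`, `start_s`
#'   in addition to the [outcome_rates()] columns).
#' @param kind `"trial_block_25"` or `"time_bin_10min"`.
#' @return Data frame `bin`, `concentration_vv`, `intensity_kmh`,
#'   `n_trials`, `hit_rate`, `mean_latency_s`.
#' @examples
#' st <- generate_study(dog_model(), seed = 1)
#' head(bin_results(study_trials(st), "trial_block_25"))
#' @export
bin_results <- function(trials, kind = c("trial_block_25", "time_bin_10min")) {
  kind <- match.arg(kind)
  tg <- trials[trials$stimulus_class == "target", ]
  tg$bin <- if (kind == "trial_block_25") {
    (tg$trial_index - 1L) %/% 25L + 1L
  } else {
    floor(tg$start_s / 600) + 1L
  }
  agg <- aggregate(cbind(n_hits = outcome == "hit", n_trials = 1) ~
                     bin + concentration_vv + intensity_kmh, data = tg,
                   FUN = sum)
  lat <- aggregate(latency_s ~ bin + concentration_vv + intensity_kmh,
                   data = tg, FUN = mean)
  names(lat)[4] <- "mean_latency_s"
  out <- merge(agg, lat, by = c("bin", "concentration_vv", "intensity_kmh"))
  out$hit_rate <- out$n_hits / out$n_trials
  out <- out[order(out$bin, -out$concentration_vv, out$intensity_kmh),
             c("bin", "concentration_vv", "intensity_kmh", "n_trials",
               "hit_rate", "mean_latency_s")]
  rownames(out) <- NULL
  out
}

#' Mean latency per concentration and intensity
#'
#' Latencies of non-responses are censored at 10 s by the scorer and enter
#' the means at that value, following the analysis convention.
#'
#' @param trials A scored-trial data frame.
#' @return Data frame `concentration_vv`, `intensity_kmh`, `n_trials`,
#'   `mean_latency_s`.
#' @export
latency_summary <- function(trials) {
  tg <- trials[trials$stimulus_class == "target", ]
  out <- aggregate(cbind(mean_latency_s = latency_s, n_trials = 1) ~
                     concentration_vv + intensity_kmh, data = tg,
                   FUN = mean)
  out$n_trials <- aggregate(latency_s ~ concentration_vv + intensity_kmh,
                            data = tg, FUN = length)$latency_s
  out[order(-out$concentration_vv, out$intensity_kmh), ]
}

#' Average heart rate per trial
#'
#' Averages the 1 Hz heart-rate samples whose timestamps fall within each
#' trial, from trial start to trial end. The HR clock and the session
#' clock must share an origin; use `offset_s` when they do not. Trials
#' containing no samples are returned as `NA` (flagged missing, never 0).
#'
#' @param hr Data frame with `timestamp_s` (sorted) and `bpm`.
#' @param trials A scored-trial data frame with `start_s`, `end_s`.
#' @param offset_s Seconds added to the HR timestamps to align clocks.
#' @return The trials data frame with added `hr_bpm` column.
#' @examples
#' hr <- data.frame(timestamp_s = 0:120, bpm = 100)
#' tr <- data.frame(trial_index = 1, start_s = 10, end_s = 20)
#' hr_per_trial(hr, tr)$hr_bpm # 100
#' @export
hr_per_trial <- function(hr, trials, offset_s = 0) {
  if (is.unsorted(hr$timestamp_s)) {
    stop_bad_arg("heart-rate timestamps must be sorted")
  }
  ts <- hr$timestamp_s + offset_s
  trials$hr_bpm <- vapply(seq_len(nrow(trials)), function(i) {
    sel <- ts >= trials$start_s[[i]] & ts <= trials$end_s[[i]]
    if (!any(sel)) NA_real_ else mean(hr$bpm[sel])
  }, numeric(1))
  trials
}
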