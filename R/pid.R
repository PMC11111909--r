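#' Construct a PID voltage trace
#'
#' A photoionization-detector recording: a voltage sample stream with a
#' per-sample valve state (odor on/off) at a fixed sampling rate (500 Hz in
#' the delivery-validation protocol).
#'
#' @param voltage_v Numeric vector of voltages (V).
#' @param valve_on Logical vector, same length, odor valve state.
#' @param sample_rate_hz Sampling rate (Hz), > 0. Default 500.
#' @param distance_cm Optional sensor distance from the odor port (cm).
#' @param dilution_vv Optional liquid dilution in the sampled vial (v/v).
#' @return A `pid_trace` object.
#' @export
pid_trace <- function(voltage_v, valve_on, sample_rate_hz = 500,
                      distance_cm = NA_real_, dilution_vv = NA_real_) {
  if (length(voltage_v) != length(valve_on)) {
    stop_bad_arg("voltage_v and valve_on must have equal length")
  }
  if (sample_rate_hz <= 0) stop_bad_arg("sample_rate_hz must be > 0")
  structure(
    list(voltage_v = as.numeric(voltage_v),
         valve_on = as.logical(valve_on),
         sample_rate_hz = sample_rate_hz,
         distance_cm = distance_cm,
         dilution_vv = dilution_vv),
    class = "pid_trace"
  )
}

#' @export
print.pid_trace <- function(x, ...) {
  cat(sprintf("<pid_trace> %d samples @ %g Hz (%.1f s), %d valve-on",
              length(x$voltage_v), x$sample_rate_hz,
              length(x$voltage_v) / x$sample_rate_hz, sum(x$valve_on)))
  if (!is.na(x$distance_cm)) cat(sprintf(", distance %g cm", x$distance_cm))
  cat("\n")
  invisible(x)
}

#' Low-pass Butterworth filtering of a PID trace
#'
#' Zero-phase (forward-backward) Butterworth low-pass filter with cutoff
#' expressed as a fraction of the Nyquist frequency (the protocol's scalar
#' of 0.01 gives a 2.5 Hz cutoff at 500 Hz sampling). The trace is padded
#' by odd reflection before filtering to suppress edge transients, so a
#' constant trace passes through unchanged (DC gain 1).
#'
#' @param trace A [pid_trace()].
#' @param cutoff_scalar Cutoff as a fraction of Nyquist, in (0, 1).
#'   Default 0.01.
#' @param order Filter order. Default 2.
#' @return The filtered `pid_trace`.
#' @examples
#' tr <- pid_trace(rep(0.3, 2000), rep(TRUE, 2000))
#' range(lowpass_filter(tr)$voltage_v - 0.3)
#' @export
lowpass_filter <- function(trace, cutoff_scalar = 0.01, order = 2) {
  stopifnot(inherits(trace, "pid_trace"))
  if (cutoff_scalar <= 0 || cutoff_scalar >= 1) {
    stop_bad_arg("cutoff_scalar must be in (0, 1)")
  }
  x <- trace$voltage_v
  n <- length(x)
  # the IIR transient at this cutoff decays with an e-folding of roughly
  # 1/(pi * cutoff) samples; a 12/cutoff pad leaves it below 1e-10
  pad <- min(n - 1L, ceiling(12 / cutoff_scalar))
  if (n <= 2 * order + 1) stop_bad_arg("trace too short to filter")
  bf <- signal::butter(order, cutoff_scalar, type = "low")
  # odd (point-reflected) extension, as is standard for zero-phase IIR
  # filtering, keeps value and slope continuous at the joints
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  trace$voltage_v <- y[seq(pad + 1L, pad + n)]
  trace
}

#' Per-cycle voltage deltas
#'
#' Splits a trace into complete odor on/off cycles (a valve-on run followed
#' by a valve-off run) and, for each, subtracts the mean off-voltage from
#' the mean on-voltage. The per-cycle off baseline absorbs slow sensor
#' drift; negative deltas are reported as-is (they diagnose baseline
#' drift). The first `settle_s` seconds after each valve transition are
#' excluded from the means to skip rise/clearance transients. A truncated
#' final cycle is dropped with a message.
#'
#' @param trace A [pid_trace()] (typically after [lowpass_filter()]).
#' @param settle_s Seconds excluded after each valve transition. Default 5.
#' @return Data frame `cycle_index`, `delta_v`, `mean_on_v`, `mean_off_v`,
#'   `distance_cm`, `dilution_vv`; zero rows if the trace holds no complete
#'   cycle.
#' @export
cycle_deltas <- function(trace, settle_s = 5) {
  stopifnot(inherits(trace, "pid_trace"))
  r <- rle(trace$valve_on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  skip <- round(settle_s * trace$sample_rate_hz)

  # A complete cycle is an on-run immediately followed by an off-run that
  # itself ends before the trace does or at its end.
  on_idx <- which(r$values)
  rows <- list()
  ci <- 0L
  for (i in on_idx) {
    if (i + 1L > length(r$values)) {
      message("dropping truncated final cycle (no off period)")
      break
    }
    on <- seq(starts[i], ends[i])
    off <- seq(starts[i + 1L], ends[i + 1L])
    if (length(on) <= skip || length(off) <= skip) {
      message("dropping cycle shorter than the settle window")
      next
    }
    ci <- ci + 1L
    mean_on <- mean(trace$voltage_v[on[-seq_len(skip)]])
    mean_off <- mean(trace$voltage_v[off[-seq_len(skip)]])
    rows[[ci]] <- data.frame(cycle_index = ci,
                             delta_v = mean_on - mean_off,
                             mean_on_v = mean_on,
                             mean_off_v = mean_off,
                             distance_cm = trace$distance_cm,
                             dilution_vv = trace$dilution_vv)
  }
  if (ci == 0L) {
    return(data.frame(cycle_index = integer(0), delta_v = numeric(0),
                      mean_on_v = numeric(0), mean_off_v = numeric(0),
                      distance_cm = numeric(0), dilution_vv = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Regression of voltage delta on log10 distance
#'
#' Least-squares fit of `delta_v ~ log10(distance_cm)`, quantifying how the
#' odor plume dilutes along the treadmill.
#'
#' @param deltas A [cycle_deltas()] data frame (pooled over distances) with
#'   at least 3 distinct distances.
#' @return A `distance_model`: list with `slope`, `intercept`, `r_squared`,
#'   `n_points`, `fit` (the `lm` object).
#' @export
fit_distance_model <- function(deltas) {
  d <- deltas[!is.na(deltas$distance_cm), ]
  if (length(unique(d$distance_cm)) < 3L) {
    stop_bad_arg("need at least 3 distinct distances")
  }
  d$log_dist <- log10(d$distance_cm)
  fit <- lm(delta_v ~ log_dist, data = d)
  structure(
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = r_squared(fit, d$delta_v),
         n_points = nrow(d),
         fit = fit),
    class = "distance_model"
  )
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf(
    "<distance_model> delta_v = %.4g * log10(distance_cm) + %.4g  (R^2 = %.3f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit a PID calibration curve over liquid dilutions
#'
#' Fits a strictly monotone mapping from log10 liquid dilution to expected
#' voltage delta (linear in log10 dilution), from headspace recordings of
#' vials at known dilutions. The inverse mapping estimates an unknown
#' concentration from a measured delta; queries outside the fitted delta
#' range are rejected rather than extrapolated.
#'
#' @param deltas A [cycle_deltas()] data frame with a `dilution_vv` column
#'   covering at least 3 dilution levels.
#' @return A `calibration_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `delta_range`, `dilution_range`, `fit`.
#' @export
fit_calibration <- function(deltas) {
  d <- deltas[!is.na(deltas$dilution_vv), ]
  if (length(unique(d$dilution_vv)) < 3L) {
    stop_bad_arg("need at least 3 distinct dilution levels")
  }
  d$log_dil <- log10(d$dilution_vv)
  fit <- lm(delta_v ~ log_dil, data = d)
  slope <- unname(coef(fit)[2])
  if (slope == 0) stop_bad_arg("calibration curve is not monotone (slope 0)")
  lev <- sort(unique(d$log_dil))
  pred <- coef(fit)[1] + slope * lev
  structure(
    list(slope = slope,
         intercept = unname(coef(fit)[1]),
         r_squared = r_squared(fit, d$delta_v),
         delta_range = range(pred),
         dilution_range = 10^range(lev),
         fit = fit),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> delta_v = %.4g * log10(dilution) + %.4g  (R^2 = %.3f)\n",
    x$slope, x$intercept, x$r_squared))
  cat(sprintf("  calibrated dilutions: %.3g to %.3g v/v\n",
              x$dilution_range[1], x$dilution_range[2]))
  invisible(x)
}

#' Estimate a concentration from a measured voltage delta
#'
#' Inverts a [fit_calibration()] curve. Deltas outside the calibrated range
#' raise an error (no extrapolation).
#'
#' @param curve A `calibration_curve`.
#' @param delta_v Measured voltage delta(s) (V).
#' @param tol Fractional tolerance on the range check. Default 1e-8.
#' @return Estimated v/v dilution(s).
#' @export
estimate_concentration <- function(curve, delta_v, tol = 1e-8) {
  stopifnot(inherits(curve, "calibration_curve"))
  slack <- tol * max(1, diff(curve$delta_range))
  if (any(delta_v < curve$delta_range[1] - slack |
          delta_v > curve$delta_range[2] + slack)) {
    stop_bad_arg(
      "delta_v %.4g outside the calibrated range [%.4g, %.4g]; refusing to extrapolate",
      delta_v[which(delta_v < curve$delta_range[1] - slack |
                    delta_v > curve$delta_range[2] + slack)][1],
      curve$delta_range[1], curve$delta_range[2])
  }
  10^((delta_v - curve$intercept) / curve$slope)
}

#' Synthesize a PID trace for a valve activation protocol
#'
#' Generates a square-wave voltage trace with first-order exponential
#' rise/decay at valve transitions, optional linear baseline drift, and
#' Gaussian noise, annotated with the valve state. Defaults follow the
#' delivery-validation protocol: 45 s odor on, 60 s off, 10 cycles,
#' 500 Hz.
#'
#' @param on_s,off_s Valve-on and valve-off durations (s). Defaults 45, 60.
#' @param cycles Number of on/off cycles. Default 10.
#' @param on_level,off_level Steady-state voltages (V) with the valve on
#'   and off.
#' @param tau_s Exponential time constant of the rise/decay (s).
#'   Default 1.
#' @param drift_v_per_s Linear baseline drift (V/s). Default 0.
#' @param noise_sd Gaussian noise SD (V). Default 0.
#' @param sample_rate_hz Sampling rate (Hz). Default 500.
#' @param distance_cm,dilution_vv Metadata attached to the trace.
#' @param seed Optional integer seed.
#' @return A [pid_trace()].
#' @examples
#' tr <- synth_pid_trace(on_s = 5, off_s = 5, cycles = 2, on_level = 0.3,
#'                       off_level = 0.1, tau_s = 0.05)
#' nrow(cycle_deltas(tr, settle_s = 1))
#' @export
synth_pid_trace <- function(on_s = 45, off_s = 60, cycles = 10,
                            on_level = 0.3, off_level = 0.1, tau_s = 1,
                            drift_v_per_s = 0, noise_sd = 0,
                            sample_rate_hz = 500, distance_cm = NA_real_,
                            dilution_vv = NA_real_, seed = NULL) {
  if (on_s <= 0 || off_s <= 0 || cycles < 1) {
    stop_bad_arg("on_s, off_s must be > 0 and cycles >= 1")
  }
  n_on <- round(on_s * sample_rate_hz)
  n_off <- round(off_s * sample_rate_hz)
  valve <- rep(rep(c(TRUE, FALSE), times = c(n_on, n_off)), cycles)
  n <- length(valve)
  t <- (seq_len(n) - 1) / sample_rate_hz

  # first-order response toward the valve-state target level
  target <- ifelse(valve, on_level, off_level)
  if (tau_s > 0) {
    a <- exp(-1 / (sample_rate_hz * tau_s))
    v <- as.numeric(stats::filter((1 - a) * target, a,
                                  method = "recursive", init = off_level))
  } else {
    v <- target
  }
  v <- v + drift_v_per_s * t
  if (noise_sd > 0) {
    v <- v + with_seed(seed, rnorm(n, sd = noise_sd))
  }
  pid_trace(v, valve, sample_rate_hz = sample_rate_hz,
            distance_cm = distance_cm, dilution_vv = dilution_vv)
}
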