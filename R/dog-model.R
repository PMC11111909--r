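#' Generative model of a simulated detection dog
#'
#' Parameterizes a subject's psychometric detection function, false-alert
#' behavior, response latencies, and heart rate, including an
#' exercise-dependent sensitivity decay: at moderate intensity (8 km/h) the
#' psychometric midpoint drifts upward (toward higher concentrations) at
#' `decay_rate` log10 units per minute once `decay_onset_min` minutes of
#' exercise have elapsed. At low intensity (4 km/h) sensitivity is stable.
#'
#' Defaults are illustrative values consistent with the printed group
#' summaries of the behavioral protocol this package models (lapse ~ miss
#' proportion of 0.02, false-alert proportion ~ 0.05 with a go bias at low
#' and a no-go bias at moderate intensity, heart-rate means of 95.9 and
#' 121.2 bpm); they are not fitted to any animal's data.
#'
#' @param mu0 Psychometric midpoint at rest, log10 v/v concentration.
#' @param sigma Psychometric slope parameter (log10 units, > 0).
#' @param lapse Probability of missing a clearly supra-threshold odor.
#' @param fa_rate_low,fa_rate_mod False-alert probability per diluent trial
#'   at 4 and 8 km/h.
#' @param decay_rate Midpoint elevation (log10 units per minute) under
#'   moderate intensity, >= 0.
#' @param decay_onset_min Minutes of moderate exercise before decay begins.
#' @param psychometric `"gaussian"` (cumulative Gaussian, default) or
#'   `"logistic"`.
#' @param decay_form `"linear"` (default) or `"exponential"`
#'   (saturating elevation with scale `decay_saturation` log10 units).
#' @param decay_saturation Asymptotic elevation for the exponential form.
#' @param latency_base_s Expected latency (s) at 1 v/v, low intensity.
#' @param latency_conc_slope Added expected latency (s) per log10 unit of
#'   dilution (latencies grow as concentration falls).
#' @param latency_intensity_offset_s Added expected latency (s) at 8 km/h.
#' @param latency_sdlog Log-scale SD of the truncated log-normal latency
#'   noise.
#' @param hr_mean_low,hr_mean_mod Mean heart rate (bpm) at 4 and 8 km/h.
#' @param hr_sd_low,hr_sd_mod Marginal SD (bpm) of the heart-rate series at
#'   each intensity.
#' @param hr_ar Lag-1 autocorrelation of the heart-rate series, in \[0, 1).
#'
#' @return An object of class `dog_model`.
#' @examples
#' dog <- dog_model()
#' p_hit(dog, 1e-3, intensity = 4, elapsed_min = 0)
#' @export
dog_model <- function(mu0 = -4.5,
                      sigma = 0.35,
                      lapse = 0.02,
                      fa_rate_low = 0.07,
                      fa_rate_mod = 0.03,
                      decay_rate = 0.1,
                      decay_onset_min = 10,
                      psychometric = c("gaussian", "logistic"),
                      decay_form = c("linear", "exponential"),
                      decay_saturation = 3,
                      latency_base_s = 1.6,
                      latency_conc_slope = 0.35,
                      latency_intensity_offset_s = 0.8,
                      latency_sdlog = 0.25,
                      hr_mean_low = 95.9,
                      hr_mean_mod = 121.2,
                      hr_sd_low = 21.6,
                      hr_sd_mod = 6.6,
                      hr_ar = 0.9) {
  psychometric <- match.arg(psychometric)
  decay_form <- match.arg(decay_form)
  if (sigma <= 0) stop_bad_arg("sigma must be > 0")
  for (p in c(lapse, fa_rate_low, fa_rate_mod)) {
    if (p < 0 || p > 1) stop_bad_arg("probabilities must be in [0, 1]")
  }
  if (decay_rate < 0) stop_bad_arg("decay_rate must be >= 0")
  if (hr_mean_low <= 0 || hr_mean_mod <= 0) {
    stop_bad_arg("heart-rate means must be positive")
  }
  if (hr_ar < 0 || hr_ar >= 1) stop_bad_arg("hr_ar must be in [0, 1)")
  structure(
    list(
      mu0 = mu0, sigma = sigma, lapse = lapse,
      fa_rate_low = fa_rate_low, fa_rate_mod = fa_rate_mod,
      decay_rate = decay_rate, decay_onset_min = decay_onset_min,
      psychometric = psychometric, decay_form = decay_form,
      decay_saturation = decay_saturation,
      latency_base_s = latency_base_s,
      latency_conc_slope = latency_conc_slope,
      latency_intensity_offset_s = latency_intensity_offset_s,
      latency_sdlog = latency_sdlog,
      hr_mean_low = hr_mean_low, hr_mean_mod = hr_mean_mod,
      hr_sd_low = hr_sd_low, hr_sd_mod = hr_sd_mod, hr_ar = hr_ar
    ),
    class = "dog_model"
  )
}

#' @export
print.dog_model <- function(x, ...) {
  cat("<dog_model>\n")
  cat(sprintf("  psychometric: %s, midpoint 10^%.2f v/v, slope %.2f, lapse %.3f\n",
              x$psychometric, x$mu0, x$sigma, x$lapse))
  cat(sprintf("  decay (%s): %.3f log10/min after %g min at 8 km/h\n",
              x$decay_form, x$decay_rate, x$decay_onset_min))
  cat(sprintf("  false alerts: %.3f (4 km/h) / %.3f (8 km/h)\n",
              x$fa_rate_low, x$fa_rate_mod))
  cat(sprintf("  heart rate: %.1f +/- %.1f bpm (4 km/h), %.1f +/- %.1f bpm (8 km/h), AR1 %.2f\n",
              x$hr_mean_low, x$hr_sd_low, x$hr_mean_mod, x$hr_sd_mod,
              x$hr_ar))
  invisible(x)
}

# Effective psychometric midpoint after `elapsed_min` minutes at `intensity`.
decayed_mu <- function(model, intensity, elapsed_min) {
  if (intensity != 8 || model$decay_rate == 0) return(model$mu0)
  t <- pmax(0, elapsed_min - model$decay_onset_min)
  shift <- switch(model$decay_form,
    linear = model$decay_rate * t,
    exponential = model$decay_saturation *
      (1 - exp(-model$decay_rate * t / model$decay_saturation))
  )
  model$mu0 + shift
}

#' Probability of detecting a target concentration
#'
#' Lapse-adjusted sigmoid of log10 concentration:
#' `p = (1 - lapse) * S((log10(c) - mu(t)) / sigma)` where `S` is a standard
#' cumulative Gaussian (or logistic) and `mu(t)` the decayed midpoint. `p`
#' is non-decreasing in concentration, non-increasing in elapsed time at
#' moderate intensity, and independent of elapsed time at low intensity.
#'
#' @param model A [dog_model()].
#' @param concentration Target v/v concentration(s), > 0.
#' @param intensity Treadmill speed (km/h), 4 or 8.
#' @param elapsed_min Minutes since the first trial onset.
#' @return Hit probability in \[0, 1\] (vectorized over `concentration`).
#' @examples
#' d <- dog_model(lapse = 0)
#' p_hit(d, 10^d$mu0, 4, 0)       # 0.5 at the midpoint
#' p_hit(d, 10^(d$mu0 + 3), 4, 0) # ~1 far above it
#' @export
p_hit <- function(model, concentration, intensity, elapsed_min = 0) {
  stopifnot(inherits(model, "dog_model"))
  if (any(concentration <= 0)) stop_bad_arg("concentration must be > 0")
  mu <- decayed_mu(model, intensity, elapsed_min)
  z <- (log10(concentration) - mu) / model$sigma
  s <- if (model$psychometric == "gaussian") pnorm(z) else stats::plogis(z)
  (1 - model$lapse) * s
}

#' Sample a response latency
#'
#' Truncated log-normal latency whose expectation (before truncation) rises
#' with dilution and with moderate intensity:
#' `latency_base_s + latency_conc_slope * (-log10 c) +
#' latency_intensity_offset_s * [intensity == 8]`. Samples are truncated to
#' the interval from the poke criterion (0.4 s) to the response window
#' (10 s).
#'
#' @inheritParams p_hit
#' @param seed Optional integer seed.
#' @param n Number of samples.
#' @return Numeric vector of latencies (s) in \[0.4, 10\].
#' @export
sample_latency <- function(model, concentration, intensity, seed = NULL,
                           n = 1L) {
  stopifnot(inherits(model, "dog_model"))
  if (any(concentration <= 0)) stop_bad_arg("concentration must be > 0")
  mean_lat <- model$latency_base_s +
    model$latency_conc_slope * (-log10(concentration)) +
    model$latency_intensity_offset_s * (intensity == 8)
  mean_lat <- pmax(mean_lat, 0.41)
  with_seed(seed, {
    x <- if (model$latency_sdlog > 0) {
      rlnorm(n, meanlog = log(mean_lat) - model$latency_sdlog^2 / 2,
             sdlog = model$latency_sdlog)
    } else {
      rep(mean_lat, n)
    }
    pmin(pmax(x, 0.4), 10)
  })
}

#' Sample the poke events of one trial
#'
#' Target trials alert with probability [p_hit()], emitting one
#' criterion-satisfying poke (0.8 s beam break) whose criterion instant
#' equals the sampled latency; diluent trials alert with the intensity's
#' false-alert rate, at a uniform latency over the response window.
#' Non-alert trials emit no pokes.
#'
#' @param model A [dog_model()].
#' @param spec One row of a session plan (needs `stimulus_class`,
#'   `concentration_vv`).
#' @param intensity Treadmill speed (km/h).
#' @param elapsed_min Minutes since first trial onset.
#' @param seed Optional integer seed.
#' @return A [poke_events()] object with 0 or 1 rows.
#' @export
sample_response <- function(model, spec, intensity, elapsed_min = 0,
                            seed = NULL) {
  stopifnot(inherits(model, "dog_model"))
  with_seed(seed, {
    if (identical(spec$stimulus_class, "target")) {
      p <- p_hit(model, spec$concentration_vv, intensity, elapsed_min)
      if (runif(1) < p) {
        lat <- sample_latency(model, spec$concentration_vv, intensity)
        poke_events(onset_s = lat - 0.4, duration_s = 0.8)
      } else {
        poke_events()
      }
    } else {
      fa <- if (intensity == 8) model$fa_rate_mod else model$fa_rate_low
      if (runif(1) < fa) {
        lat <- runif(1, 0.4, 10)
        poke_events(onset_s = lat - 0.4, duration_s = 0.8)
      } else {
        poke_events()
      }
    }
  })
}

#' Generate a 1 Hz heart-rate series
#'
#' Stationary AR(1) process around the intensity's mean with the model's
#' marginal SD: `x_t = m + ar * (x_{t-1} - m) + e_t`, innovation SD
#' `sd * sqrt(1 - ar^2)`, initialized from the stationary distribution.
#'
#' @param model A [dog_model()].
#' @param intensity Treadmill speed (km/h), 4 or 8.
#' @param duration_min Length of the series in minutes (> 0).
#' @param seed Optional integer seed.
#' @return Data frame with `timestamp_s` (0, 1, 2, ...) and `bpm`.
#' @examples
#' hr <- generate_hr(dog_model(), 8, duration_min = 2, seed = 1)
#' mean(hr$bpm)
#' @export
generate_hr <- function(model, intensity, duration_min, seed = NULL) {
  stopifnot(inherits(model, "dog_model"))
  if (duration_min <= 0) stop_bad_arg("duration_min must be > 0")
  n <- ceiling(60 * duration_min)
  m <- if (intensity == 8) model$hr_mean_mod else model$hr_mean_low
  s <- if (intensity == 8) model$hr_sd_mod else model$hr_sd_low
  ar <- model$hr_ar
  bpm <- with_seed(seed, {
    if (s == 0) {
      rep(m, n)
    } else {
      e <- rnorm(n, sd = s * sqrt(1 - ar^2))
      x <- numeric(n)
      x[1] <- rnorm(1, mean = 0, sd = s)
      for (i in seq_len(n)[-1]) x[i] <- ar * x[i - 1] + e[i]
      m + x
    }
  })
  data.frame(timestamp_s = seq_len(n) - 1, bpm = bpm)
}
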