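# Small, fast fixtures: 100 Hz, short cycles. The generator's protocol
# defaults (45 s on / 60 s off, 10 cycles, 500 Hz) are exercised once below.

fix_trace <- function(delta = 0.2, off = 0.1, ...) {
  synth_pid_trace(on_s = 10, off_s = 10, cycles = 3, on_level = off + delta,
                  off_level = off, tau_s = 0.05, sample_rate_hz = 100, ...)
}

test_that("the zero-phase Butterworth filter has unit DC gain", {
  tr <- pid_trace(rep(0.3, 2000), rep(TRUE, 2000), sample_rate_hz = 500)
  out <- lowpass_filter(tr)
  expect_lt(max(abs(out$voltage_v - 0.3)), 1e-9)
  expect_error(lowpass_filter(tr, cutoff_scalar = 1.5), "\\(0, 1\\)")
})

test_that("the filter separates passband from stopband", {
  fs <- 500
  t <- seq(0, 60, by = 1 / fs)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))

  # 50 Hz (20x the 2.5 Hz cutoff): attenuated by far more than 99%
  hi <- pid_trace(sin(2 * pi * 50 * t), rep(TRUE, length(t)), fs)
  expect_lt(max(abs(lowpass_filter(hi)$voltage_v[mid])), 0.01)

  # 0.1 Hz (well inside the passband): amplitude preserved within 5%
  lo <- pid_trace(sin(2 * pi * 0.1 * t), rep(TRUE, length(t)), fs)
  expect_gt(max(abs(lowpass_filter(lo)$voltage_v[mid])), 0.95)
})

test_that("cycle deltas recover the programmed on/off difference", {
  d <- cycle_deltas(fix_trace(), settle_s = 1)
  expect_equal(nrow(d), 3)
  expect_equal(d$delta_v, rep(0.2, 3), tolerance = 1e-3)

  # per-cycle baseline subtraction bounds the drift error by
  # drift * (on_s + off_s)/2 instead of letting it accumulate over the trace
  drift <- 0.001
  dd <- cycle_deltas(fix_trace(drift_v_per_s = drift), settle_s = 1)
  expect_lt(max(abs(dd$delta_v - 0.2)), drift * (10 + 10))
  expect_lt(diff(range(dd$delta_v)), 1e-6) # bias, not accumulation

  # an all-off trace yields no cycles
  off <- pid_trace(rep(0.1, 500), rep(FALSE, 500), 100)
  expect_equal(nrow(cycle_deltas(off)), 0)

  # truncated final cycle is dropped with a message
  v <- c(rep(TRUE, 500), rep(FALSE, 500), rep(TRUE, 500))
  tr <- pid_trace(ifelse(v, 0.3, 0.1), v, 100)
  expect_message(d2 <- cycle_deltas(tr, settle_s = 1), "truncated")
  expect_equal(nrow(d2), 1)
})

test_that("the delta pipeline is linear in the trace voltage", {
  tr <- fix_trace(noise_sd = 0.005, seed = 8)
  base <- cycle_deltas(lowpass_filter(tr, 0.05), settle_s = 1)$delta_v
  for (k in c(0.5, 2, 7)) {
    scaled <- tr
    scaled$voltage_v <- k * tr$voltage_v
    got <- cycle_deltas(lowpass_filter(scaled, 0.05), settle_s = 1)$delta_v
    expect_equal(got, k * base, tolerance = 1e-10)
  }
})

test_that("filter plus deltas recover the level within 2% at SNR >= 10", {
  tr <- fix_trace(noise_sd = 0.02, seed = 99) # delta 0.2, SNR 10
  d <- cycle_deltas(lowpass_filter(tr, 0.05), settle_s = 1)
  expect_equal(mean(d$delta_v), 0.2, tolerance = 0.02 * 0.2 / 0.2)
  expect_lt(abs(mean(d$delta_v) - 0.2) / 0.2, 0.02)
})

test_that("the log-distance regression recovers a noiseless fixture", {
  dist <- c(7, 15, 30, 50, 76)
  traces <- lapply(dist, function(dc) {
    fix_trace(delta = -0.08 * log10(dc) + 0.25, distance_cm = dc)
  })
  deltas <- do.call(rbind, lapply(traces, cycle_deltas, settle_s = 1))
  m <- fit_distance_model(deltas)
  expect_equal(m$slope, -0.08, tolerance = 1e-3)
  expect_equal(m$intercept, 0.25, tolerance = 1e-3)
  expect_gt(m$r_squared, 0.9999)
  expect_equal(m$n_points, 15)

  # flat response: slope 0
  flat <- do.call(rbind, lapply(dist, function(dc) {
    data.frame(cycle_index = 1, delta_v = 0.2, mean_on_v = 0.3,
               mean_off_v = 0.1, distance_cm = dc, dilution_vv = NA)
  }))
  expect_equal(fit_distance_model(flat)$slope, 0)
  expect_error(fit_distance_model(deltas[deltas$distance_cm < 10, ]),
               "3 distinct")
})

test_that("noisy regression slopes land within their sampling error", {
  set.seed(5)
  dist <- rep(c(7, 15, 30, 50, 76), each = 10)
  sigma <- 0.01
  d <- data.frame(cycle_index = 1, delta_v = -0.08 * log10(dist) + 0.25 +
                    rnorm(length(dist), sd = sigma),
                  mean_on_v = NA, mean_off_v = NA, distance_cm = dist,
                  dilution_vv = NA)
  m <- fit_distance_model(d)
  se <- summary(m$fit)$coefficients["log_dist", "Std. Error"]
  expect_lt(abs(m$slope - (-0.08)), 3 * se)

  # 95% CI coverage of the true slope across replicated fixtures
  hits <- 0
  reps <- 200
  for (r in 1:reps) {
    d$delta_v <- -0.08 * log10(dist) + 0.25 + rnorm(length(dist), sd = sigma)
    ci <- confint(fit_distance_model(d)$fit)["log_dist", ]
    hits <- hits + (ci[1] <= -0.08 && -0.08 <= ci[2])
  }
  expect_gt(hits / reps, 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
  expect_lte(hits / reps, 1)
})

test_that("the calibration curve inverts within its fitted range only", {
  dils <- 10^c(-3, -2.5, -2, -1.5)
  deltas <- do.call(rbind, lapply(dils, function(dv) {
    data.frame(cycle_index = 1:3, delta_v = 0.1 * log10(dv) + 0.5,
               mean_on_v = NA, mean_off_v = NA, distance_cm = NA,
               dilution_vv = dv)
  }))
  curve <- fit_calibration(deltas)
  expect_equal(curve$r_squared, 1)
  # round trip through the inverse mapping
  for (dv in dils) {
    expect_equal(estimate_concentration(curve, 0.1 * log10(dv) + 0.5), dv,
                 tolerance = 1e-9)
  }
  expect_error(estimate_concentration(curve, 0.1), "refusing to extrapolate")
  expect_error(fit_calibration(deltas[deltas$dilution_vv > 1e-2, ]),
               "3 distinct")
})

test_that("a constant plume maps to a constant estimated concentration", {
  # treadmill fixture: deltas at several distances all produced by the same
  # airborne concentration (0.002 equivalent), inverted via a calibration
  # curve fitted on headspace dilutions
  dils <- 10^seq(-3.5, -1.5, by = 0.5)
  calib <- do.call(rbind, lapply(dils, function(dv) {
    data.frame(cycle_index = 1, delta_v = 0.12 * (log10(dv) + 4),
               mean_on_v = NA, mean_off_v = NA, distance_cm = NA,
               dilution_vv = dv)
  }))
  curve <- fit_calibration(calib)
  true_delta <- 0.12 * (log10(0.002) + 4)
  est <- estimate_concentration(curve,
                                true_delta + runif(6, -0.005, 0.005))
  expect_true(all(abs(log10(est) - log10(0.002)) < 0.5))
})

test_that("the synthetic trace follows the activation protocol", {
  tr <- synth_pid_trace() # protocol defaults
  expect_equal(length(tr$voltage_v), 10 * (45 + 60) * 500)
  expect_equal(sum(tr$valve_on), 10 * 45 * 500)
  tr2 <- synth_pid_trace(seed = 3, noise_sd = 0.01, cycles = 1)
  tr3 <- synth_pid_trace(seed = 3, noise_sd = 0.01, cycles = 1)
  expect_identical(tr2$voltage_v, tr3$voltage_v)
  expect_error(synth_pid_trace(on_s = -1), "> 0")
})
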