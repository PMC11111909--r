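make_trials <- function(conc, intensity, n_hit, n_target, n_fa = 0,
                        n_diluent = 50, lat_hit = 3) {
  tg <- data.frame(trial_index = seq_len(n_target),
                   stimulus_class = "target",
                   concentration_vv = conc, intensity_kmh = intensity,
                   outcome = rep(c("hit", "miss"),
                                 c(n_hit, n_target - n_hit)),
                   latency_s = rep(c(lat_hit, 10),
                                   c(n_hit, n_target - n_hit)),
                   start_s = (seq_len(n_target) - 1) * 20, end_s = 1)
  if (n_diluent == 0) return(tg)
  rbind(tg, data.frame(trial_index = n_target + seq_len(n_diluent),
                       stimulus_class = "diluent", concentration_vv = NA,
                       intensity_kmh = intensity,
                       outcome = rep(c("false_alert", "correct_rejection"),
                                     c(n_fa, n_diluent - n_fa)),
                       latency_s = 10, start_s = 0, end_s = 1))
}

test_that("hit and false-alert rates are exact cell ratios", {
  tr <- make_trials(1e-3, 8, n_hit = 45, n_target = 50, n_fa = 0)
  r <- outcome_rates(tr)
  expect_equal(r$hit_rate, 45 / 50)
  expect_equal(r$fa_rate, 0)
  expect_equal(r$cr_rate, 1)
  expect_equal(r$n_trials, 50)

  tr2 <- make_trials(1e-3, 8, n_hit = 13, n_target = 13, n_fa = 5)
  r2 <- outcome_rates(tr2)
  expect_equal(r2$hit_rate, 1)
  expect_equal(r2$fa_rate, 0.1)
  expect_error(outcome_rates(tr2[tr2$stimulus_class == "diluent", ]),
               "no target trials")
  tr_bad <- tr2
  tr_bad$outcome[1] <- "oops"
  expect_error(outcome_rates(tr_bad), "scored outcome")
})

test_that("diluent trials share one false-alert rate across concentrations", {
  tr <- rbind(make_trials(1e-3, 8, 10, 12, n_fa = 5),
              make_trials(1e-4, 8, 5, 13, n_diluent = 0))
  r <- outcome_rates(tr)
  expect_equal(nrow(r), 2)
  expect_equal(unique(r$fa_rate), 0.1)
  expect_equal(unique(r$n_noise), 50)
})

test_that("A' matches its defining identities and worked values", {
  expect_equal(a_prime(0.5, 0.5), 0.5)
  expect_equal(a_prime(1, 0), 1)
  expect_equal(a_prime(0.75, 0.25), 5 / 6)
  # complement symmetry
  for (i in 1:50) {
    h <- runif(1); f <- runif(1)
    expect_equal(a_prime(f, h), 1 - a_prime(h, f), tolerance = 1e-12)
  }
  expect_error(a_prime(1.2, 0), "\\[0, 1\\]")
})

test_that("B'' matches its worked values and antisymmetry", {
  expect_equal(b_double_prime(0.75, 0.25), 0)
  expect_equal(b_double_prime(0.9, 0.3), -0.4)
  expect_equal(b_double_prime(0.3, 0.9), 0.4)
  # zero bias whenever H + F = 1
  for (h in seq(0.05, 0.95, by = 0.1)) {
    expect_equal(b_double_prime(h, 1 - h), 0)
  }
  # antisymmetry wherever defined
  for (i in 1:50) {
    h <- runif(1); f <- runif(1)
    expect_equal(b_double_prime(h, f), -b_double_prime(f, h),
                 tolerance = 1e-12)
  }
  # degenerate rates: NaN with a warning, or corrected with counts
  expect_warning(v <- b_double_prime(1, 0), "undefined")
  expect_true(is.nan(v))
  corrected <- b_double_prime(1, 0, n_signal = 25, n_noise = 25)
  expect_equal(corrected, b_double_prime(1 - 1 / 50, 1 / 50))
})

test_that("the extreme-rate correction replaces only 0 and 1", {
  expect_equal(correct_extreme_rate(c(0, 0.3, 1), 25),
               c(1 / 50, 0.3, 1 - 1 / 50))
  expect_error(correct_extreme_rate(0.5, 0), "positive")
})

test_that("the threshold is the first concentration at or below 0.5", {
  rates <- data.frame(concentration_vv = 10^c(-2, -2.5, -3, -3.5),
                      intensity_kmh = 8,
                      hit_rate = c(1, 0.9, 0.8, 0.45))
  th <- determine_threshold(rates)
  expect_true(th$reached)
  expect_equal(th$threshold_concentration, 10^-3.5)
  expect_equal(th$threshold_intensity, 8)

  rates$hit_rate <- c(0.9, 0.5, 0.2, 0.1) # inclusive rule: 2nd qualifies
  expect_equal(determine_threshold(rates)$threshold_concentration, 10^-2.5)
  expect_equal(determine_threshold(rates, inclusive = FALSE)
               $threshold_concentration, 10^-3)

  rates$hit_rate <- c(1, 0.9, 0.8, 0.7)
  th2 <- determine_threshold(rates)
  expect_false(th2$reached)
  expect_true(is.na(th2$threshold_concentration))
  expect_true(all(is.na(th2$steps$dilution_step)))
})

test_that("dilution steps are log10 ratios to the threshold", {
  expect_equal(dilution_steps(0.01, 0.001), 1)
  expect_equal(dilution_steps(0.001, 0.001), 0)
  expect_equal(dilution_steps(10^-2.5, 10^-3), 0.5)
  expect_equal(dilution_steps(0.00316, 0.001), 0.5, tolerance = 1e-3)
  # exact linearity in log10 concentration
  for (i in 1:20) {
    cc <- 10^runif(1, -7, -1); th <- 10^runif(1, -7, -1)
    expect_equal(dilution_steps(cc * 10^0.5, th) - dilution_steps(cc, th),
                 0.5, tolerance = 1e-12)
  }
  expect_error(dilution_steps(-1, 0.001), "> 0")
})

test_that("trial and time bins use the documented boundaries", {
  tr <- make_trials(1e-3, 8, n_hit = 50, n_target = 100, n_diluent = 0)
  tb <- bin_results(tr, "trial_block_25")
  expect_equal(tb$bin, 1:4)
  # boundary convention: trial 75 -> block 3, trial 76 -> block 4
  tr75 <- tr[tr$trial_index %in% c(75, 76), ]
  expect_equal(bin_results(tr75, "trial_block_25")$bin, c(3, 4))
  # a trial starting at exactly 600 s falls in the second time bin
  tr600 <- tr[1:2, ]
  tr600$start_s <- c(599.9, 600.0)
  expect_equal(sort(bin_results(tr600, "time_bin_10min")$bin), c(1, 2))
})

test_that("a strong-decay subject stops hitting the lowest concentration", {
  b <- make_block_design(1, 1e-2)
  plan <- randomize_session(b, 8, seed = 31)
  dog <- dog_model(mu0 = -3.5, decay_rate = 0.2)
  sr <- run_session(plan, dog, seed = 32)
  tb <- bin_results(sr$trials, "trial_block_25")
  last <- tb[tb$bin == 4 & tb$concentration_vv == min(b$concentrations), ]
  expect_equal(last$hit_rate, 0)
})

test_that("censored latencies enter the means at 10 s", {
  tr <- make_trials(1e-3, 4, n_hit = 2, n_target = 3, n_diluent = 0)
  tr$latency_s[1:2] <- c(2, 4)
  expect_equal(latency_summary(tr)$mean_latency_s, (2 + 4 + 10) / 3)
  tr$outcome <- "miss"; tr$latency_s <- 10
  expect_equal(latency_summary(tr)$mean_latency_s, 10)
})

test_that("per-trial heart rate averages the overlapping samples", {
  hr <- data.frame(timestamp_s = c(100, 102, 104), bpm = c(100, 102, 104))
  trials <- data.frame(trial_index = 1, start_s = 99, end_s = 105)
  expect_equal(hr_per_trial(hr, trials)$hr_bpm, 102)

  # constant series gives the constant everywhere
  hr2 <- data.frame(timestamp_s = 0:100, bpm = 90)
  trials2 <- data.frame(trial_index = 1:3, start_s = c(0, 30, 60),
                        end_s = c(10, 40, 70))
  expect_true(all(hr_per_trial(hr2, trials2)$hr_bpm == 90))

  # a trial with no overlapping samples is missing, never zero
  trials3 <- data.frame(trial_index = 1, start_s = 10.2, end_s = 10.8)
  expect_true(is.na(hr_per_trial(hr2, trials3)$hr_bpm))

  # clock offset alignment
  hr3 <- data.frame(timestamp_s = 0:10, bpm = 70)
  trials4 <- data.frame(trial_index = 1, start_s = 1000, end_s = 1005)
  expect_equal(hr_per_trial(hr3, trials4, offset_s = 1000)$hr_bpm, 70)
  expect_error(hr_per_trial(data.frame(timestamp_s = c(2, 1), bpm = 1),
                            trials4), "sorted")
})
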