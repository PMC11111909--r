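test_that("the psychometric function behaves at its landmarks", {
  d <- dog_model(lapse = 0, decay_rate = 0)
  expect_equal(p_hit(d, 10^d$mu0, 4, 0), 0.5)
  expect_gt(p_hit(d, 10^(d$mu0 + 3), 4, 0), 0.999)
  expect_lt(p_hit(d, 10^(d$mu0 - 3), 4, 0), 0.001)

  # lapse scales the upper asymptote
  dl <- dog_model(lapse = 0.1, decay_rate = 0)
  expect_equal(p_hit(dl, 10^(dl$mu0 + 5), 4, 0), 0.9, tolerance = 1e-6)

  # monotone in concentration
  cc <- 10^seq(-7, -2, by = 0.25)
  expect_true(all(diff(p_hit(d, cc, 8, 15)) >= 0))
  expect_error(p_hit(d, 0, 4, 0), "> 0")
})

test_that("sensitivity decay is gated to moderate intensity and onset", {
  d <- dog_model(decay_rate = 0.1, decay_onset_min = 10)
  # 20 min at 8 km/h shifts the midpoint by exactly +1 log10 unit
  expect_equal(p_hit(d, 10^(d$mu0 + 1), 8, 20), p_hit(d, 10^d$mu0, 8, 0))
  # no decay before onset or at low intensity
  expect_equal(p_hit(d, 1e-4, 8, 10), p_hit(d, 1e-4, 8, 0))
  expect_equal(p_hit(d, 1e-4, 4, 30), p_hit(d, 1e-4, 4, 0))
  # non-increasing in elapsed time at 8 km/h
  p_t <- sapply(seq(0, 30, 2), function(t) p_hit(d, 1e-4, 8, t))
  expect_true(all(diff(p_t) <= 0))
})

test_that("latencies follow the concentration and intensity structure", {
  d <- dog_model(latency_base_s = 2, latency_conc_slope = 0,
                 latency_intensity_offset_s = 0, latency_sdlog = 0)
  expect_equal(sample_latency(d, 1e-4, 4, seed = 1), 2)

  d2 <- dog_model(latency_sdlog = 0)
  for (cc in 10^c(-2, -3.5, -5)) {
    expect_gt(sample_latency(d2, cc, 8, seed = 1),
              sample_latency(d2, cc, 4, seed = 1))
  }
  # truncation to the response window
  d3 <- dog_model(latency_base_s = 9, latency_sdlog = 1)
  lat <- sample_latency(d3, 1e-6, 8, seed = 7, n = 500)
  expect_true(all(lat <= 10 & lat >= 0.4))
})

test_that("sampled responses reproduce the programmed rates", {
  d <- dog_model(lapse = 0, decay_rate = 0)
  spec_hi <- list(stimulus_class = "target",
                  concentration_vv = 10^(d$mu0 + 4))
  # certain detection emits a criterion-satisfying poke every time
  for (s in 1:20) {
    pk <- sample_response(d, spec_hi, 4, 0, seed = s)
    expect_equal(nrow(pk), 1)
    expect_gte(pk$duration_s, 0.4)
  }
  # zero false-alert rate emits nothing on diluent trials
  d0 <- dog_model(fa_rate_low = 0, fa_rate_mod = 0)
  for (s in 1:20) {
    expect_equal(nrow(sample_response(d0, list(stimulus_class = "diluent"),
                                      4, 0, seed = s)), 0)
  }
  # binomial sampling: alert rate within 3 SE of p_hit
  spec_mid <- list(stimulus_class = "target",
                   concentration_vv = 10^(d$mu0 + 0.25))
  p <- p_hit(d, spec_mid$concentration_vv, 4, 0)
  n <- 2000
  hits <- sum(vapply(seq_len(n), function(s) {
    nrow(sample_response(d, spec_mid, 4, 0, seed = s)) > 0
  }, logical(1)))
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("heart-rate series are stationary AR(1) around the intensity mean", {
  d <- dog_model()
  flat <- generate_hr(dog_model(hr_sd_low = 0, hr_sd_mod = 0), 8, 2,
                      seed = 1)
  expect_true(all(flat$bpm == 121.2))
  expect_equal(nrow(flat), 120)

  hr <- generate_hr(d, 8, duration_min = 100, seed = 42)
  n <- nrow(hr)
  # AR(1) mean standard error: sd * sqrt((1+ar)/(1-ar)) / sqrt(n)
  se <- d$hr_sd_mod * sqrt((1 + d$hr_ar) / (1 - d$hr_ar)) / sqrt(n)
  expect_lt(abs(mean(hr$bpm) - 121.2), 3 * se)
  expect_lt(abs(sd(hr$bpm) - d$hr_sd_mod), 0.15 * d$hr_sd_mod)

  hr4 <- generate_hr(d, 4, duration_min = 100, seed = 43)
  se4 <- d$hr_sd_low * sqrt((1 + d$hr_ar) / (1 - d$hr_ar)) / sqrt(n)
  expect_lt(abs(mean(hr4$bpm) - 95.9), 3 * se4)

  # white-noise check: ar = 0 gives negligible lag-1 autocorrelation
  w <- generate_hr(dog_model(hr_ar = 0), 8, 100, seed = 44)$bpm
  r1 <- cor(w[-1], w[-length(w)])
  expect_lt(abs(r1), 3 / sqrt(length(w)))
})

test_that("a full study runs until the stopping rule fires", {
  # strong decay: threshold falls inside block 2's range
  st <- generate_study(dog_model(mu0 = -4.7, decay_rate = 0.2), seed = 5)
  expect_equal(st$stopped_after_block, 2)
  expect_equal(length(st$sessions), 8)
  expect_equal(length(st$hr), 8)

  # a perfect detector never meets the criterion through block 3
  st2 <- generate_study(perfect_detector(), seed = 6)
  expect_true(is.na(st2$stopped_after_block))
  expect_equal(length(st2$sessions), 12)

  # byte-identical regeneration from the same seed
  st3 <- generate_study(dog_model(mu0 = -4.7, decay_rate = 0.2), seed = 5)
  expect_identical(study_trials(st), study_trials(st3))
  expect_identical(st$hr, st3$hr)
})

test_that("sensitivity three steps above threshold stays high", {
  st <- generate_study(dog_model(mu0 = -4.75, decay_rate = 0, lapse = 0.02),
                       seed = 21)
  rates <- outcome_rates(study_trials(st))
  th <- determine_threshold(rates)
  expect_true(th$reached)
  steps <- dilution_steps(rates$concentration_vv,
                          th$threshold_concentration)
  high <- rates$a_prime[steps >= 2.5]
  expect_true(length(high) > 0)
  expect_true(all(high > 0.85))
})
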