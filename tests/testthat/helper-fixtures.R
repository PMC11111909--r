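# Shared fixtures and independent oracles, built in code at test time.

# Random sorted, non-overlapping poke stream (uses the ambient RNG stream).
# Event times live on a 10 ms lattice offset by 5 ms, so no poke boundary,
# criterion instant, or window close ever falls within half a step of a
# 1 ms simulator tick: every stream is unambiguously resolvable at both
# the analytic and the stepped scorer's resolution.
random_poke_stream <- function(max_pokes = 4, mean_gap = 4) {
  k <- sample(0:max_pokes, 1)
  if (k == 0) return(poke_events())
  durs <- round(runif(k, 0.05, 1.2), 2) + 0.005
  gaps <- round(rexp(k, rate = 1 / mean_gap) + 0.01, 2) + 0.005
  onsets <- cumsum(gaps) + c(0, cumsum(durs))[seq_len(k)]
  poke_events(onsets, durs)
}

# Independent A' oracle: area under the one-point ROC computed from the two
# corner triangles of the unit square, 1 - (F/H + (1-H)/(1-F))/4 for H >= F
# and by the complement symmetry otherwise. An algebraically different
# route from the packaged sign/max formula.
a_prime_oracle <- function(H, F) {
  if (isTRUE(all.equal(H, F)) || H == F) return(0.5)
  if (H > F) 1 - 0.25 * (F / H + (1 - H) / (1 - F))
  else 1 - a_prime_oracle(F, H)
}

# Subject that responds to everything instantly (and never false-alerts).
perfect_detector <- function() {
  dog_model(mu0 = -20, lapse = 0, fa_rate_low = 0, fa_rate_mod = 0,
            decay_rate = 0, latency_base_s = 0.5, latency_conc_slope = 0,
            latency_intensity_offset_s = 0, latency_sdlog = 0)
}

# Subject that never pokes at all.
null_responder <- function() {
  dog_model(lapse = 1, fa_rate_low = 0, fa_rate_mod = 0, decay_rate = 0)
}
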