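---
title: "Models and methods behind treadsniff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind treadsniff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treadsniff)
```

treadsniff implements the computational machinery of a Go/no-go olfactory
threshold paradigm in which dogs are tested while exercising on a
treadmill-mounted olfactometer. This vignette is the package's account of
its models, its defaults, and the reasoning behind the design choices that
the protocol itself leaves open.

## The trial state machine

A trial starts at odor-valve activation. The subject's nose pokes
(infrared beam breaks) arrive as non-overlapping timed events, and the
scorer applies these rules:

- An **alert** is scored at the first instant a *single continuous* poke
  reaches the criterion duration (`poke_criterion_s`, default 0.4 s)
  inside the active response window. The criterion is deliberately not
  summed across pokes: the behavioral definition is holding the nose in
  the port, so two 0.3 s pokes do not add up to an alert.
- The initial window is `window_s` (10 s). A **sub-criterion poke** that
  starts inside the initial window extends the window once by
  `extension_s` (10 s), for a maximum of 20 s. A poke still below
  criterion at the instant the initial window closes counts as such a
  sub-criterion poke and earns the same extension — physically, the beam
  is still broken when the timer expires.
- If no alert occurs by the (possibly extended) window end, the trial is
  an **all-clear**. Target + alert = hit, target + all-clear = miss,
  diluent + alert = false alert, diluent + all-clear = correct rejection.
  Hits always reinforce; pre-assigned correct rejections reinforce;
  misses and false alerts never do.

Three points were genuinely open and are resolved as follows, each
configurable through `trial_params()`:

- **Extension multiplicity.** The protocol allows "up to an additional
  10 s"; we implement a single extension (`max_extensions = 1`). A
  sub-criterion poke *during* the extension grants nothing further — the
  alternative (chained extensions) would make trial duration unbounded.
- **Diluent-trial extensions.** The all-clear is defined as 10 s without
  pokes, which leaves sub-criterion pokes on diluent trials undefined. We
  run the identical machine for both stimulus classes
  (`extend_diluent = TRUE`) so go and no-go trials share one code path.
- **Stopping-rule comparison.** The block rule is stated once as "below
  50%" and once as "at or below 0.5"; we adopt the inclusive form
  (`stop_rule_inclusive = TRUE`), which matches the threshold definition
  ("first concentration with ≤ 0.5 hit rate") exactly.

Latency is the alert instant on the odor-onset clock; for all-clear trials
it is censored at exactly 10 s, the convention used for non-responses in
the analysis. When an alert lands inside the extension its latency can
exceed 10 s; we report the true instant rather than clipping it, since the
censoring convention applies to non-responses only.

The session clock starts at the first trial's odor onset. The 2-minute
treadmill warm-up is recorded as metadata and excluded, because
duration-dependent effects are expressed against time on task. Each trial
contributes its scored duration plus a 10 s inter-trial interval; the
reported session duration runs to the last trial's termination with no
trailing interval.

The event-driven scorer is verified against `score_trial_stepped()`, a
deliberately naive 1 ms time-stepped simulation of the same rules
(implemented in C++ so that tens of thousands of streams are cheap). The
test-suite streams are drawn on a 10 ms lattice offset 5 ms from the
stepped grid, so no poke boundary or criterion instant ever falls within
half a step of a simulator tick — every generated stream is resolvable
identically at both resolutions, and the agreement check is exact rather
than probabilistic.

## The constrained scheduler

Each 100-trial session is randomized in ten disjoint sets of ten trials:
five diluent trials per set, each of the block's four concentrations at
least once, and one concentration doubled to fill the tenth slot. The
protocol states the resulting counts (12–13 per concentration per session)
but not how the doubled concentration is chosen; uniform per-set choice
would produce counts outside that range. We therefore allocate the ten
doublings in a balanced way — two concentrations doubled three times and
two doubled twice, assignment and within-set order seeded and uniform —
which is the least structured scheme consistent with the printed counts.

Correct-rejection reinforcement is pre-assigned to exactly
`round(0.40 × 50) = 20` diluent trials, chosen uniformly.

## The synthetic dog

`dog_model()` is a generative stand-in for a subject, used to exercise and
test every downstream stage. Its components:

- **Psychometric function**: lapse-adjusted cumulative Gaussian in log10
  concentration, `p = (1 − λ) Φ((log10 c − μ(t)) / σ)` (logistic available
  via `psychometric = "logistic"`). The cumulative Gaussian is the
  standard psychophysical choice; σ is in log10 units.
- **Exercise decay**: `μ(t) = μ0 + δ · max(0, t − t0)` at 8 km/h only;
  stable at 4 km/h. Linear-after-onset is the simplest form consistent
  with near-ceiling performance in the first 10 minutes and collapse at
  threshold-level concentrations by 20–30 minutes; a saturating
  exponential is available via `decay_form = "exponential"`.
- **False alerts**: per-diluent-trial probability with two intensity
  levels and no concentration dependence, because the paradigm's bias
  measure is roughly constant across concentrations but shifts with
  speed.
- **Latency**: expectation `base + slope · (−log10 c) + offset ·
  1[8 km/h]`, i.e. slower responses to fainter odors and at the trot,
  with truncated log-normal noise on [0.4, 10] s. No latency distribution
  is prescribed anywhere in the protocol; the log-normal family is our
  choice (right-skewed, positive), flagged as such.
- **Heart rate**: stationary lag-1 autoregressive series at 1 Hz around
  the intensity's mean — steady-state exercise, no within-session trend.

Default parameter values are illustrative, set once from printed group
summaries rather than fitted to any animal: midpoint 10^-4.5 v/v
(mid-range of the design), σ = 0.35 so that a half-log step spans a large
but not saturating probability change, lapse 0.02 (the reported miss
proportion at criterion), false-alert rates 0.07/0.03 at low/moderate
intensity (overall rate near 0.05 with a go bias at the walk and a no-go
bias at the trot), heart-rate means 95.9 and 121.2 bpm with SDs 21.6 and
6.6 bpm and AR(1) coefficient 0.9. The decay default is δ = 0.1 log10
units/min after t0 = 10 min. That pair reproduces the full qualitative
pattern: detection at the threshold concentration is intact through
10 minutes, passes 50% during the 10–20 minute bin, and is essentially
absent past 20 minutes, while the highest tested concentration (1.5 log
units above) stays high through a whole session. A faster decay would
drag the highest concentration down by session end, which the paradigm's
reference results rule out.

One deviation from a flat parameter list: the heart-rate SD is
intensity-specific (`hr_sd_low`, `hr_sd_mod`) because the printed SDs at
the two speeds differ by a factor of three; a single SD slot cannot
represent both.

What the generator does **not** emulate: olfactometer airflow physics,
sniffing dynamics, trial-to-trial serial dependence in behavior,
reinforcement-driven learning or motivation drift, inter-session carryover
or fatigue, and recovery after exercise ends. Passing tests therefore show
that the analysis machinery is correct and that the study design can
detect an intensity × duration interaction of the built-in form — not that
real dogs behave like the model.

## Threshold, dilution steps, and aggregation

The detection threshold is the first concentration, scanning from the
highest tested downward, with hit rate at or below 0.5; if no cell
qualifies the result is an explicit "not reached", never a substituted
value. By default either intensity may determine it, matching the stopping
rule; per-intensity thresholds are available via the `intensity` argument.
Dilution steps rescale concentration to `log10(c / threshold)`, so 0 is
threshold and each half-log dilution is 0.5 steps. (The protocol's own
worked example contains an apparent typo — 0.316 v/v against a 0.001
threshold is 2.5 steps by the stated formula, not 1.5; 0.0316 fits. We
implement the formula.)

Rates pool trials, not session-wise rates, across the sessions of a cell:
per-session concentration counts are unequal (12 vs 13), so averaging
per-session rates would weight trials unevenly. Diluent trials belong to
no concentration, so every concentration cell at an intensity shares the
false-alert rate pooled over that intensity's diluent trials — this is
what makes per-dilution-step A′ computable from shared blanks.

For the signal-detection indices, H or F at exactly 0 or 1 makes B″
undefined and pins A′ at its bounds; sessions near threshold genuinely
produce such cells (no hits in the last trial block). We apply the
standard 1/(2N) replacement (0 → 1/(2N), 1 → 1 − 1/(2N)) before the
formulas, switchable off via `correction = FALSE`. B″ is implemented as
the plain Grier ratio `[H(1−H) − F(1−F)] / [H(1−H) + F(1−F)]`, which is
antisymmetric under swapping H and F (negative = go bias, positive = no-go
bias); a sign-prefixed variant circulating in the literature is symmetric
instead, and disagrees with the antisymmetry property the index is meant
to have below the H = F diagonal. The A′ implementation is tested to
1e-12 against an algebraically independent geometric form of the one-point
ROC area, `1 − ¼ (F/H + (1−H)/(1−F))` for H ≥ F.

Binning follows half-open conventions: trial blocks split indices 1–100 as
1–25 / 26–50 / 51–75 / 76–100, and time bins split trial *start* times
into [0, 600), [600, 1200), [1200, …) seconds. Per-trial heart rate
averages the 1 Hz samples whose timestamps fall within [start, end] of
each trial; a trial too short to contain a sample is reported missing,
never zero, and a clock offset option covers recordings whose origin is
not the first odor onset.

## PID calibration pipeline

Odor delivery validation records photoionization-detector voltage at
500 Hz through 45 s on / 60 s off valve cycles. The pipeline:

- **Filtering**: low-pass Butterworth at `cutoff_scalar` × Nyquist
  (default 0.01, i.e. 2.5 Hz at 500 Hz). The filter order is unspecified
  by the protocol; we use order 2 applied forward–backward for zero phase.
  The trace is extended by odd reflection before filtering — the
  underlying `filtfilt` zero-pads internally, and at this cutoff the IIR
  transient has an e-folding of roughly 1/(π · cutoff) samples, so the pad
  length is 12/cutoff samples to push edge error below 1e-10 and keep the
  DC gain exactly 1 in practice.
- **Cycle deltas**: mean on-voltage minus mean off-voltage per complete
  on/off cycle. Per-cycle subtraction bounds slow-drift error by
  drift × half the cycle length instead of letting it accumulate across
  the trace; negative deltas are reported, not clipped, since they
  diagnose baseline drift. The first 5 s after each valve transition are
  excluded (`settle_s`) to skip rise and clearance transients — the
  protocol is silent on settling, and 5 s is several rise time constants
  for this sensor class. Truncated final cycles are dropped with a
  message.
- **Distance model**: least squares of ΔV on log10(distance), fitted on
  per-cycle deltas by default (ten per distance) rather than per-distance
  means; both carry the same point estimate, but per-cycle fitting keeps
  the replicate variance visible.
- **Calibration curve**: linear in log10 liquid dilution (the functional
  form is unstated; linear-in-log is the conventional PID response model
  over a modest range), strictly monotone by construction, inverted for
  concentration estimates. Queries outside the fitted ΔV range raise an
  error rather than extrapolate.

## Reproducibility and numerical conventions

Every stochastic function takes a `seed`; seeded calls save and restore
the caller's RNG state, and sub-seeds for independent stages are derived
arithmetically in doubles to stay inside 31-bit integer range. Identical
configurations write byte-identical dataset directories, and each
`manifest.json` records the seed and a hash of the full configuration.

Test problem sizes are chosen to exercise the asymptotics while keeping a
full suite run around a minute: 1,000 seeded sessions for the scheduler
counts, 10,000 poke streams for state-machine agreement, 1,000 random
rate pairs for the A′ oracle, 50 seeded studies for threshold recovery
(decay off — with decay on, the either-intensity threshold is the decayed
moderate-intensity one, elevated above the generating midpoint *by
design*, so decay-on recovery of μ0 would test the wrong quantity), and
100 paired sessions for the decay-specificity sign test.

## Limitations

The package analyzes and simulates; it does not control hardware (valves,
treadmill, heart-rate straps) and does not model the tracer-odorant
substitution used in delivery validation. The synthetic dog is a tool for
verifying machinery and exploring design sensitivity, not a calibrated
animal model; with n = 3 subjects in the motivating paradigm, its defaults
should be read as one plausible dog, not a population.
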