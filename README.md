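# treadsniff

Go/no-go olfactory detection-threshold testing for dogs exercising on a
treadmill-mounted olfactometer: scheduling, trial scoring, simulation, and
analysis.

## The problem

Working dogs often have to detect faint odors *while* exercising, yet
olfactory thresholds are almost always measured at rest. In the
olfacto-treadmill paradigm a dog walks (4 km/h, low intensity) or trots
(8 km/h, moderate intensity) on a treadmill while an olfactometer presents
100 Go/no-go trials per session: on half the trials one of four half-log
target-odor dilutions, on the other half the diluent alone. A sustained
nose poke of at least 0.4 s within a 10 s response window (extended once by
10 s after a shorter poke) scores an alert; 10 s without a criterion poke
scores an all-clear. Blocks of four sessions descend through overlapping
concentration ranges (10^-2 … 10^-3.5, 10^-3.5 … 10^-5, 10^-5 … 10^-6.5 v/v)
until some concentration's hit rate falls to 0.5 or below at either
intensity — that concentration is the dog's detection threshold.

This package implements the full computational side of that paradigm for
researchers in canine olfaction and exercise physiology:

- **Scheduler** — constrained sets-of-ten randomization (5 diluent trials
  per set of 10, every concentration at least once per set, balanced
  doubling giving 12–13 presentations per concentration per session, 40%
  pre-assigned correct-rejection reinforcement).
- **Trial scorer** — the event-driven poke-criterion / window-extension
  state machine, validated against an independent 1 ms time-stepped
  simulator.
- **Analytics** — hit and false-alert rates, censored latencies,
  non-parametric signal detection (A′ sensitivity, B″ bias), threshold
  determination, dilution-step rescaling
  (step = log10(concentration / threshold)), 25-trial-block and 10-minute
  binning, per-trial heart-rate averaging.
- **Synthetic dog** — a generative model whose psychometric midpoint
  degrades with exercise duration at moderate intensity only, so every
  stage of the pipeline runs and is testable without animal data.
- **PID calibration** — photoionization-detector trace processing for odor
  delivery validation: zero-phase Butterworth low-pass at 0.01 × Nyquist,
  per-cycle on/off baseline subtraction, ΔV ~ log10(distance) regression,
  and an invertible calibration curve over liquid dilutions.

## The model at the core

Per-trial detection probability follows a lapse-adjusted cumulative
Gaussian in log10 concentration,

    p(c, t) = (1 − λ) Φ( (log10 c − μ(t)) / σ ),

where the midpoint drifts under moderate-intensity exercise,

    μ(t) = μ0 + δ · max(0, t − t0) · 1[intensity = 8 km/h],

with δ the decay rate (log10 units/min) and t0 the onset (min). Sensitivity
and bias are the standard non-parametric indices

    A′ = 0.5 + sgn(H−F) [(H−F)² + |H−F|] / [4 max(H,F) − 4HF],
    B″ = [H(1−H) − F(1−F)] / [H(1−H) + F(1−F)],

with an optional 1/(2N) extreme-rate correction.

## Worked example

```r
library(treadsniff)

dog <- dog_model(mu0 = -4.5)          # midpoint 10^-4.5 v/v
st  <- generate_study(dog, seed = 11) # blocks of 4 sessions until stop
st
#> <study> 8 sessions over 2 block(s); stopping rule fired after block 2

rates <- outcome_rates(study_trials(st))
th    <- determine_threshold(rates)
th
#> <threshold_result> threshold 0.0001 v/v (determined at 8 km/h)

rates$dilution_step <- dilution_steps(rates$concentration_vv,
                                      th$threshold_concentration)
head(rates[, c("concentration_vv", "intensity_kmh", "hit_rate",
               "mean_latency_s", "a_prime", "b_double_prime",
               "dilution_step")], 8)
#>   concentration_vv intensity_kmh hit_rate mean_latency_s a_prime b_double_prime dilution_step
#> 1         0.010000             4    0.958           2.71   0.977        -0.0367           2.0
#> 2         0.010000             8    0.885           3.97   0.960         0.5027           2.0
#> 3         0.003162             4    0.960           2.74   0.978        -0.0562           1.5
#> 4         0.003162             8    1.000           3.34   0.986        -0.2833           1.5
#> 5         0.001000             4    1.000           2.52   0.983        -0.3736           1.0
#> 6         0.001000             8    0.833           4.36   0.946         0.6088           1.0
#> 7         0.000316             4    1.000           2.84   0.986        -0.6315           0.5
#> 8         0.000316             8    0.688           5.69   0.906         0.7283           0.5
```

The simulated dog stops in block 2 with a threshold of 10^-4 v/v,
determined at 8 km/h: hit rates stay near ceiling at the walk but sag at
the trot as concentration approaches threshold, latencies lengthen at the
trot at every concentration, and B″ shifts from a go bias (negative, more
false alerts) at 4 km/h toward a no-go bias (positive, more misses) at
8 km/h while A′ stays high except near threshold — the behavioral signature
the generative model is built to emulate.

Datasets round-trip through delimited text:

```r
simulate_study(study_config(dog = list(mu0 = -4.5), seed = 11), "data/")
report <- analyze_study("data/", out_dir = "report/")
```

A thin command-line front-end over the same functions ships in
`inst/scripts/treadsniff.R` (subcommands `simulate`, `analyze`,
`calibrate-pid`).

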