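Package: treadsniff
Title: Olfactory Detection Thresholds During Treadmill Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for Go/no-go olfactory detection-threshold testing of dogs
    exercising on a treadmill-mounted olfactometer. Provides a constrained
    stimulus scheduler (sets-of-ten randomization at 50% target frequency),
    an event-driven trial-scoring state machine with poke-criterion and
    window-extension logic, a descending-block threshold procedure with a
    hit-rate stopping rule, non-parametric signal-detection analytics
    (A-prime, B-double-prime), dilution-step rescaling, trial- and time-binned
    summaries, per-trial heart-rate averaging, and a photoionization-detector
    (PID) calibration pipeline (Butterworth low-pass filtering, per-cycle
    baseline subtraction, log-distance regression, calibration curves). A
    generative model of a simulated subject with exercise-intensity- and
    duration-dependent sensitivity decay lets every stage run without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    jsonlite,
    rlang,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
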