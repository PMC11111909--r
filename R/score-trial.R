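#' Construct a set of nose-poke events
#'
#' A poke event is one continuous infrared beam break, recorded relative to
#' odor onset. Events must be strictly positive in duration, sorted by
#' onset, and non-overlapping.
#'
#' @param onset_s Numeric vector of onsets (s from odor onset, >= 0).
#' @param duration_s Numeric vector of durations (s, > 0).
#' @return A `poke_events` data frame with columns `onset_s`, `duration_s`.
#' @examples
#' poke_events(c(1.2, 5.0), c(0.2, 0.8))
#' @export
poke_events <- function(onset_s = numeric(0), duration_s = numeric(0)) {
  if (length(onset_s) != length(duration_s)) {
    stop_bad_arg("onset_s and duration_s must have equal length")
  }
  if (any(duration_s <= 0)) stop_bad_arg("poke durations must be > 0")
  if (any(onset_s < 0)) stop_bad_arg("poke onsets must be >= 0")
  if (is.unsorted(onset_s, strictly = FALSE)) {
    stop_bad_arg("poke events must be sorted by onset")
  }
  if (length(onset_s) > 1L &&
      any(onset_s[-1L] < (onset_s + duration_s)[-length(onset_s)])) {
    stop_bad_arg("poke events must not overlap")
  }
  structure(
    data.frame(onset_s = as.numeric(onset_s),
               duration_s = as.numeric(duration_s)),
    class = c("poke_events", "data.frame")
  )
}

#' Score one Go/no-go trial from its poke events
#'
#' Event-driven implementation of the trial state machine. An alert is
#' scored at the first instant a single continuous poke reaches the
#' criterion duration (default 0.4 s) inside the active response window. A
#' sub-criterion poke that starts inside the initial window extends the
#' window once by `extension_s` (so the maximum window is 20 s under the
#' defaults); a poke still below criterion when the initial window closes
#' counts as such a sub-criterion poke. If no alert occurs by the (possibly
#' extended) window end the trial is an all-clear. Outcomes follow the
#' stimulus class: target + alert = hit, target + all-clear = miss,
#' diluent + alert = false alert, diluent + all-clear = correct rejection.
#' Hits are always reinforced; correct rejections are reinforced when
#' pre-assigned; misses and false alerts never are.
#'
#' Latency is the alert instant on the odor-onset clock (it can exceed the
#' initial window when the extension is used); for all-clear trials latency
#' is censored at exactly `window_s` (10 s under the defaults), as in the
#' analysis convention for non-responses.
#'
#' @param spec One row of a [randomize_session()] plan (or any list with
#'   `stimulus_class` and `cr_reinforced`).
#' @param pokes A [poke_events()] object.
#' @param params A [trial_params()] object.
#' @return A list of class `trial_result`: `outcome`, `latency_s`,
#'   `responded`, `reinforced`, `window_end_s` (active window close,
#'   odor-onset clock), `rel_end_s` (trial termination: alert instant for
#'   responses, window close otherwise).
#' @examples
#' p <- trial_params()
#' spec <- list(stimulus_class = "target", cr_reinforced = NA)
#' score_trial(spec, poke_events(3.0, 0.6), p)$latency_s       # 3.4
#' score_trial(spec, poke_events(), p)$outcome                 # miss
#' # sub-criterion poke extends the window; alert lands inside it:
#' score_trial(spec, poke_events(c(9.8, 14), c(0.2, 0.5)), p)$latency_s
#' @export
score_trial <- function(spec, pokes = poke_events(), params = trial_params()) {
  if (!inherits(pokes, "poke_events")) {
    pokes <- poke_events(pokes$onset_s, pokes$duration_s)
  }
  target <- identical(spec$stimulus_class, "target")
  crit <- params$poke_criterion_s
  w <- params$window_s
  w_init <- params$window_s
  ext_left <- params$max_extensions
  may_extend <- target || params$extend_diluent
  alert_t <- NA_real_

  for (i in seq_len(nrow(pokes))) {
    onset <- pokes$onset_s[[i]]
    dur <- pokes$duration_s[[i]]
    if (onset >= w) break # window already closed before this poke began
    crit_t <- onset + crit
    if (dur >= crit && crit_t <= w) {
      alert_t <- crit_t
      break
    }
    # Sub-criterion so far (too short, or criterion instant past the close):
    # grants the one extension if it started inside the initial window.
    if (ext_left > 0L && may_extend && onset < w_init) {
      w <- w_init + params$extension_s
      ext_left <- ext_left - 1L
      if (dur >= crit && crit_t <= w) {
        alert_t <- crit_t
        break
      }
    }
  }

  responded <- !is.na(alert_t)
  outcome <- if (target) {
    if (responded) "hit" else "miss"
  } else {
    if (responded) "false_alert" else "correct_rejection"
  }
  reinforced <- switch(outcome,
    hit = TRUE,
    miss = FALSE,
    false_alert = FALSE,
    correct_rejection = isTRUE(spec$cr_reinforced)
  )
  structure(
    list(
      outcome = outcome,
      latency_s = if (responded) alert_t else params$window_s,
      responded = responded,
      reinforced = reinforced,
      window_end_s = w,
      rel_end_s = if (responded) alert_t else w
    ),
    class = "trial_result"
  )
}

#' Millisecond-stepped reference scorer
#'
#' A brute-force, time-stepped simulation of the same window/extension
#' logic, advancing a clock in `dt` steps and tracking the continuous poke
#' run length. Independent of the event-driven [score_trial()] code path;
#' used to validate it. Latency is resolved to within one step.
#'
#' @param pokes A [poke_events()] object.
#' @param params A [trial_params()] object.
#' @param target Is this a target trial (affects only whether extension is
#'   allowed when `extend_diluent` is off)?
#' @param dt Step size in seconds. Default 0.001 (1 ms).
#' @return List with `responded` (logical) and `latency_s` (alert instant,
#'   or `window_s` if no alert).
#' @export
score_trial_stepped <- function(pokes, params = trial_params(),
                                target = TRUE, dt = 0.001) {
  if (!inherits(pokes, "poke_events")) {
    pokes <- poke_events(pokes$onset_s, pokes$duration_s)
  }
  res <- ms_score_trial(
    pokes$onset_s, pokes$duration_s,
    params$poke_criterion_s, params$window_s, params$extension_s,
    as.integer(params$max_extensions) *
      as.integer(target || params$extend_diluent),
    dt
  )
  list(responded = res$responded,
       latency_s = if (res$responded) res$latency_s else params$window_s)
}
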