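#' Trial-level timing and scoring parameters
#'
#' Bundles the Go/no-go trial parameters used by the scheduler and the
#' trial-scoring state machine. Defaults match the final-phase protocol:
#' a 0.4 s continuous nose-poke criterion, a 10 s response window that a
#' sub-criterion poke extends once by a further 10 s, a 10 s inter-trial
#' interval, and 40% reinforcement of correct rejections.
#'
#' @param poke_criterion_s Continuous beam-break duration (s) scored as an
#'   alert. Default 0.4.
#' @param window_s Initial response window (s) from odor onset. Default 10.
#' @param extension_s Extension (s) granted after a sub-criterion poke inside
#'   the initial window. Default 10.
#' @param max_extensions Number of extensions a trial may receive. The
#'   protocol allows "up to an additional 10 s", i.e. one. Default 1.
#' @param extend_diluent Should sub-criterion pokes also extend diluent
#'   (no-go) trials? Default `TRUE`, so go and no-go trials share one state
#'   machine.
#' @param iti_s Inter-trial interval (s) appended after each trial.
#'   Default 10.
#' @param cr_reinforcement_rate Proportion of correct rejections pre-assigned
#'   for reinforcement. Default 0.40.
#' @param stop_rule_inclusive Should the block stopping rule fire at a hit
#'   rate exactly equal to 0.5 (`TRUE`, the threshold definition "first
#'   concentration with <= 0.5 hit rate") or strictly below (`FALSE`)?
#'   Default `TRUE`.
#' @param warmup_min Treadmill warm-up (min) before the first trial; recorded
#'   as metadata and excluded from the session clock. Default 2.
#'
#' @return An object of class `trial_params` (a named list).
#' @examples
#' trial_params()
#' trial_params(cr_reinforcement_rate = 0.5)
#' @export
trial_params <- function(poke_criterion_s = 0.4,
                         window_s = 10,
                         extension_s = 10,
                         max_extensions = 1L,
                         extend_diluent = TRUE,
                         iti_s = 10,
                         cr_reinforcement_rate = 0.4,
                         stop_rule_inclusive = TRUE,
                         warmup_min = 2) {
  if (poke_criterion_s <= 0) stop_bad_arg("poke_criterion_s must be > 0")
  if (window_s <= 0 || extension_s < 0 || iti_s < 0) {
    stop_bad_arg("window_s must be > 0 and extension_s, iti_s >= 0")
  }
  if (cr_reinforcement_rate < 0 || cr_reinforcement_rate > 1) {
    stop_bad_arg("cr_reinforcement_rate must be in [0, 1]")
  }
  structure(
    list(
      poke_criterion_s = poke_criterion_s,
      window_s = window_s,
      extension_s = extension_s,
      max_extensions = as.integer(max_extensions),
      extend_diluent = isTRUE(extend_diluent),
      iti_s = iti_s,
      cr_reinforcement_rate = cr_reinforcement_rate,
      stop_rule_inclusive = isTRUE(stop_rule_inclusive),
      warmup_min = warmup_min
    ),
    class = "trial_params"
  )
}

#' @export
print.trial_params <- function(x, ...) {
  cat("<trial_params>\n")
  cat(sprintf("  poke criterion: %.2f s | window: %g s (+%g s x %d)\n",
              x$poke_criterion_s, x$window_s, x$extension_s,
              x$max_extensions))
  cat(sprintf("  ITI: %g s | CR reinforcement: %d%% | stop rule: hit rate %s 0.5\n",
              x$iti_s, round(100 * x$cr_reinforcement_rate),
              if (x$stop_rule_inclusive) "<=" else "<"))
  invisible(x)
}
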