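#' Randomize a 100-trial session under the sets-of-ten constraints
#'
#' Builds the stimulus schedule for one testing session: 100 trials at 50%
#' target frequency, randomized in ten disjoint sets of ten trials. Each set
#' holds exactly five diluent trials and each of the block's four
#' concentrations at least once; one concentration is presented twice to
#' fill the tenth slot. The doubled concentration is allocated in a balanced
#' way across the ten sets (each concentration doubled two or three times),
#' which yields the protocol's 12–13 presentations per concentration per
#' session. Correct-rejection reinforcement flags are pre-assigned at the
#' configured rate.
#'
#' @param design A [make_block_design()] object.
#' @param intensity Session treadmill speed in km/h, 4 or 8.
#' @param seed Integer seed; identical seeds give identical plans.
#' @param params A [trial_params()] object.
#'
#' @return A `session_plan`: data frame with columns `trial_index`,
#'   `stimulus_class` (`"target"`/`"diluent"`), `concentration_vv` (`NA` for
#'   diluent trials), `cr_reinforced` (logical, `NA` for target trials), and
#'   attributes `intensity`, `block_index`, `concentrations`, `params`,
#'   `seed`.
#' @examples
#' plan <- randomize_session(make_block_design(1, 1e-2), intensity = 8,
#'                           seed = 1)
#' table(plan$stimulus_class)
#' table(plan$concentration_vv[plan$stimulus_class == "target"])
#' @export
randomize_session <- function(design, intensity, seed = NULL,
                              params = trial_params()) {
  stopifnot(inherits(design, "block_design"))
  if (!intensity %in% c(4, 8)) stop_bad_arg("intensity must be 4 or 8 km/h")
  conc <- design$concentrations
  if (length(unique(conc)) != 4L) {
    stop_bad_arg("design must carry 4 distinct concentrations")
  }
  plan <- with_seed(seed, {
    # Which concentration fills the tenth slot of each of the 10 sets:
    # two concentrations are doubled 3x and two 2x (2+2+3+3 = 10), so
    # per-session counts are 10 + {2,3} = 12 or 13.
    thrice <- sample(4L, 2L)
    doubles <- sample(c(rep(thrice, 3L), rep(setdiff(1:4, thrice), 2L)))
    stim <- integer(0)
    for (s in seq_len(10L)) {
      # 0 codes diluent; 1..4 code the concentrations.
      set <- c(rep(0L, 5L), 1:4, doubles[[s]])
      stim <- c(stim, sample(set))
    }
    stim
  })
  df <- data.frame(
    trial_index = seq_along(plan),
    stimulus_class = ifelse(plan == 0L, "diluent", "target"),
    concentration_vv = ifelse(plan == 0L, NA_real_, conc[pmax(plan, 1L)]),
    cr_reinforced = NA,
    stringsAsFactors = FALSE
  )
  attr(df, "intensity") <- intensity
  attr(df, "block_index") <- design$block_index
  attr(df, "concentrations") <- conc
  attr(df, "params") <- params
  attr(df, "seed") <- seed
  class(df) <- c("session_plan", "data.frame")
  assign_cr_reinforcement(df, rate = params$cr_reinforcement_rate,
                          seed = derive_seed(seed, 1L))
}

#' Pre-assign correct-rejection reinforcement flags
#'
#' Flags exactly `round(rate * n_diluent)` diluent trials for reinforcement
#' should the subject correctly reject them, chosen uniformly at random.
#' Target trials keep `NA` (correct alerts are always reinforced).
#'
#' @param plan A [randomize_session()] plan.
#' @param rate Proportion of diluent trials to flag, in \[0, 1\].
#'   Default 0.40.
#' @param seed Integer seed.
#' @return The plan with its `cr_reinforced` column replaced.
#' @examples
#' plan <- randomize_session(make_block_design(1, 1e-2), 4, seed = 2)
#' sum(assign_cr_reinforcement(plan, 0.4, seed = 3)$cr_reinforced,
#'     na.rm = TRUE)
#' @export
assign_cr_reinforcement <- function(plan, rate = 0.4, seed = NULL) {
  stopifnot(inherits(plan, "session_plan"))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1) {
    stop_bad_arg("rate must be a single number in [0, 1]")
  }
  idx <- which(plan$stimulus_class == "diluent")
  n_flag <- round(rate * length(idx))
  chosen <- with_seed(seed, sample(idx, n_flag))
  plan$cr_reinforced <- NA
  plan$cr_reinforced[idx] <- FALSE
  plan$cr_reinforced[chosen] <- TRUE
  plan
}

#' Validate the sets-of-ten invariants of a session plan
#'
#' Checks the scheduling contract: 50/50 diluent/target split, five diluent
#' trials in every disjoint decade, every concentration at least once per
#' decade, per-session concentration counts of 12 or 13, and the configured
#' number of reinforcement flags.
#'
#' @param plan A `session_plan`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_session_plan <- function(plan) {
  stopifnot(inherits(plan, "session_plan"))
  if (nrow(plan) != 100L) stop_bad_arg("plan must have 100 trials")
  if (sum(plan$stimulus_class == "diluent") != 50L) {
    stop_bad_arg("plan must have exactly 50 diluent trials")
  }
  decade <- (plan$trial_index - 1L) %/% 10L
  for (d in unique(decade)) {
    sel <- plan[decade == d, ]
    if (sum(sel$stimulus_class == "diluent") != 5L) {
      stop_bad_arg("decade %d must contain exactly 5 diluent trials", d + 1L)
    }
    if (length(unique(sel$concentration_vv[sel$stimulus_class == "target"])) != 4L) {
      stop_bad_arg("decade %d must present each concentration at least once",
                   d + 1L)
    }
  }
  counts <- table(plan$concentration_vv[plan$stimulus_class == "target"])
  if (!all(counts %in% c(12L, 13L))) {
    stop_bad_arg("per-session concentration counts must be 12 or 13")
  }
  params <- attr(plan, "params")
  expected <- round(params$cr_reinforcement_rate * 50L)
  if (sum(plan$cr_reinforced, na.rm = TRUE) != expected) {
    stop_bad_arg("expected %d reinforced correct-rejection flags", expected)
  }
  invisible(TRUE)
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> block %d, %g km/h, %d trials\n",
              attr(x, "block_index"), attr(x, "intensity"), nrow(x)))
  cat("  concentrations (v/v): ",
      paste(signif(attr(x, "concentrations"), 4), collapse = ", "),
      "\n", sep = "")
  NextMethod()
}
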