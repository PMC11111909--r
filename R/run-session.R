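#' Run a scheduled session against a simulated dog
#'
#' Couples the scheduler, the generative subject model, and the trial
#' scorer. The session clock starts at the first trial's odor onset (the
#' treadmill warm-up is metadata only); each trial occupies its scored
#' duration plus the inter-trial interval, and the elapsed time at each
#' trial's onset is passed to the dog model so duration-dependent decay
#' acts within the session. The reported session duration runs from the
#' first odor onset to the last trial's termination (no trailing ITI).
#'
#' @param plan A [randomize_session()] plan.
#' @param dog A [dog_model()].
#' @param seed Optional integer seed (one stream drives all trials).
#' @return A `session_result`: list with `plan`, `trials` (data frame: one
#'   row per trial with `trial_index`, `stimulus_class`, `concentration_vv`,
#'   `intensity_kmh`, `outcome`, `latency_s`, `reinforced`, `start_s`,
#'   `end_s`), `pokes` (data frame `trial_index`, `onset_s`, `duration_s`,
#'   onsets relative to odor onset), and `duration_min`.
#' @examples
#' plan <- randomize_session(make_block_design(1, 1e-2), 8, seed = 1)
#' sr <- run_session(plan, dog_model(), seed = 2)
#' table(sr$trials$outcome)
#' @export
run_session <- function(plan, dog, seed = NULL) {
  stopifnot(inherits(plan, "session_plan"), inherits(dog, "dog_model"))
  params <- attr(plan, "params")
  intensity <- attr(plan, "intensity")
  n <- nrow(plan)
  outcome <- character(n)
  latency <- numeric(n)
  reinforced <- logical(n)
  start_s <- numeric(n)
  end_s <- numeric(n)
  poke_rows <- vector("list", n)

  with_seed(seed, {
    t <- 0
    for (i in seq_len(n)) {
      spec <- list(stimulus_class = plan$stimulus_class[[i]],
                   concentration_vv = plan$concentration_vv[[i]],
                   cr_reinforced = plan$cr_reinforced[[i]])
      pk <- sample_response(dog, spec, intensity, elapsed_min = t / 60)
      res <- score_trial(spec, pk, params)
      outcome[i] <- res$outcome
      latency[i] <- res$latency_s
      reinforced[i] <- res$reinforced
      start_s[i] <- t
      end_s[i] <- t + res$rel_end_s
      if (nrow(pk) > 0) {
        poke_rows[[i]] <- data.frame(trial_index = plan$trial_index[[i]],
                                     onset_s = pk$onset_s,
                                     duration_s = pk$duration_s)
      }
      t <- end_s[i] + params$iti_s
    }
  })

  trials <- data.frame(
    trial_index = plan$trial_index,
    stimulus_class = plan$stimulus_class,
    concentration_vv = plan$concentration_vv,
    intensity_kmh = intensity,
    outcome = outcome,
    latency_s = latency,
    reinforced = reinforced,
    start_s = start_s,
    end_s = end_s,
    stringsAsFactors = FALSE
  )
  pokes <- if (all(vapply(poke_rows, is.null, logical(1)))) {
    data.frame(trial_index = integer(0), onset_s = numeric(0),
               duration_s = numeric(0))
  } else {
    do.call(rbind, poke_rows[!vapply(poke_rows, is.null, logical(1))])
  }
  structure(
    list(plan = plan, trials = trials, pokes = pokes,
         duration_min = end_s[n] / 60,
         intensity = intensity,
         block_index = attr(plan, "block_index"),
         seed = seed),
    class = "session_result"
  )
}

#' @export
print.session_result <- function(x, ...) {
  tab <- table(factor(x$trials$outcome,
                      levels = c("hit", "miss", "false_alert",
                                 "correct_rejection")))
  cat(sprintf("<session_result> block %d, %g km/h, %.1f min\n",
              x$block_index, x$intensity, x$duration_min))
  cat(sprintf("  hits %d | misses %d | false alerts %d | correct rejections %d\n",
              tab[["hit"]], tab[["miss"]], tab[["false_alert"]],
              tab[["correct_rejection"]]))
  invisible(x)
}

#' Per-cell hit rates of a block of sessions
#'
#' Pools trials (not session-wise rates) across the sessions of one block
#' and returns the hit rate for each concentration at each intensity.
#' Pooling trials is the appropriate aggregation because per-session
#' concentration counts are unequal (12 vs 13).
#'
#' @param sessions List of [run_session()] results from one block.
#' @return Data frame `concentration_vv`, `intensity_kmh`, `n_trials`,
#'   `n_hits`, `hit_rate`, sorted by descending concentration.
#' @export
block_hit_rates <- function(sessions) {
  trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  tg <- trials[trials$stimulus_class == "target", ]
  agg <- aggregate(cbind(n_hits = outcome == "hit", n_trials = 1) ~
                     concentration_vv + intensity_kmh, data = tg, FUN = sum)
  agg$hit_rate <- agg$n_hits / agg$n_trials
  agg[order(-agg$concentration_vv, agg$intensity_kmh), ]
}

#' Block stopping rule
#'
#' Testing stops once any concentration at either exercise intensity shows
#' a hit rate at or below 0.5 (the inclusive comparison matches the
#' threshold definition "first concentration with <= 0.5 hit rate"; set
#' `inclusive = FALSE` for a strict < 0.5 rule).
#'
#' @param block_rates A [block_hit_rates()] data frame covering all 4
#'   concentrations at both intensities.
#' @param inclusive Fire at exactly 0.5? Default `TRUE`.
#' @return Logical: should testing stop after this block?
#' @examples
#' rates <- expand.grid(concentration_vv = 10^-(2:5 / 2) * 1e-1,
#'                      intensity_kmh = c(4, 8))
#' rates$hit_rate <- 0.9
#' stop_rule(rates)          # FALSE
#' rates$hit_rate[8] <- 0.45
#' stop_rule(rates)          # TRUE
#' @export
stop_rule <- function(block_rates, inclusive = TRUE) {
  needed <- c("concentration_vv", "intensity_kmh", "hit_rate")
  if (!all(needed %in% names(block_rates))) {
    stop_bad_arg("block_rates needs columns %s", paste(needed, collapse = ", "))
  }
  cells <- unique(block_rates[, c("concentration_vv", "intensity_kmh")])
  if (length(unique(cells$concentration_vv)) < 4L ||
      length(unique(cells$intensity_kmh)) < 2L) {
    stop_bad_arg(
      "block_rates must cover all 4 concentrations at both intensities")
  }
  if (any(is.na(block_rates$hit_rate))) {
    stop_bad_arg("block_rates contains missing hit rates")
  }
  if (inclusive) any(block_rates$hit_rate <= 0.5)
  else any(block_rates$hit_rate < 0.5)
}

#' Simulate a complete descending-block threshold study
#'
#' Runs blocks of four 100-trial sessions (two per intensity, in the
#' block's counterbalanced order) through the scheduler, the dog model, and
#' the scorer, evaluating the stopping rule after each block, until the
#' rule fires or the block list is exhausted.
#'
#' @param dog A [dog_model()].
#' @param blocks List of [make_block_design()] objects (default:
#'   [block_sequence()] of 3 blocks from 10^-2 down).
#' @param seed Integer seed driving schedule randomization and behavior.
#' @param params A [trial_params()].
#' @param hr Also generate a heart-rate series per session? Default `TRUE`.
#' @return A `study` object: list with `sessions` (list of
#'   `session_result`), `hr` (list of HR data frames, same order),
#'   `block_rates` (list of [block_hit_rates()] per completed block),
#'   `stopped_after_block` (integer, `NA` if the rule never fired), `dog`,
#'   `params`, `seed`.
#' @examples
#' st <- generate_study(dog_model(), seed = 7)
#' st$stopped_after_block
#' @export
generate_study <- function(dog, blocks = block_sequence(3L), seed = NULL,
                           params = trial_params(), hr = TRUE) {
  stopifnot(inherits(dog, "dog_model"))
  sessions <- list()
  hr_list <- list()
  block_rates <- list()
  stopped <- NA_integer_
  k <- 0L
  for (b in blocks) {
    block_sessions <- list()
    for (j in seq_along(b$intensity_sequence)) {
      k <- k + 1L
      s_seed <- derive_seed(seed, 10L * b$block_index + j)
      plan <- randomize_session(b, b$intensity_sequence[[j]],
                                seed = s_seed, params = params)
      sr <- run_session(plan, dog, seed = derive_seed(s_seed, 1L))
      block_sessions[[j]] <- sr
      sessions[[k]] <- sr
      if (hr) {
        hr_list[[k]] <- generate_hr(dog, sr$intensity,
                                    duration_min = sr$duration_min,
                                    seed = derive_seed(s_seed, 2L))
      }
    }
    rates <- block_hit_rates(block_sessions)
    block_rates[[b$block_index]] <- rates
    if (stop_rule(rates, inclusive = params$stop_rule_inclusive)) {
      stopped <- b$block_index
      break
    }
  }
  structure(
    list(sessions = sessions, hr = hr_list, block_rates = block_rates,
         stopped_after_block = stopped, dog = dog, params = params,
         seed = seed),
    class = "study"
  )
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf("<study> %d sessions over %d block(s); stopping rule %s\n",
              length(x$sessions), length(x$block_rates),
              if (is.na(x$stopped_after_block)) "never fired"
              else sprintf("fired after block %d", x$stopped_after_block)))
  invisible(x)
}

#' Pool the trial tables of a study or session list
#'
#' @param x A `study` object or list of `session_result`s.
#' @return One data frame of scored trials with added `session` and
#'   `block_index` columns.
#' @export
study_trials <- function(x) {
  sessions <- if (inherits(x, "study")) x$sessions else x
  do.call(rbind, lapply(seq_along(sessions), function(i) {
    tr <- sessions[[i]]$trials
    tr$session <- i
    tr$block_index <- sessions[[i]]$block_index
    tr
  }))
}
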