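# Internal helpers shared across modules.

#' Evaluate an expression under a local, seeded RNG state
#'
#' Saves and restores `.Random.seed` so seeded package functions never
#' perturb the caller's random-number stream. With `seed = NULL` the
#' expression runs on the ambient stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct 31-bit sub-seed from a base seed, for independent
# stages. Arithmetic in doubles (exact far beyond 2^31) to avoid integer
# overflow when sub-seeds are themselves re-derived.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coefficient of determination, computed directly so degenerate (perfect or
# zero-variance) fits stay quiet and bounded in [0, 1].
r_squared <- function(fit, y) {
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  max(0, min(1, 1 - ss_res / ss_tot))
}

stop_bad_arg <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)
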