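#' Non-parametric sensitivity A'
#'
#' Computes the non-parametric signal-detection sensitivity index A' from a
#' hit rate `H` and false-alert rate `F` (Stanislaw & Todorov's
#' formulation):
#' \deqn{A' = 0.5 + \mathrm{sgn}(H-F)\,\frac{(H-F)^2 + |H-F|}{4\max(H,F) - 4HF}.}
#' A' is 0.5 when `H = F` (no discrimination), 1 when `H = 1, F = 0`
#' (perfect performance), and satisfies `A'(F, H) = 1 - A'(H, F)`.
#'
#' @param H Hit rate(s) in \[0, 1\].
#' @param F False-alert rate(s) in \[0, 1\].
#' @return A' in \[0, 1\] (vectorized).
#' @examples
#' a_prime(0.5, 0.5)   # 0.5
#' a_prime(1, 0)       # 1
#' a_prime(0.75, 0.25) # 5/6
#' @export
a_prime <- function(H, F) {
  if (any(H < 0 | H > 1 | F < 0 | F > 1)) {
    stop_bad_arg("H and F must be in [0, 1]")
  }
  d <- H - F
  denom <- 4 * pmax(H, F) - 4 * H * F
  out <- ifelse(d == 0, 0.5,
                0.5 + sign(d) * (d^2 + abs(d)) / denom)
  # H = F already handled; denom is 0 only when H = F in {0, 1}.
  out
}

#' Non-parametric response bias B''
#'
#' Computes the non-parametric bias index B'' (Grier's ratio):
#' \deqn{B'' = \frac{H(1-H) - F(1-F)}{H(1-H) + F(1-F)}.}
#' B'' ranges over \[-1, 1\]; 0 means no bias (it is exactly 0 whenever
#' `H + F = 1`), negative values a go (yes) bias, positive values a no-go
#' bias, and swapping the two rates flips the sign:
#' `B''(H, F) = -B''(F, H)`. The denominator vanishes when both rates are
#' extreme (0 or 1);
#' supply the trial counts `n_signal`/`n_noise` to apply the standard
#' 1/(2N) extreme-rate correction in that case, otherwise `NaN` is returned
#' with a warning.
#'
#' @inheritParams a_prime
#' @param n_signal,n_noise Optional trial counts behind `H` and `F`, used
#'   only to rescue degenerate (extreme-rate) inputs.
#' @return B'' in \[-1, 1\] (vectorized).
#' @examples
#' b_double_prime(0.75, 0.25) # 0
#' b_double_prime(0.9, 0.3)   # -0.4
#' b_double_prime(0.3, 0.9)   # +0.4
#' @export
b_double_prime <- function(H, F, n_signal = NULL, n_noise = NULL) {
  if (any(H < 0 | H > 1 | F < 0 | F > 1)) {
    stop_bad_arg("H and F must be in [0, 1]")
  }
  degenerate <- (H %in% c(0, 1)) & (F %in% c(0, 1))
  if (any(degenerate)) {
    if (!is.null(n_signal) && !is.null(n_noise)) {
      H <- ifelse(degenerate, correct_extreme_rate(H, n_signal), H)
      F <- ifelse(degenerate, correct_extreme_rate(F, n_noise), F)
    } else {
      warning("B'' undefined for extreme H and F; returning NaN ",
              "(supply n_signal/n_noise for the 1/(2N) correction)")
    }
  }
  hh <- H * (1 - H)
  ff <- F * (1 - F)
  ifelse(hh + ff == 0, NaN, (hh - ff) / (hh + ff))
}

#' Extreme-rate (1/(2N)) correction
#'
#' Replaces a rate of 0 with `1/(2n)` and a rate of 1 with `1 - 1/(2n)`,
#' the standard adjustment before computing signal-detection indices from
#' finite trial counts; intermediate rates are untouched.
#'
#' @param rate Rate(s) in \[0, 1\].
#' @param n Trial count(s) behind each rate.
#' @return Corrected rate(s).
#' @examples
#' correct_extreme_rate(c(0, 0.5, 1), 25)
#' @export
correct_extreme_rate <- function(rate, n) {
  if (any(n <= 0)) stop_bad_arg("trial counts must be positive")
  ifelse(rate == 0, 1 / (2 * n), ifelse(rate == 1, 1 - 1 / (2 * n), rate))
}
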