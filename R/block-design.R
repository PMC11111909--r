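#' Build a descending block of four half-log odor concentrations
#'
#' A testing block covers four liquid dilutions spaced in half-log (10^0.5)
#' steps, spanning 1.5 log10 units, paired with an alternating
#' exercise-intensity sequence over its four sessions. Consecutive blocks
#' overlap: block k+1's top concentration equals block k's bottom, so a
#' subject always has one previously detectable concentration in range.
#'
#' @param block_index Positive integer block number.
#' @param top_concentration Highest v/v dilution in the block (e.g. `1e-2`
#'   for the first block).
#' @param order Intensity sequence over the four sessions, `"8-4-8-4"` or
#'   `"4-8-4-8"` (km/h).
#'
#' @return A `block_design`: list with `block_index`, `concentrations`
#'   (length-4 numeric, descending), `intensity_sequence` (length-4 numeric).
#' @examples
#' make_block_design(1, 1e-2, "8-4-8-4")$concentrations
#' # block 2 starts at block 1's bottom:
#' make_block_design(2, 10^-3.5)$concentrations
#' @export
make_block_design <- function(block_index, top_concentration,
                              order = c("8-4-8-4", "4-8-4-8")) {
  order <- match.arg(order)
  if (length(block_index) != 1L || block_index < 1) {
    stop_bad_arg("block_index must be a single integer >= 1")
  }
  if (!is.numeric(top_concentration) || length(top_concentration) != 1L ||
      !is.finite(top_concentration) || top_concentration <= 0) {
    stop_bad_arg("top_concentration must be a single positive number")
  }
  conc <- top_concentration * 10^(-0.5 * (0:3))
  speeds <- if (order == "8-4-8-4") c(8, 4, 8, 4) else c(4, 8, 4, 8)
  structure(
    list(
      block_index = as.integer(block_index),
      concentrations = conc,
      intensity_sequence = speeds
    ),
    class = "block_design"
  )
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design> block %d\n", x$block_index))
  cat("  concentrations (v/v): ",
      paste(signif(x$concentrations, 4), collapse = ", "), "\n", sep = "")
  cat("  intensity sequence (km/h): ",
      paste(x$intensity_sequence, collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Chain descending blocks for a full threshold study
#'
#' Builds up to `n_blocks` overlapping blocks starting from
#' `top_concentration`, alternating the session intensity order between
#' blocks (counterbalancing), with block k+1 topped at block k's bottom.
#'
#' @param n_blocks Number of blocks.
#' @param top_concentration Top v/v dilution of block 1. Default `1e-2`.
#' @param first_order Intensity order of block 1. Default `"8-4-8-4"`.
#' @return List of `block_design`.
#' @examples
#' sapply(block_sequence(3), function(b) min(b$concentrations))
#' @export
block_sequence <- function(n_blocks = 3L, top_concentration = 1e-2,
                           first_order = c("8-4-8-4", "4-8-4-8")) {
  first_order <- match.arg(first_order)
  orders <- rep(c(first_order,
                  setdiff(c("8-4-8-4", "4-8-4-8"), first_order)),
                length.out = n_blocks)
  out <- vector("list", n_blocks)
  top <- top_concentration
  for (k in seq_len(n_blocks)) {
    out[[k]] <- make_block_design(k, top, orders[[k]])
    top <- min(out[[k]]$concentrations)
  }
  out
}
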