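# Deterministic seed derivation: counter-based splitting so that every
# stochastic sub-task (trial replicate, arm-specific draw stream) gets its own
# reproducible substream without touching global RNG state between tasks.
#
# Arithmetic stays in doubles below 2^53, results in [1, 2^31 - 2], so derived
# seeds are always valid 32-bit integer seeds for set.seed().

.SEED_MOD <- 2147483647  # 2^31 - 1, prime

#' Derive a child seed from a master seed
#'
#' Deterministic Lehmer-style mixing of a master seed with a stream index.
#' Used throughout the simulation engine so that per-trial and per-arm draws
#' are reproducible and independent of evaluation order.
#'
#' @param seed Master seed (integer-valued).
#' @param index Nonnegative stream counter.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 2)
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  s <- (abs(seed) %% .SEED_MOD)
  x <- (s * 48271 + index * 16807 + 1) %% .SEED_MOD
  # one more multiplicative round to decorrelate adjacent indices
  x <- (x * 69621) %% .SEED_MOD
  as.integer(ifelse(x == 0, 1, x))
}

#' Number of subjects per arm at the interim look
#'
#' @param n_total Planned subjects per arm.
#' @param interim_fraction Fraction of enrolment at the single interim look.
#' @return Integer interim sample size per arm, `ceiling(fraction * n_total)`.
#' @keywords internal
interim_n <- function(n_total, interim_fraction) {
  as.integer(ceiling(interim_fraction * n_total))
}
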