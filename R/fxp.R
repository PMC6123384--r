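# Fixed-point primitives.  These are the only arithmetic operations the
# simulator core performs besides saturating addition: a corrected signed
# shift, a leak with guaranteed one-LSB decay, randomized rounding, a
# four-uniform normal approximation, and a Bernoulli blank-out draw.  All
# stochastic primitives are pure functions of (seed, id, tick): the same key
# always yields the same draw, which is what makes simulations reproducible
# and independent of core partitioning.

.check_exp <- function(e) {
  if (any(abs(e) > 15L)) stop("shift exponent out of range: |exponent| must be <= 15")
}

.check_width <- function(x, bits) {
  smax <- 2^(bits - 1) - 1
  smin <- -2^(bits - 1)
  if (any(x > smax | x < smin)) {
    stop(sprintf("value outside the declared %d-bit width [%d, %d]", bits, smin, smax))
  }
}

#' Corrected signed power-of-two shift
#'
#' Computes `x * 2^exponent` using only bit shifts. Down-shifts truncate
#' toward zero (`sign(x) * (|x| >> -exponent)`), which differs from a plain
#' arithmetic right shift exactly on negative inputs of small magnitude: an
#' arithmetic shift of `-2^a'` by `a > a'` positions yields -1, whereas a
#' multiplication by `2^-a` should yield 0. Up-shifts saturate at the
#' declared width instead of wrapping.
#'
#' @param exponent integer shift exponent(s), in `[-15, 15]`; the first
#'   argument is always the exponent.
#' @param x integer value(s) within the declared width.
#' @param bits state width in bits (default 16, range -32768..32767).
#' @return integer vector of shifted values, saturated to the width.
#' @examples
#' fx_shift(3, 1)    # 8
#' fx_shift(-3, -4)  # 0, where floor(-4 / 8) would be -1
#' fx_shift(-2, 5)   # 1 (truncation toward zero)
#' @export
fx_shift <- function(exponent, x, bits = 16L) {
  .check_exp(exponent)
  .check_width(x, bits)
  fx_shift_cpp(as.integer(exponent), as.integer(x), as.integer(bits))
}

#' Leak increment toward rest
#'
#' The contribution a power-of-two coupling coefficient makes to a state
#' update: `sign * fx_shift(exponent, x)`, except that a leak-signed
#' contribution (coefficient opposing the sign of `x`) whose shifted
#' magnitude truncates to zero returns `-sign(x)` instead, guaranteeing at
#' least one LSB of decay toward the resting state. A zero coefficient sign
#' is the exact-zero sentinel and contributes nothing. Iterating
#' `x <- x + fx_leak(-1, e, x)` therefore reaches exactly 0 from any state
#' and stays there.
#'
#' @param sign coefficient sign(s) in `{-1, 0, 1}`.
#' @param exponent integer shift exponent(s) in `[-15, 15]`.
#' @param x integer state value(s).
#' @param bits state width in bits.
#' @return integer vector of increments.
#' @examples
#' fx_leak(-1, -2, 100)  # -25
#' fx_leak(-1, -4, 8)    # -1: minimum one-LSB decay
#' fx_leak(0, 5, 123)    # 0: zero sentinel
#' @export
fx_leak <- function(sign, exponent, x, bits = 16L) {
  .check_exp(exponent)
  if (any(!sign %in% c(-1L, 0L, 1L))) stop("coefficient sign must be -1, 0 or +1")
  .check_width(x, bits)
  fx_leak_cpp(as.integer(sign), as.integer(exponent), as.integer(x), as.integer(bits))
}

#' Randomized rounding of a low-precision update
#'
#' Interprets the `r` least significant bits of `|delta|` as a probability:
#' the result is `|delta| >> r`, incremented by one with probability
#' `p / 2^r` where `p` is the integer formed by the discarded bits, with the
#' sign of `delta` re-applied. The expectation equals `delta / 2^r` exactly,
#' which is what makes coarse weight updates unbiased. `r = 0` returns
#' `delta` unchanged.
#'
#' @param delta signed integer update(s).
#' @param r number of probability bits, `>= 0`.
#' @param seed global seed of the random stream.
#' @param id,tick key components (e.g. synapse index and tick); draws are
#'   deterministic functions of `(seed, id, tick)`.
#' @return integer vector of rounded updates.
#' @export
fx_round <- function(delta, r, seed = 1L, id = 0L, tick = 0L) {
  if (r < 0) stop("r must be >= 0")
  fx_round_cpp(as.integer(delta), as.integer(r), as.integer(seed),
               as.integer(id), as.integer(tick))
}

#' Integer noise with programmable power-of-two variance
#'
#' Zero-mean additive state noise with variance approximately
#' `2^var_exp`, built as the sum of four independent uniform integer draws
#' (the standard digital approximation of a normal sequence from four
#' uniform generators). Deterministic given `(seed, id, tick, comp)`.
#'
#' @param var_exp variance exponent; `NA` disables the source (returns 0).
#' @param seed,id,tick,comp stream key components.
#' @return integer vector of draws.
#' @export
fx_noise <- function(var_exp, seed = 1L, id = 0L, tick = 0L, comp = 0L) {
  n <- max(length(id), length(tick), length(comp))
  if (is.na(var_exp)) return(integer(n))
  fx_noise_cpp(as.integer(var_exp), as.integer(seed), as.integer(id),
               as.integer(tick), as.integer(comp))
}

#' Half-width of the uniform components of the noise generator
#'
#' The integer `a` such that the sum of four uniforms on `[-a, a]` has
#' variance closest to `2^var_exp`.
#'
#' @param var_exp variance exponent.
#' @return integer half-width.
#' @export
fx_noise_halfwidth <- function(var_exp) {
  fx_noise_halfwidth_cpp(as.integer(var_exp))
}

#' Bernoulli blank-out draw
#'
#' Multiplicative synaptic stochasticity: each delivery survives with
#' probability `p_num / 2^p_den_exp`. Deterministic given
#' `(seed, id, tick)`.
#'
#' @param p_num integer numerator, `0 <= p_num <= 2^p_den_exp`.
#' @param p_den_exp denominator exponent.
#' @param seed,id,tick stream key components.
#' @return integer vector of 0/1 masks.
#' @export
fx_blankout <- function(p_num, p_den_exp, seed = 1L, id = 0L, tick = 0L) {
  if (p_num < 0 || p_num > 2^p_den_exp) {
    stop("p_num must lie in [0, 2^p_den_exp]")
  }
  fx_blankout_cpp(as.integer(p_num), as.integer(p_den_exp), as.integer(seed),
                  as.integer(id), as.integer(tick))
}
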