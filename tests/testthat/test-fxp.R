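# Fixed-point primitives: the corrected shift, the leak operator,
# randomized rounding, the four-uniform noise source and blank-out draws.

test_that("corrected shift matches exact power-of-two products and truncates toward zero", {
  expect_identical(fx_shift(3L, 1L), 8L)
  expect_identical(fx_shift(0L, 12345L), 12345L)
  expect_identical(fx_shift(-2L, 5L), 1L)       # trunc(5/4), not floor
  expect_identical(fx_shift(-2L, -5L), -1L)     # trunc(-5/4) = -1, floor would be -2
  # oracle: truncation toward zero of x * 2^e in floating point
  set.seed(4)
  x <- sample(-32768:32767, 500)
  for (e in -6:-1) {
    expect_identical(fx_shift(e, x), as.integer(trunc(x * 2^e)))
  }
  # saturating upshift, never wraparound
  expect_identical(fx_shift(4L, 30000L), 32767L)
  expect_identical(fx_shift(4L, -30000L), -32768L)
})

test_that("shift of -2^a' by a > a' positions is exactly zero where plain shifts give -1", {
  for (a in 1:15) {
    for (ap in 0:(a - 1)) {
      expect_identical(fx_shift(-a, -2^ap), 0L)
      expect_identical(floor(-2^ap / 2^a), -1) # the arithmetic-shift defect corrected
    }
  }
})

test_that("leak operator guarantees one-LSB decay toward rest and honours the zero sentinel", {
  expect_identical(fx_leak(-1L, -2L, 100L), -25L)
  expect_identical(fx_leak(-1L, -4L, 8L), -1L)  # magnitude truncates to 0 -> minimum decay
  expect_identical(fx_leak(-1L, -4L, -8L), 1L)
  expect_identical(fx_leak(0L, 7L, 31000L), 0L)
  expect_identical(fx_leak(1L, -4L, 8L), 0L)    # growth-signed truncation is not forced
})

test_that("iterated leak reaches exactly zero with strictly decreasing magnitude and stays there", {
  set.seed(11)
  for (e in 1:6) {
    ok <- TRUE
    for (x0 in c(sample(-32768:32767, 20), -32768L, 32767L, 1L, -1L)) {
      x <- as.integer(x0)
      prev <- abs(x)
      steps <- 0L
      while (x != 0L && ok) {
        x <- x + fx_leak(-1L, -e, x)
        if (x != 0L && abs(x) >= prev) ok <- FALSE
        prev <- abs(x)
        steps <- steps + 1L
        if (steps > 40000L) ok <- FALSE
      }
      if (x + fx_leak(-1L, -e, x) != 0L) ok <- FALSE # absorbing at rest
    }
    expect_true(ok, label = paste("leak-to-rest at exponent", e))
  }
})

test_that("randomized rounding is deterministic per key and unbiased in expectation", {
  expect_identical(fx_round(64L, 6L), 1L)    # low bits zero: deterministic
  expect_identical(fx_round(0L, 6L), 0L)
  expect_identical(fx_round(123L, 0L), 123L) # r = 0 passes through
  expect_identical(fx_round(1L, 6L, seed = 5L, id = 3L, tick = 9L),
                   fx_round(1L, 6L, seed = 5L, id = 3L, tick = 9L))
  n <- 100000L
  for (delta in c(1L, -7L, 63L, -64L, 200L)) {
    draws <- fx_round(delta, 6L, seed = 2L, id = 0:(n - 1L), tick = 0L)
    expect_true(all(draws %in% c(sign(delta) * (abs(delta) %/% 64),
                                 sign(delta) * (abs(delta) %/% 64 + 1L))))
    p <- (abs(delta) %% 64) / 64
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(draws) - delta / 64), max(3 * se, 1e-12))
  }
})

test_that("noise draws are zero-mean with programmable power-of-two variance", {
  expect_identical(fx_noise(NA), 0L)
  n <- 100000L
  for (v in c(4L, 6L, 8L)) {
    z <- fx_noise(v, seed = 3L, id = 0:(n - 1L))
    sdz <- sqrt(2^v)
    expect_lt(abs(mean(z)), 3 * sdz / sqrt(n))
    expect_lt(abs(stats::var(z) - 2^v) / 2^v, 0.1)
  }
})

test_that("blank-out draws hit their dyadic probability", {
  n <- 100000L
  expect_true(all(fx_blankout(256L, 8L, id = 0:999) == 1L))
  expect_true(all(fx_blankout(0L, 8L, id = 0:999) == 0L))
  b <- fx_blankout(128L, 8L, seed = 2L, id = 0:(n - 1L))
  expect_lt(abs(mean(b) - 0.5), 3 * 0.5 / sqrt(n))
})

test_that("stochastic primitives are pure functions of their key", {
  a <- fx_noise(6L, seed = 9L, id = 0:99, tick = 5L)
  b <- fx_noise(6L, seed = 9L, id = 0:99, tick = 5L)
  expect_identical(a, b)
  expect_false(identical(a, fx_noise(6L, seed = 10L, id = 0:99, tick = 5L)))
  expect_false(identical(a, fx_noise(6L, seed = 9L, id = 0:99, tick = 6L)))
})
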