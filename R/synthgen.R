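# Deterministic synthetic input generators: Poisson spike schedules,
# the bars-and-stripes pattern set, and noise-embedded repeating spike
# patterns.  All generators are pure functions of (spec, seed).

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Poisson spike trains from a rate schedule
#'
#' Generates spike events as independent Bernoulli draws per (tick,
#' channel) with probability `rate / 1000` (one tick is nominally 1 ms),
#' the standard discrete approximation of a Poisson process at these rates.
#'
#' @param schedule `data.frame` with columns `from`, `to` (tick range,
#'   inclusive start, exclusive end), `ch_from`, `ch_to` (channel range,
#'   inclusive) and `rate` (Hz). Ranges for the same channel must not
#'   overlap.
#' @param seed integer seed; regeneration is bit-identical.
#' @return event `data.frame` with columns `tick`, `channel`, sorted.
#' @export
poisson_trains <- function(schedule, seed = 1L) {
  stopifnot(all(c("from", "to", "ch_from", "ch_to", "rate") %in% names(schedule)))
  if (any(schedule$rate < 0)) stop("rates must be >= 0")
  .with_seed(seed, {
    parts <- lapply(seq_len(nrow(schedule)), function(i) {
      s <- schedule[i, ]
      ticks <- seq.int(s$from, s$to - 1L)
      chans <- seq.int(s$ch_from, s$ch_to)
      if (s$rate == 0 || !length(ticks)) {
        return(data.frame(tick = integer(), channel = integer()))
      }
      p <- s$rate / 1000
      hit <- which(stats::runif(length(ticks) * length(chans)) < p)
      data.frame(tick = ticks[(hit - 1L) %% length(ticks) + 1L],
                 channel = chans[(hit - 1L) %/% length(ticks) + 1L])
    })
    ev <- do.call(rbind, parts)
    ev <- ev[order(ev$tick, ev$channel), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  })
}

#' The bars-and-stripes pattern set
#'
#' All 32 labelled 4x4 binary patterns: the 16 patterns with constant rows
#' ("bars", one per subset of rows switched on) and the 16 with constant
#' columns ("stripes"). The all-off and all-on patterns appear in both
#' classes. Canonical order: bars by row bit code 0..15, then stripes by
#' column bit code.
#'
#' @return a list with `patterns` (32 x 4 x 4 binary array) and `label`
#'   (factor `bars`/`stripes`).
#' @export
bars_stripes <- function() {
  pat <- array(0L, c(32L, 4L, 4L))
  for (code in 0:15) {
    bits <- as.integer(intToBits(code))[1:4]
    pat[code + 1L, , ] <- matrix(rep(bits, 4L), nrow = 4L)              # row r on iff bit r
    pat[code + 17L, , ] <- matrix(rep(bits, 4L), nrow = 4L, byrow = TRUE) # col c on iff bit c
  }
  list(patterns = pat,
       label = factor(rep(c("bars", "stripes"), each = 16L)))
}

#' Noise-embedded repeating spike pattern
#'
#' A fixed random spike pattern is presented repeatedly, interleaved with
#' freshly drawn random segments of the same firing rate, so the pattern is
#' statistically invisible in the rate. Ground-truth window annotations are
#' returned for selectivity scoring.
#'
#' @param n_inputs number of input channels.
#' @param pattern_len pattern window length in ticks.
#' @param gap_len noise segment length between presentations.
#' @param n_repeats number of pattern presentations.
#' @param rate firing rate (Hz) of both pattern and noise segments.
#' @param seed integer seed.
#' @return a list with `events` (tick, channel), `windows` (`start`,
#'   `end`, exclusive, and `type` = `pattern`/`noise`), and `ticks` (total
#'   duration).
#' @export
embedded_pattern_trains <- function(n_inputs = 100L, pattern_len = 50L,
                                    gap_len = 150L, n_repeats = 20L,
                                    rate = 15, seed = 1L) {
  .with_seed(seed, {
    p <- rate / 1000
    draw_seg <- function(len) {
      hit <- which(stats::runif(len * n_inputs) < p)
      data.frame(tick = (hit - 1L) %% len,
                 channel = (hit - 1L) %/% len + 1L)
    }
    # the pattern is drawn conditioned on the exact expected spike count, so
    # that its rate matches the noise segments' mean rate by construction and
    # detection has to rely on spike timing, not on a rate imbalance
    n_pat <- round(pattern_len * n_inputs * p)
    slot <- sample.int(pattern_len * n_inputs, n_pat)
    pattern <- data.frame(tick = (slot - 1L) %% pattern_len,
                          channel = (slot - 1L) %/% pattern_len + 1L)
    pattern <- pattern[order(pattern$tick, pattern$channel), ]
    evs <- list(); wins <- list()
    t0 <- 0L
    for (r in seq_len(n_repeats)) {
      noise <- draw_seg(gap_len)
      noise$tick <- noise$tick + t0
      evs[[length(evs) + 1L]] <- noise
      wins[[length(wins) + 1L]] <- data.frame(start = t0, end = t0 + gap_len,
                                              type = "noise")
      t0 <- t0 + gap_len
      pp <- pattern
      pp$tick <- pp$tick + t0
      evs[[length(evs) + 1L]] <- pp
      wins[[length(wins) + 1L]] <- data.frame(start = t0, end = t0 + pattern_len,
                                              type = "pattern")
      t0 <- t0 + pattern_len
    }
    ev <- do.call(rbind, evs)
    ev <- ev[order(ev$tick, ev$channel), , drop = FALSE]
    rownames(ev) <- NULL
    list(events = ev, windows = do.call(rbind, wins), ticks = t0)
  })
}

#' Read an IDX-format image or label file
#'
#' Minimal reader for the IDX binary format used by the MNIST distribution
#' (optional: nothing in the package or its tests requires a download).
#' Image files are returned as a numeric `n x pixels` matrix scaled to
#' `[0, 1]`, ready to be used as per-pixel Poisson rate factors; label
#' files as an integer vector.
#'
#' @param path file path.
#' @return matrix of intensities or integer labels.
#' @export
load_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  dtype <- bitwAnd(bitwShiftR(magic, 8L), 255L)
  ndim <- bitwAnd(magic, 255L)
  if (bitwAnd(bitwShiftR(magic, 16L), 65535L) != 0L || dtype != 8L ||
      !(ndim %in% c(1L, 3L))) {
    stop("not an IDX file: bad magic number")
  }
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  n <- prod(dims)
  data <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  if (length(data) != n) stop("truncated IDX file")
  if (ndim == 1L) return(as.integer(data))
  matrix(data / 255, nrow = dims[1], ncol = dims[2] * dims[3], byrow = TRUE)
}
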