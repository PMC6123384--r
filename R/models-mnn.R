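# Mihalas-Niebur style neuron behaviours on the fixed-point fabric.
#
# The generalized linear integrate-and-fire family (membrane potential,
# adaptive threshold, internal after-spike currents) maps onto the framework
# as follows: component 1 is the membrane-minus-threshold spiking variable
# (the spike condition V >= Theta(t) becomes x0 >= 0 against a constant
# threshold after absorbing the adaptive threshold into linear adaptation
# currents), components 2-3 are adaptation / internal currents coupled into
# the membrane through power-of-two coefficients, and the spike-triggered
# additive current increments (I_j <- I_j + P_j) are realized as
# self-synapses, since hardware resets are constant-valued. All continuous
# coefficients are snapped to the nearest signed power of two.

#' Mihalas-Niebur behaviour presets
#'
#' Parameter sets for the six classic firing behaviours: `tonic`, `phasic`,
#' `mixed`, `classI`, `classII` and `tonic-burst`. Each entry gives the
#' membrane leak, the drive current, threshold, refractory period, and the
#' adaptation / internal current couplings (decay, membrane coupling,
#' spike-triggered increment with its gain exponent).
#'
#' @return named list of preset parameter lists.
#' @export
mnn_presets <- function() {
  list(
    tonic = list(k = 1L, leak = -2^-4, I_e = 40L, theta = 500L, refr = 4L),
    classI = list(k = 1L, leak = 0, I_e = 8L, theta = 1000L, refr = 4L),
    classII = list(k = 2L, leak = -2^-4, I_e = 70L, theta = 500L, refr = 4L,
                   a01 = -2^-1, a11 = -2^-8, P1 = 100L, g1 = 4L),
    phasic = list(k = 2L, leak = -2^-4, I_e = 40L, theta = 500L, refr = 4L,
                  a01 = -2^-2, a11 = 0, P1 = 100L, g1 = 3L),
    mixed = list(k = 2L, leak = -2^-4, I_e = 120L, theta = 500L, refr = 3L,
                 a01 = -2^-2, a11 = -2^-7, P1 = 80L, g1 = 2L),
    `tonic-burst` = list(k = 3L, leak = -2^-3, I_e = 80L, theta = 500L, refr = 2L,
                         a01 = 2^-1, a11 = -2^-1, P1 = 100L, g1 = 3L,
                         a02 = -2^-3, a22 = -2^-7, P2 = 60L, g2 = 2L)
  )
}

#' Build a Mihalas-Niebur behaviour network
#'
#' One neuron configured for the requested behaviour preset. The drive
#' current can be overridden (used for rate-versus-current sweeps).
#'
#' @param preset preset name, see [mnn_presets()].
#' @param I_e optional drive current override.
#' @return a [run_config()].
#' @export
build_mnn <- function(preset, I_e = NULL) {
  ps <- mnn_presets()
  if (!preset %in% names(ps)) {
    stop(sprintf("unknown preset '%s'; available: %s", preset,
                 paste(names(ps), collapse = ", ")))
  }
  p <- ps[[preset]]
  if (!is.null(I_e)) p$I_e <- I_e
  k <- p$k
  A <- matrix(0, k, k)
  A[1, 1] <- p$leak
  if (k >= 2) {
    A[1, 2] <- p$a01
    A[2, 2] <- p$a11
    if (!is.null(p$a10)) A[2, 1] <- p$a10
  }
  if (k >= 3) {
    A[1, 3] <- p$a02
    A[3, 3] <- p$a22
  }
  gains <- c(0L, if (k >= 2) p$g1 else NULL, if (k >= 3) p$g2 else NULL)
  g <- neuron_group(k = k, A = as_shift_matrix(nearest_shift(A)),
                    b = c(as.integer(p$I_e), rep(0L, k - 1L)),
                    theta = c(p$theta, rep(NA, k - 1L)),
                    reset_en = c(TRUE, rep(FALSE, k - 1L)), Xr = 0L,
                    refractory = p$refr, gain = gains,
                    name = paste0("mnn-", preset))
  syn <- NULL
  if (k >= 2 && !is.null(p$P1) && p$P1 != 0) {
    syn <- synapse_table(pre = 1L, post = 1L, target = 2L, weight = p$P1)
  }
  if (k >= 3 && !is.null(p$P2) && p$P2 != 0) {
    syn <- rbind(syn, synapse_table(pre = 1L, post = 1L, target = 3L, weight = p$P2))
  }
  run_config(list(g), group_of = 1L, synapses = syn)
}

#' Simulate a behaviour preset
#'
#' @param preset preset name.
#' @param ticks run length.
#' @param seed run seed.
#' @param I_e optional drive current override.
#' @return spike tick vector.
#' @export
run_mnn <- function(preset, ticks = 2000L, seed = 1L, I_e = NULL) {
  cfg <- build_mnn(preset, I_e = I_e)
  sim_run(cfg, ticks, seed = seed)$raster$tick
}

#' Steady-state rate versus drive current
#'
#' Firing rate (Hz, from the second half of the run, excluding onset
#' transients) across a sweep of drive currents.
#'
#' @param preset preset name.
#' @param currents integer drive currents.
#' @param ticks run length per current.
#' @param seed run seed.
#' @return numeric rates, one per current.
#' @export
mnn_fi_curve <- function(preset, currents, ticks = 3000L, seed = 1L) {
  vapply(currents, function(I) {
    s <- run_mnn(preset, ticks = ticks, seed = seed, I_e = I)
    sum(s >= ticks / 2) / (ticks / 2000)
  }, numeric(1))
}

#' Behaviour classifiers for the preset battery
#'
#' Six predicates, one per behaviour, each operating on the statistics of a
#' standard run (and, for the excitability classes, an f-I sweep). Each
#' classifier accepts its own preset and rejects behaviourally different
#' ones; [mnn_battery()] evaluates the full matrix.
#'
#' @return named list of functions `f(stats) -> logical`.
#' @export
mnn_classifiers <- function() {
  list(
    tonic = function(st) {
      length(st$spikes) >= 10 && st$last_quarter_active &&
        stats::sd(st$isis) / mean(st$isis) < 0.1 && !st$bimodal
    },
    phasic = function(st) {
      length(st$spikes) >= 1 && all(st$spikes < st$ticks / 4)
    },
    mixed = function(st) {
      n <- length(st$isis)
      n >= 6 && st$last_quarter_active &&
        st$isis[1] < 0.5 * stats::median(st$isis[(n %/% 2):n]) &&
        stats::sd(st$isis[(n %/% 2):n]) / mean(st$isis[(n %/% 2):n]) < 0.15
    },
    `tonic-burst` = function(st) st$bimodal && st$last_quarter_active,
    classI = function(st) {
      r <- st$fi[st$fi > 0]
      length(r) >= 3 && min(r) / max(st$fi) <= 0.15
    },
    classII = function(st) {
      r <- st$fi[st$fi > 0]
      length(r) >= 3 && min(r) / max(st$fi) >= 0.4
    }
  )
}

.mnn_stats <- function(preset, ticks = 2000L, seed = 1L) {
  spikes <- run_mnn(preset, ticks = ticks, seed = seed)
  isis <- diff(spikes)
  bimodal <- FALSE
  if (length(isis) >= 6) {
    s <- sort(isis)
    gaps <- diff(s)
    i <- which.max(gaps)
    # bimodal if the largest gap splits the ISIs into two populations that
    # are each tight relative to the gap, with the long mode >= 4x the short
    if (i >= 3 && i <= length(s) - 2) {
      lo <- s[1:i]; hi <- s[(i + 1):length(s)]
      bimodal <- gaps[i] > 3 * max(stats::sd(lo), stats::sd(hi), 1) &&
        mean(hi) > 4 * mean(lo)
    }
  }
  currents <- c(2L, 4L, 8L, 16L, 32L, 64L, 40L, 50L, 60L, 80L, 120L, 200L)
  fi <- mnn_fi_curve(preset, currents, seed = seed)
  list(preset = preset, spikes = spikes, isis = isis, ticks = ticks,
       bimodal = bimodal, fi = fi,
       last_quarter_active = any(spikes >= 3 * ticks / 4))
}

#' Run the behaviour battery
#'
#' Evaluates every classifier on every preset.
#'
#' @param seed run seed.
#' @param ticks run length per preset.
#' @return logical matrix, rows = presets, columns = classifiers.
#' @export
mnn_battery <- function(seed = 1L, ticks = 2000L) {
  presets <- names(mnn_presets())
  cls <- mnn_classifiers()
  out <- matrix(FALSE, length(presets), length(cls),
                dimnames = list(presets, names(cls)))
  for (p in presets) {
    st <- .mnn_stats(p, ticks = ticks, seed = seed)
    for (cn in names(cls)) out[p, cn] <- isTRUE(cls[[cn]](st))
  }
  out
}
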