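# Spiking neural fields: a 1-D sheet of threshold units with
# difference-of-Gaussians lateral connectivity, realized as 100 internal
# one-component no-reset neurons, all-to-all connected through quantized
# 8-bit weights, driven one-to-one by 100 external Poisson channels. With
# the Heaviside activation of the continuum model, a unit's output is
# simply "spiking this tick" (no reset, no refractory period): the discrete
# update u[t+1] = u[t] - leak(u[t]) + W s[t] + input is the field equation.

#' Uniform quantizer
#'
#' `Q(r) = delta * floor(r / delta + 0.5)`, the quantizer used to map a
#' continuous lateral kernel onto the low-precision weight grid.
#'
#' @param x numeric values.
#' @param delta quantizer step.
#' @return quantized values (multiples of `delta`).
#' @export
quantize <- function(x, delta) delta * floor(x / delta + 0.5)

#' Neural-field presets
#'
#' Kernel and input-schedule parameters of the three demonstrations:
#' `bump` (self-sustained localized activity), `selection`
#' (winner-take-all between two stimuli), and `tracking` (an asymmetric
#' kernel following a displaced input patch).
#'
#' @return named list of preset parameter lists.
#' @export
field_presets <- function() {
  list(
    bump = list(K_e = 18, K_i = 10, sigma_e = 3, sigma_i = 50, shift = 0,
                theta = 200L, leak = -2^-3, w_in = 127L, gain = 3L,
                input = data.frame(from = 0, to = 400,
                                   ch_from = c(40, 1, 61), ch_to = c(60, 39, 100),
                                   rate = c(35, 10, 10))),
    selection = list(K_e = 22, K_i = 12, sigma_e = 3, sigma_i = 50, shift = 0,
                     theta = 200L, leak = -2^-3, w_in = 127L, gain = 3L,
                     input = data.frame(from = 0, to = 500,
                                        ch_from = c(20, 70), ch_to = c(40, 90),
                                        rate = 50)),
    tracking = list(K_e = 10, K_i = 12, sigma_e = 3, sigma_i = 50, shift = 1,
                    theta = 200L, leak = -2^-3, w_in = 127L, gain = 3L,
                    patch_lo = c(10, 30, 50, 70, 85), patch_w = 10,
                    patch_period = 500, rate = 50)
  )
}

#' Build a neural-field network
#'
#' @param preset preset name, see [field_presets()].
#' @param n lattice size (number of field units).
#' @param delta quantizer step on the integer weight scale.
#' @return a [run_config()].
#' @export
build_field <- function(preset, n = 100L, delta = 1) {
  ps <- field_presets()
  if (!preset %in% names(ps)) {
    stop(sprintf("unknown preset '%s'; available: %s", preset,
                 paste(names(ps), collapse = ", ")))
  }
  p <- ps[[preset]]
  g <- neuron_group(k = 1L, A = matrix(p$leak), theta = p$theta,
                    reset_en = FALSE, refractory = 0L, gain = p$gain,
                    name = paste0("field-", preset))
  # periodic (ring) lateral distances: without wrap-around, edge units get
  # less long-range inhibition and the background can ignite spurious bumps
  # at the boundaries
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    dd <- (i - j) %% n
    ifelse(dd > n / 2, dd - n, dd)
  })
  wk <- quantize(p$K_e * exp(-(d - p$shift)^2 / (2 * p$sigma_e^2)) -
                 p$K_i * exp(-d^2 / (2 * p$sigma_i^2)), delta) / delta
  idx <- which(wk != 0 & row(d) != col(d), arr.ind = TRUE)
  syn <- rbind(
    synapse_table(pre = idx[, 2], post = idx[, 1], target = 1L,
                  weight = as.integer(wk[idx])),
    synapse_table(pre = n + seq_len(n), post = seq_len(n), target = 1L,
                  weight = p$w_in)
  )
  run_config(list(g), group_of = rep(1L, n), n_ext = n, synapses = syn)
}

#' Input event schedule of a field preset
#'
#' @param preset preset name.
#' @param seed generator seed.
#' @param n lattice size.
#' @return event `data.frame`.
#' @export
field_input <- function(preset, seed = 1L, n = 100L) {
  p <- field_presets()[[preset]]
  if (preset == "tracking") {
    t0 <- (seq_along(p$patch_lo) - 1L) * p$patch_period
    sched <- data.frame(from = t0, to = t0 + p$patch_period,
                        ch_from = p$patch_lo, ch_to = p$patch_lo + p$patch_w,
                        rate = p$rate)
  } else {
    sched <- p$input
  }
  poisson_trains(sched, seed = seed)
}

#' Run a neural-field demonstration
#'
#' @param preset preset name.
#' @param ticks run length (2500 by default, as in the demonstrations).
#' @param seed seed for both the input generator and the run.
#' @return a [sim_run()] result with the preset name attached.
#' @export
run_field <- function(preset, ticks = 2500L, seed = 1L) {
  cfg <- build_field(preset)
  ev <- field_input(preset, seed = seed)
  res <- sim_run(cfg, ticks, seed = seed, events = ev)
  res$preset <- preset
  res
}

#' Behaviour metrics of a field run
#'
#' For `bump`: mean per-unit activity inside units 40-60 versus outside,
#' after input removal (tick > 400), and unimodality of the final activity
#' profile. For `selection`: total late activity in each stimulated region.
#' For `tracking`: activity centre of mass in the second half of each
#' input-patch epoch, with the patch centre targets.
#'
#' @param res a [run_field()] result.
#' @param n lattice size.
#' @return named list of metrics.
#' @export
field_metrics <- function(res, n = 100L) {
  r <- res$raster
  prof <- function(a, b) tabulate(r$neuron[r$tick >= a & r$tick < b], n)
  if (res$preset == "bump") {
    cnt <- prof(401, max(r$tick) + 1L)
    late <- prof(2200, 2500)
    act <- which(late > 0)
    list(inside = mean(cnt[40:60]), outside = mean(cnt[-(40:60)]),
         ratio = mean(cnt[40:60]) / max(mean(cnt[-(40:60)]), 1e-9),
         unimodal = length(act) > 0 && all(diff(act) == 1),
         mode = if (length(act)) act[which.max(late[act])] else NA)
  } else if (res$preset == "selection") {
    late <- prof(2000, 2500)
    a <- sum(late[20:40]); b <- sum(late[70:90])
    list(region_a = a, region_b = b,
         exactly_one = xor(a > 50 * 5, b > 50 * 5) && min(a, b) < 0.1 * max(a, b))
  } else {
    p <- field_presets()$tracking
    t0 <- (seq_along(p$patch_lo) - 1L) * p$patch_period
    centers <- vapply(seq_along(t0), function(i) {
      cnt <- prof(t0[i] + 250, t0[i] + p$patch_period)
      if (sum(cnt) == 0) NA_real_ else sum(seq_len(n) * cnt) / sum(cnt)
    }, numeric(1))
    list(centers = centers, targets = p$patch_lo + p$patch_w / 2,
         max_abs_err = max(abs(centers - (p$patch_lo + p$patch_w / 2))))
  }
}
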