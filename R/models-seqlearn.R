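# Unsupervised spike-pattern learning with the voltage/calcium rule:
# 100 input channels project all-to-all onto 5 four-component neurons
# (membrane V, calcium Ca, comparator, modulator). The comparator is
# eta_plus when V exceeds V_lth and eta_minus otherwise; the modulator adds
# a homeostatic term driving calcium (a spike-count trace fed by a
# self-synapse) toward its set point. Every pre-synaptic spike changes its
# weight by the post neuron's modulator, gated by a boxcar that excludes
# the post-reset/refractory voltage range (otherwise the reset that follows
# each pattern-evoked spike coherently depresses exactly the late-pattern
# inputs and detectors unlearn themselves).

#' Default sequence-learning parameters
#'
#' @return named list of parameters (units: state LSBs and ticks).
#' @export
seqlearn_params <- function() {
  list(n_in = 100L, n_out = 5L,
       leak_v = -2^-3, leak_ca = -2^-6,
       theta = 3000L, Xr = 1000L, refr = 3L,
       v_lth = 2400L, eta_plus = 8L, eta_minus = -2L,
       eta_h_exp = -3L, ca_target = 20L,
       gamma = 16L, gain_in = 2L, gain_ca = 2L,
       r_bits = 3L, gate_min = 1500L,
       w_min = 0L, w_max = 127L, w0_range = c(15L, 45L))
}

#' Build the sequence-learning network
#'
#' @param w0 integer vector of initial input weights
#'   (`n_in * n_out`, input-major).
#' @param params parameter list, see [seqlearn_params()].
#' @param frozen if `TRUE`, weight updates are disabled (evaluation mode).
#' @return a [run_config()].
#' @export
build_seqlearn <- function(w0, params = seqlearn_params(), frozen = FALSE) {
  p <- params
  A <- matrix(0, 4, 4)
  A[1, 1] <- p$leak_v
  A[2, 2] <- p$leak_ca
  g <- neuron_group(
    k = 4L, A = as_shift_matrix(A), theta = c(p$theta, NA, NA, NA),
    reset_en = c(TRUE, FALSE, FALSE, FALSE), Xr = c(p$Xr, 0L, 0L, 0L),
    refractory = p$refr, gain = c(p$gain_in, p$gain_ca, 0L, 0L),
    derived = derived_vcal(v = 1L, ca = 2L, th = 3L, mod = 4L,
                           v_lth = p$v_lth, eta_plus = p$eta_plus,
                           eta_minus = p$eta_minus, eta_h_exp = p$eta_h_exp,
                           eta_h_sign = 1L, ca_target = p$ca_target),
    name = "seqlearn")
  pl <- plasticity_state(mod = 4L, gain_exp = 0L, w_min = p$w_min,
                         w_max = p$w_max, r_bits = p$r_bits,
                         gate = list(comp = 1L, min = p$gate_min, max = 32767L))
  syn <- rbind(
    synapse_table(pre = rep(p$n_out + seq_len(p$n_in), each = p$n_out),
                  post = rep(seq_len(p$n_out), p$n_in), target = 1L,
                  weight = as.integer(w0), plast = 1L),
    # calcium trace: each output increments its own Ca on every spike
    synapse_table(pre = seq_len(p$n_out), post = seq_len(p$n_out),
                  target = 2L, weight = p$gamma)
  )
  run_config(list(g), group_of = rep(1L, p$n_out), n_ext = p$n_in,
             synapses = syn, plasticity = list(pl),
             learn_period = if (frozen) 1L else 0L,
             learn_freeze = if (frozen) 1L else 0L)
}

#' Train on a noise-embedded repeating pattern and score selectivity
#'
#' Trains on [embedded_pattern_trains()] input, then evaluates with frozen
#' weights on a fresh sequence containing the same pattern, and reports the
#' firing rate of every output inside pattern windows versus noise
#' segments.
#'
#' @param seed seed for weights, input generation and the runs.
#' @param n_repeats training pattern presentations.
#' @param n_eval evaluation presentations.
#' @param pattern_len,gap_len,rate input schedule, see
#'   [embedded_pattern_trains()].
#' @param params parameter list.
#' @return list with `pattern_rate`, `noise_rate`, `ratio` (per output,
#'   Hz), the trained weights and the evaluation raster.
#' @export
seqlearn_demo <- function(seed = 1L, n_repeats = 600L, n_eval = 40L,
                          pattern_len = 50L, gap_len = 150L, rate = 15,
                          params = seqlearn_params()) {
  p <- params
  w0 <- .with_seed(seed + 17L, {
    sample(seq(p$w0_range[1], p$w0_range[2]), p$n_in * p$n_out, replace = TRUE)
  })
  tr <- embedded_pattern_trains(p$n_in, pattern_len, gap_len, n_repeats,
                                rate, seed = seed)
  cfg <- build_seqlearn(w0, params = p)
  res <- sim_run(cfg, tr$ticks, seed = seed, events = tr$events,
                 record_spikes = FALSE)
  te <- embedded_pattern_trains(p$n_in, pattern_len, gap_len, n_eval,
                                rate, seed = seed) # same seed = same pattern
  cfg_f <- build_seqlearn(w0, params = p, frozen = TRUE)
  st <- sim_state(cfg_f)
  st$w <- res$state$w
  ev_res <- sim_run(cfg_f, te$ticks, seed = seed + 1000L, state = st,
                    events = te$events)
  r <- ev_res$raster
  inwin <- function(t, wins) {
    i <- findInterval(t, wins$start)
    i >= 1 & t < wins$end[pmax(i, 1)]
  }
  pw <- te$windows[te$windows$type == "pattern", ]
  nw <- te$windows[te$windows$type == "noise", ]
  rp <- vapply(seq_len(p$n_out), function(nn) {
    sum(r$neuron == nn & inwin(r$tick, pw)) / sum(pw$end - pw$start) * 1000
  }, numeric(1))
  rn <- vapply(seq_len(p$n_out), function(nn) {
    sum(r$neuron == nn & inwin(r$tick, nw)) / sum(nw$end - nw$start) * 1000
  }, numeric(1))
  list(pattern_rate = rp, noise_rate = rn,
       ratio = rp / pmax(rn, 0.5), w = res$state$w, raster = r)
}
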