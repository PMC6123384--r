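# The forward-table, pre-sensitive, nearest-neighbour three-factor engine.

test_that("acausal and causal updates match hand-computed single-pair cases", {
  # pre at 100, post forced to spike near 95: one acausal delta
  r <- run_stdp_pair(pre_ticks = 100L, force_ticks = 93L, ticks = 150L)
  expect_identical(length(r$post), 1L)
  lag <- 100L - r$post
  expect_gt(lag, 0L)
  expect_identical(r$dw, -fx_shift(r$ac_exp[lag + 1L], 64L))
  # pre with no post spike in any window: no change
  r2 <- run_stdp_pair(pre_ticks = 500L, force_ticks = 100L, ticks = 700L)
  expect_identical(r2$dw, 0L)
  # post spiking after the pre: one causal delta committed at timer expiry
  r3 <- run_stdp_pair(pre_ticks = 100L, force_ticks = 102L, ticks = 200L)
  lag3 <- r3$post - 100L
  expect_identical(r3$dw, fx_shift(r3$ca_exp[lag3 + 1L], 64L))
})

test_that("event-driven totals equal the brute-force nearest-neighbour oracle", {
  set.seed(99)
  for (trial in 1:25) {
    T <- 2000L
    pre <- sort(sample(0:(T - 1L), stats::rpois(1, 40)))
    force <- sort(sample(0:(T - 1L), stats::rpois(1, 40)))
    r <- run_stdp_pair(unique(pre), unique(force), T + 20L)
    o <- nn_stdp_oracle(unique(pre), r$post, r$ca_exp, r$ac_exp,
                        t_ca = 16L, t_ac = 16L, xm = 64L)
    expect_identical(as.integer(r$dw), as.integer(o))
  }
})

test_that("weights never leave their bounds and frozen plasticity conserves them", {
  net <- random_network(5, n = 40L)
  res <- sim_run(net$cfg, 1500, seed = 2, events = net$events)
  pl <- net$cfg$plasticity[[1]]
  expect_true(all(res$state$w >= pl$w_min & res$state$w <= pl$w_max))
  expect_false(identical(res$state$w, sim_state(net$cfg)$w)) # learning happened
  # same network with updates globally frozen: no weight changes at all
  cfg_f <- net$cfg
  cfg_f$learn_period <- 1L; cfg_f$learn_freeze <- 1L
  cfg_f$core <- spikefix:::.build_core_cfg(cfg_f)
  res_f <- sim_run(cfg_f, 1500, seed = 2, events = net$events)
  expect_identical(res_f$state$w, sim_state(cfg_f)$w)
})

test_that("zero modulator yields zero delta regardless of lag", {
  r <- run_stdp_pair(pre_ticks = c(50L, 100L, 150L), force_ticks = c(48L, 103L),
                     ticks = 300L, xm = 0L)
  expect_identical(r$dw, 0L)
})

test_that("the boxcar gate blocks updates when the gated component is outside its band", {
  g <- neuron_group(k = 2, A = as_shift_matrix(matrix(0, 2, 2)),
                    b = c(500L, 0L), theta = c(30000L, NA),
                    reset_en = FALSE, x_init = c(0L, 64L))
  mk <- function(gate) {
    pl <- plasticity_state(mod = 2L, gain_exp = 0L, w_min = -30000L,
                           w_max = 30000L, gate = gate)
    run_config(list(g), group_of = 1L, n_ext = 1L,
               synapses = synapse_table(pre = 2L, post = 1L, target = 1L,
                                        weight = 0L, plast = 1L),
               plasticity = list(pl))
  }
  ev <- data.frame(tick = c(1L, 3L, 8L), channel = 1L)
  # x1 ramps by 500/tick; gate [0, 2000] admits only the early spikes
  r_in <- sim_run(mk(list(comp = 1L, min = 0L, max = 2000L)), 12, events = ev)
  r_all <- sim_run(mk(NULL), 12, events = ev)
  expect_identical(r_all$state$w[1], 3L * 64L)
  expect_identical(r_in$state$w[1], 2L * 64L) # the tick-8 update is gated out
})

test_that("the state rule updates on every pre spike, linear in the modulator", {
  g <- neuron_group(k = 2, A = as_shift_matrix(matrix(0, 2, 2)),
                    theta = c(30000L, NA), reset_en = FALSE,
                    x_init = c(0L, -48L))
  pl <- plasticity_state(mod = 2L, gain_exp = -2L, w_min = -30000L, w_max = 30000L)
  cfg <- run_config(list(g), group_of = 1L, n_ext = 1L,
                    synapses = synapse_table(pre = 2L, post = 1L, target = 1L,
                                             weight = 100L, plast = 1L),
                    plasticity = list(pl))
  ev <- data.frame(tick = c(2L, 5L, 9L), channel = 1L)
  r <- sim_run(cfg, 12, events = ev)
  expect_identical(r$state$w[1], 100L + 3L * fx_shift(-2L, -48L))
})

test_that("weight commits clip into the configured range", {
  g <- neuron_group(k = 2, A = as_shift_matrix(matrix(0, 2, 2)),
                    theta = c(30000L, NA), reset_en = FALSE, x_init = c(0L, 100L))
  pl <- plasticity_state(mod = 2L, gain_exp = 0L, w_min = -128L, w_max = 127L)
  cfg <- run_config(list(g), group_of = 1L, n_ext = 1L,
                    synapses = synapse_table(pre = 2L, post = 1L, target = 1L,
                                             weight = 120L, plast = 1L),
                    plasticity = list(pl))
  ev <- data.frame(tick = 0:9, channel = 1L)
  r <- sim_run(cfg, 12, events = ev)
  expect_identical(r$state$w[1], 127L) # clipped at w_max despite +100/spike
})

test_that("update-on-dropped-spikes decouples learning from blank-out", {
  g <- neuron_group(k = 2, A = as_shift_matrix(matrix(0, 2, 2)),
                    theta = c(30000L, NA), reset_en = FALSE, x_init = c(0L, 8L))
  mk <- function(on_dropped) {
    pl <- plasticity_state(mod = 2L, gain_exp = 0L, w_min = -30000L,
                           w_max = 30000L, on_dropped = on_dropped)
    run_config(list(g), group_of = 1L, n_ext = 1L,
               synapses = synapse_table(pre = 2L, post = 1L, target = 1L,
                                        weight = 0L, plast = 1L, blankout = 0.5),
               plasticity = list(pl))
  }
  n_ev <- 400L
  ev <- data.frame(tick = seq_len(n_ev) - 1L, channel = 1L)
  r_on <- sim_run(mk(TRUE), n_ev + 2L, seed = 3, events = ev)
  r_off <- sim_run(mk(FALSE), n_ev + 2L, seed = 3, events = ev)
  expect_identical(r_on$state$w[1], n_ev * 8L)  # every spike updates
  frac <- r_off$state$w[1] / (n_ev * 8L)        # only surviving deliveries do
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(n_ev))
})

test_that("timer memory is one slot per neuron, independent of synapse count", {
  net <- random_network(7, n = 50L)
  st <- sim_state(net$cfg)
  expect_identical(length(st$last_spike), 50L + net$cfg$n_ext)
  expect_identical(length(st$pending), 50L + net$cfg$n_ext)
})

test_that("derived voltage/calcium components implement the comparator and homeostasis", {
  A <- matrix(0, 4, 4)
  g <- neuron_group(k = 4, A = as_shift_matrix(A), b = c(100L, 0L, 0L, 0L),
                    theta = c(30000L, NA, NA, NA), reset_en = FALSE,
                    derived = derived_vcal(v = 1, ca = 2, th = 3, mod = 4,
                                           v_lth = 450L, eta_plus = 8L,
                                           eta_minus = -2L, eta_h_exp = -2L,
                                           eta_h_sign = 1L, ca_target = 40L))
  cfg <- run_config(list(g), group_of = 1L)
  r <- sim_run(cfg, 8, watch = 1)
  th <- as.integer(r$traces[, 1, 3])
  expect_identical(th[1:4], rep(-2L, 4))  # V = 100..400 <= 450
  expect_identical(th[5:8], rep(8L, 4))   # V = 500..800 > 450
  expect_identical(as.integer(r$traces[1, 1, 4]), -2L + fx_shift(-2L, 40L))
})
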