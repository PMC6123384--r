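# Per-tick neuron integration, threshold/reset/spike logic, refractory
# clamping, and synaptic accumulation timing.

leaky1 <- function(leak_exp, b = 0L, x0 = 0L, theta = NA, reset = !is.na(theta),
                   refr = 0L, noise = NA) {
  A <- matrix(if (leak_exp == 0) 0 else -2^leak_exp, 1, 1)
  g <- neuron_group(k = 1, A = A, b = b, theta = theta, reset_en = reset,
                    Xr = 0L, refractory = refr, x_init = x0, noise = noise)
  run_config(list(g), group_of = 1L)
}

test_that("stage-1 integration follows the difference equation", {
  # leak: 100 - 100/4 = 75
  r <- sim_run(leaky1(-2L, x0 = 100L), 1, watch = 1)
  expect_identical(r$traces[1, 1, 1], 75L)
  # zero transition matrix + constant input = linear integrator
  r2 <- sim_run(leaky1(0L, b = 5L), 4, watch = 1)
  expect_identical(as.integer(r2$traces[, 1, 1]), c(5L, 10L, 15L, 20L))
  # minimum-decay: 3 - trunc(3/16) would stall, forced one-LSB decay
  r3 <- sim_run(leaky1(-4L, x0 = 3L), 3, watch = 1)
  expect_identical(as.integer(r3$traces[, 1, 1]), c(2L, 1L, 0L))
})

test_that("spike comparison is >= and reset/refractory behave as configured", {
  # b=250, theta=1000: x reaches exactly 1000 at tick 3 -> spike (>=)
  cfg <- leaky1(0L, b = 250L, theta = 1000L, refr = 0L)
  r <- sim_run(cfg, 10)
  expect_identical(r$raster$tick[1], 3L)
  # one LSB below threshold: no spike, state keeps its value
  cfg2 <- leaky1(0L, b = 0L, x0 = 999L, theta = 1000L)
  r2 <- sim_run(cfg2, 3, watch = 1)
  expect_identical(nrow(r2$raster), 0L)
  expect_identical(as.integer(r2$traces[, 1, 1]), rep(999L, 3))
  # refractory: spike period = charge time + refractory
  cfg3 <- leaky1(0L, b = 300L, theta = 900L, refr = 2L)
  r3 <- sim_run(cfg3, 30)
  expect_identical(diff(r3$raster$tick), rep(5L, length(r3$raster$tick) - 1L)) # 3 charge + 2 clamp
})

test_that("a neuron in refractory never spikes, for any input magnitude", {
  g <- neuron_group(k = 1, b = 0L, theta = 500L, Xr = 0L, refractory = 8L,
                    gain = 6L)
  cfg <- run_config(list(g), group_of = 1L, n_ext = 1L,
                    synapses = synapse_table(pre = 2L, post = 1L, target = 1L,
                                             weight = 127L))
  ev <- data.frame(tick = 0:40, channel = 1L) # massive sustained drive
  r <- sim_run(cfg, 42, events = ev)
  expect_true(all(diff(r$raster$tick) >= 9L)) # refractory + 1
})

test_that("per-component conditional reset is independent of spiking", {
  # component 2 resets at its own threshold without emitting spikes
  A <- as_shift_matrix(matrix(0, 2, 2))
  g <- neuron_group(k = 2, A = A, b = c(0L, 10L), theta = c(30000L, 50L),
                    reset_en = c(TRUE, TRUE), Xr = c(0L, 0L))
  cfg <- run_config(list(g), group_of = 1L)
  r <- sim_run(cfg, 12, watch = 1)
  expect_identical(nrow(r$raster), 0L)
  x2 <- as.integer(r$traces[, 1, 2])
  expect_identical(max(x2), 40L) # 50 reached -> reset before recording
  expect_identical(x2[5], 0L)    # 10,20,30,40,50->0
})

test_that("no-reset mode spikes while above threshold without altering the state", {
  g <- neuron_group(k = 1, b = 50L, theta = 120L, reset_en = FALSE,
                    refractory = 0L)
  cfg <- run_config(list(g), group_of = 1L)
  r <- sim_run(cfg, 6, watch = 1)
  expect_identical(r$raster$tick, c(2L, 3L, 4L, 5L)) # x=150 at tick 2, keeps rising
  expect_identical(as.integer(r$traces[, 1, 1]), c(50L, 100L, 150L, 200L, 250L, 300L))
})

test_that("deliveries arrive at t+1+delay and are applied at the next integration", {
  g <- neuron_group(k = 1, theta = NA, reset_en = FALSE)
  mk <- function(delay) {
    run_config(list(g), group_of = 1L, n_ext = 1L, max_delay = 5L,
               synapses = synapse_table(pre = 2L, post = 1L, target = 1L,
                                        weight = 40L, delay = delay))
  }
  # external event at tick 5, delay 0: accumulated at 5, visible at tick 5's
  # end-of-tick... state change shows from tick 6's integration
  r0 <- sim_run(mk(0L), 10, events = data.frame(tick = 5L, channel = 1L), watch = 1)
  expect_identical(as.integer(r0$traces[, 1, 1]), c(rep(0L, 6), rep(40L, 4)))
  # delay 3: three ticks later than the delay-0 case
  r3 <- sim_run(mk(3L), 10, events = data.frame(tick = 5L, channel = 1L), watch = 1)
  expect_identical(as.integer(r3$traces[, 1, 1]), c(rep(0L, 9), 40L))
})

test_that("internal spike at t affects its target's integration at t+2", {
  gA <- neuron_group(k = 1, b = 500L, theta = 1000L, Xr = 0L)
  gB <- neuron_group(k = 1, theta = NA, reset_en = FALSE)
  cfg <- run_config(list(gA, gB), group_of = c(1L, 2L),
                    synapses = synapse_table(pre = 1L, post = 2L, target = 1L,
                                             weight = 7L))
  r <- sim_run(cfg, 6, watch = 2)
  expect_identical(r$raster$tick[r$raster$neuron == 1][1], 1L)
  expect_identical(as.integer(r$traces[, 1, 1]), c(0L, 0L, 0L, 7L, 7L, 14L))
})

test_that("synaptic gain shifts weights and blank-out drops deliveries at its rate", {
  g2 <- neuron_group(k = 1, theta = NA, reset_en = FALSE, gain = 2L)
  cfg <- run_config(list(g2), group_of = 1L, n_ext = 1L,
                    synapses = synapse_table(pre = 2L, post = 1L, target = 1L,
                                             weight = 10L))
  r <- sim_run(cfg, 3, events = data.frame(tick = 0L, channel = 1L), watch = 1)
  expect_identical(r$traces[2, 1, 1], 40L) # weight * 2^2
  # blank-out at p = 1/2: mean accumulated input converges to half
  gb <- neuron_group(k = 1, theta = NA, reset_en = FALSE)
  T <- 4000L
  cfgb <- run_config(list(gb), group_of = 1L, n_ext = 1L,
                     synapses = synapse_table(pre = 2L, post = 1L, target = 1L,
                                              weight = 1L, blankout = 0.5))
  rb <- sim_run(cfgb, T + 1L, events = data.frame(tick = 0:(T - 1L), channel = 1L),
                seed = 6)
  frac <- rb$state$x[1, 1] / T
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(T))
  expect_equal(count_synops(rb), rb$state$x[1, 1]) # one SynOp per surviving delivery
})

test_that("membrane plus synaptic-current coupling yields a rise-then-decay PSP", {
  # x2: current driven by the spike; x1: membrane driven by x2
  A <- matrix(0, 2, 2); A[1, 1] <- -2^-3; A[2, 2] <- -2^-2; A[1, 2] <- 2^-1
  g <- neuron_group(k = 2, A = as_shift_matrix(A), theta = NA, reset_en = FALSE)
  cfg <- run_config(list(g), group_of = 1L, n_ext = 1L,
                    synapses = synapse_table(pre = 2L, post = 1L, target = 2L,
                                             weight = 100L))
  r <- sim_run(cfg, 40, events = data.frame(tick = 0L, channel = 1L), watch = 1)
  v <- as.integer(r$traces[, 1, 1])
  pk <- which.max(v)
  expect_gt(v[pk], 0L)
  expect_gt(pk, 2L)                          # rises over several ticks
  expect_true(all(diff(v[1:pk]) >= 0L))      # monotone rise
  expect_lt(v[40], v[pk])                    # then decays
})

test_that("saturation clamps states at the declared width", {
  g <- neuron_group(k = 1, b = 30000L, theta = NA, reset_en = FALSE)
  r <- sim_run(run_config(list(g), group_of = 1L), 5, watch = 1)
  expect_identical(r$traces[5, 1, 1], 32767L)
  g2 <- neuron_group(k = 1, b = -30000L, theta = NA, reset_en = FALSE)
  r2 <- sim_run(run_config(list(g2), group_of = 1L), 5, watch = 1)
  expect_identical(r2$traces[5, 1, 1], -32768L)
  # optional per-component floor (rectifying integrator)
  g3 <- neuron_group(k = 1, b = -50L, x_min = 0L, theta = NA, reset_en = FALSE)
  r3 <- sim_run(run_config(list(g3), group_of = 1L), 5, watch = 1)
  expect_true(all(r3$traces[, 1, 1] == 0L))
})
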