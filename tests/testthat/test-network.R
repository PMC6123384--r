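# Multi-core tick loop: routing, determinism, partition invariance,
# chunked continuation and SynOp accounting.

test_that("runs are deterministic under a fixed seed and empty runs are empty", {
  net <- random_network(3, n = 60L)
  a <- sim_run(net$cfg, 800, seed = 4, events = net$events)
  b <- sim_run(net$cfg, 800, seed = 4, events = net$events)
  expect_identical(a$raster, b$raster)
  expect_identical(a$state$w, b$state$w)
  expect_identical(a$synops, b$synops)
  c <- sim_run(net$cfg, 800, seed = 5, events = net$events)
  expect_false(identical(a$raster, c$raster))
  expect_identical(nrow(sim_run(net$cfg, 0)$raster), 0L)
})

test_that("partitioning neurons across cores leaves rasters and weights bit-identical", {
  nets <- lapply(c(1L, 2L, 4L), function(k) random_network(17, n = 80L, cores = k))
  res <- lapply(nets, function(nn) sim_run(nn$cfg, 1200, seed = 9, events = nn$events))
  expect_identical(res[[1]]$raster[c("tick", "neuron")], res[[2]]$raster[c("tick", "neuron")])
  expect_identical(res[[1]]$raster[c("tick", "neuron")], res[[3]]$raster[c("tick", "neuron")])
  expect_identical(res[[1]]$state$w, res[[2]]$state$w)
  expect_identical(res[[1]]$state$w, res[[3]]$state$w)
})

test_that("chunked runs continue exactly from the returned state", {
  net <- random_network(8, n = 50L)
  full <- sim_run(net$cfg, 900, seed = 2, events = net$events)
  s1 <- sim_run(net$cfg, 333, seed = 2, events = net$events)
  s2 <- sim_run(net$cfg, 400, seed = 2, state = s1$state, events = net$events)
  s3 <- sim_run(net$cfg, 167, seed = 2, state = s2$state, events = net$events)
  joined <- rbind(s1$raster, s2$raster, s3$raster)
  rownames(joined) <- NULL
  expect_identical(joined, full$raster)
  expect_identical(s3$state, full$state)
})

test_that("no event is consumed at or before its emission tick", {
  # a spike emitted at t reaches a target's state strictly after t
  gA <- neuron_group(k = 1, b = 1000L, theta = 1000L, Xr = 0L)
  gB <- neuron_group(k = 1, theta = NA, reset_en = FALSE)
  cfg <- run_config(list(gA, gB), group_of = c(1L, 2L),
                    synapses = synapse_table(pre = 1L, post = 2L, target = 1L,
                                             weight = 5L))
  r <- sim_run(cfg, 4, watch = 2)
  first_spike <- r$raster$tick[r$raster$neuron == 1][1]
  first_effect <- which(r$traces[, 1, 1] != 0L)[1] - 1L
  expect_gt(first_effect, first_spike)
})

test_that("SynOps count delivered-and-accumulated events", {
  g <- neuron_group(k = 1, theta = NA, reset_en = FALSE)
  cfg <- run_config(list(g), group_of = rep(1L, 10L), n_ext = 1L,
                    synapses = synapse_table(pre = 11L, post = 1:10, target = 1L,
                                             weight = 1L))
  expect_identical(count_synops(sim_run(cfg, 5)), 0)       # no spikes, no ops
  r <- sim_run(cfg, 5, events = data.frame(tick = 1L, channel = 1L))
  expect_identical(count_synops(r), 10)                    # fanout 10, no blank-out
  cfgb <- run_config(list(g), group_of = rep(1L, 10L), n_ext = 1L,
                     synapses = synapse_table(pre = 11L, post = 1:10, target = 1L,
                                              weight = 1L, blankout = 0.5))
  tot <- sum(vapply(1:300, function(s) {
    count_synops(sim_run(cfgb, 3, seed = s,
                         events = data.frame(tick = 0L, channel = 1L)))
  }, numeric(1)))
  expect_lt(abs(tot / 300 - 5), 3 * sqrt(10 * 0.25) / sqrt(300))
})

test_that("events addressed outside the network are rejected", {
  g <- neuron_group(k = 1, theta = NA, reset_en = FALSE)
  cfg <- run_config(list(g), group_of = 1L, n_ext = 2L)
  expect_error(sim_run(cfg, 5, events = data.frame(tick = 1L, channel = 3L)),
               "channels")
  expect_error(sim_run(cfg, 5, events = data.frame(tick = -1L, channel = 1L)),
               "tick")
})
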