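# Model builders: structural checks and degenerate-case sanity. The full
# behaviour batteries live in the acceptance suite.

test_that("builders reject unknown presets and produce valid configs", {
  expect_error(build_mnn("bogus"), "unknown preset")
  expect_error(build_field("bogus"), "unknown preset")
  for (p in names(mnn_presets())) expect_s3_class(build_mnn(p), "run_config")
  for (p in names(field_presets())) expect_s3_class(build_field(p), "run_config")
})

test_that("field kernel quantizer follows Q(r) = delta * floor(r/delta + 0.5)", {
  expect_identical(quantize(0.3, 0.25), 0.25)
  expect_identical(quantize(-0.3, 0.25), -0.25)
  expect_identical(quantize(0.124, 0.25), 0)
  cfg <- build_field("bump")
  rec <- cfg$synapses[cfg$synapses$pre <= 100, ]
  expect_true(all(rec$weight >= -128L & rec$weight <= 127L)) # 8-bit kernel
})

test_that("eRBM weight symmetry is exact at all times by shared storage", {
  p <- erbm_params()
  p$n_hidden <- 10L
  cfg <- build_erbm(params = p, seed = 3)
  st <- sim_state(cfg)
  W0 <- erbm_weights(cfg, st$w)
  expect_identical(W0$vh, W0$hv)
  bs <- bars_stripes()
  bits <- c(as.vector(t(bs$patterns[5, , ])), 1L, 0L)
  ev <- spikefix:::.with_seed(9, erbm_pres_events(cfg$meta, 0L, bits))
  res <- sim_run(cfg, erbm_pres_len(p), seed = 2, events = ev)
  W1 <- erbm_weights(cfg, res$state$w)
  expect_identical(W1$vh, W1$hv)
  expect_false(identical(W1$vh, W0$vh)) # learning did happen
})

test_that("disabling update-on-dropped-spikes slows weight movement on the same seed", {
  p <- erbm_params(); p$n_hidden <- 10L
  move <- function(on_dropped) {
    pp <- p
    cfg <- build_erbm(params = pp, seed = 3)
    if (!on_dropped) {
      cfg$plasticity[[1]]$on_dropped <- FALSE
      cfg$core <- spikefix:::.build_core_cfg(cfg)
    }
    st <- sim_state(cfg)
    bs <- bars_stripes()
    ev <- spikefix:::.with_seed(9, do.call(rbind, lapply(1:6, function(j) {
      bits <- c(as.vector(t(bs$patterns[j, , ])), 1L, 0L)
      erbm_pres_events(cfg$meta, (j - 1L) * erbm_pres_len(pp), bits)
    })))
    res <- sim_run(cfg, 6L * erbm_pres_len(pp), seed = 2, events = ev,
                   record_spikes = FALSE)
    sum(abs(res$state$w[1:180] - st$w[1:180]))
  }
  expect_gt(move(TRUE), move(FALSE))
})

test_that("sequence rule with homeostasis off and V above threshold only potentiates", {
  p <- seqlearn_params()
  p$n_in <- 10L; p$n_out <- 2L
  w0 <- rep(60L, 20L)
  cfg <- build_seqlearn(w0, params = p)
  # disable homeostasis and pin V above V_lth with a large bias
  cfg$groups[[1]]$derived$eta_h_sign <- 0L
  cfg$groups[[1]]$b[1] <- 1000L        # drive V far above V_lth at equilibrium
  cfg$groups[[1]]$theta[1] <- 32767L   # never spikes/resets: V stays high
  cfg$core <- spikefix:::.build_core_cfg(cfg)
  # events start after the charging transient so V > V_lth at every pre spike
  ev <- poisson_trains(data.frame(from = 50, to = 3000, ch_from = 1, ch_to = 10,
                                  rate = 40), seed = 3)
  # indices of the plastic (input) weights in the sorted weight store
  pw <- sort(unique(cfg$core$syn$widx[cfg$core$syn$pl >= 0L] + 1L))
  w_t <- sim_state(cfg)$w[pw]
  st <- NULL
  for (chunk in 1:3) {
    res <- sim_run(cfg, 1000, seed = 4, state = st, events = ev,
                   record_spikes = FALSE)
    st <- res$state
    expect_true(all(st$w[pw] >= w_t))
    w_t <- st$w[pw]
  }
  expect_true(all(w_t == 127L)) # monotone increase until clip
})

test_that("eRBP matched prediction and label rates leave error neurons silent", {
  chk <- erbp_matched_error_check(ticks = 3000L, seed = 1L)
  expect_identical(chk$err_spikes, 0L)
  expect_false(chk$weight_changed)
})

test_that("eRBP learn-freeze blocks updates in the first 400 ticks of a presentation", {
  p <- erbp_params()
  cfg <- build_erbp(params = p, seed = 2)
  labels <- 1L
  ev <- erbp_task_events(labels, params = p, seed = 3)
  ev_freeze <- ev[ev$tick < p$freeze - 50L, ] # events only inside the freeze window
  w0 <- sim_state(cfg)$w
  res <- sim_run(cfg, p$freeze - 40L, seed = 5, events = ev_freeze)
  expect_identical(res$state$w, w0)
  # the same drive outside the freeze window does move weights
  ev_live <- ev_freeze
  ev_live$tick <- ev_live$tick + p$freeze + 100L
  res2 <- sim_run(cfg, p$freeze + 500L, seed = 5, events = ev_live)
  expect_false(identical(res2$state$w, w0))
})
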