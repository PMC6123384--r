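# Event-driven random back-propagation (eRBP): a feed-forward spiking
# classifier trained online by a three-factor rule. Hidden and prediction
# neurons carry a plasticity-modulation compartment fed by spiking error
# neurons; weight updates are error-modulated, membrane-gated, triggered by
# pre-synaptic spikes, with 8-bit weights and randomized rounding (r = 6).
# Error is coded by one positive and one negative rectifying integrator per
# class, driven with opposing signs by the prediction neurons and the
# (regular) label spike train; prediction modulators get one-to-one error
# feedback, hidden modulators a fixed random zero-sum projection.

#' Default eRBP network parameters
#'
#' @return named list: layer sizes, neuron constants, wiring strengths,
#'   learning constants, and the presentation schedule (1500 ticks per
#'   stimulus with updates frozen during the first 400).
#' @export
erbp_params <- function() {
  list(n_in = 16L, n_hidden = 10L, n_class = 2L,
       leak = -2^-3, vt_hidden = 1000L, vt_pred = 1000L, vt_err = 256L,
       refr = 20L,                     # also the label inter-spike interval
       w_label = 64L, g_pred = 127L, g_hidden = 16L,
       gain_v = 5L, gain_m = 3L,
       boxcar = c(-30000L, 2000L),
       lr_exp = -2L, r_bits = 6L, blankout = 0.5,
       w0_mean_in = 20, w0_sd = 12,
       period = 1500L, freeze = 400L,
       rate_hi = 60, rate_lo = 5)
}

#' Build an eRBP classifier network
#'
#' Internal neurons are ordered hidden, prediction, then error pairs
#' (E+, E- per class); external channels are the data inputs followed by
#' one label channel per class.
#'
#' @param params parameter list, see [erbp_params()].
#' @param seed seed for the initial weights and the random error feedback.
#' @param frozen if `TRUE`, weight updates are disabled.
#' @return a [run_config()] with layer index metadata in `$layers`.
#' @export
build_erbp <- function(params = erbp_params(), seed = 1L, frozen = FALSE) {
  p <- params
  n_h <- p$n_hidden; n_p <- p$n_class; n_e <- 2L * p$n_class
  hid <- seq_len(n_h); prd <- n_h + seq_len(n_p); err <- n_h + n_p + seq_len(n_e)
  ep <- err[seq(1, n_e, 2)]; em <- err[seq(2, n_e, 2)]
  n_neu <- n_h + n_p + n_e
  ch_data <- seq_len(p$n_in); ch_lab <- p$n_in + seq_len(p$n_class)
  A2 <- as_shift_matrix(matrix(c(p$leak, 0, 0, p$leak), 2, 2))
  g_hid <- neuron_group(k = 2, A = A2, theta = c(p$vt_hidden, NA),
                        reset_en = c(TRUE, FALSE), Xr = 0L, refractory = p$refr,
                        gain = c(p$gain_v, p$gain_m), name = "hidden")
  g_prd <- neuron_group(k = 2, A = A2, theta = c(p$vt_pred, NA),
                        reset_en = c(TRUE, FALSE), Xr = 0L, refractory = p$refr,
                        gain = c(p$gain_v, p$gain_m), name = "prediction")
  # error neurons: non-leaky rectifying integrators, reset to zero on spike
  g_err <- neuron_group(k = 1, theta = p$vt_err, Xr = 0L, x_min = 0L,
                        refractory = 0L, gain = 0L, name = "error")
  pl <- plasticity_state(mod = 2L, gain_exp = p$lr_exp, w_min = -128L,
                         w_max = 127L, r_bits = p$r_bits,
                         gate = list(comp = 1L, min = p$boxcar[1], max = p$boxcar[2]))
  wts <- .with_seed(seed + 7777L, {
    list(dh = pmax(pmin(round(stats::rnorm(p$n_in * n_h, p$w0_mean_in, p$w0_sd)), 127), -128),
         hp = pmax(pmin(round(stats::rnorm(n_h * n_p, 0, p$w0_sd)), 127), -128),
         gsign = replicate(n_h, {
           gk <- sample(c(-1L, 1L), p$n_class, replace = TRUE)
           if (sum(gk) != 0) gk <- rep_len(c(-1L, 1L), p$n_class) # zero-sum
           gk
         }))
  })
  syn <- rbind(
    synapse_table(pre = n_neu + rep(ch_data, each = n_h), post = rep(hid, p$n_in),
                  target = 1L, weight = wts$dh, plast = 1L, blankout = p$blankout),
    synapse_table(pre = rep(hid, each = n_p), post = rep(prd, n_h),
                  target = 1L, weight = wts$hp, plast = 1L, blankout = p$blankout),
    synapse_table(pre = prd, post = ep, target = 1L, weight = p$w_label),
    synapse_table(pre = prd, post = em, target = 1L, weight = -p$w_label),
    synapse_table(pre = n_neu + ch_lab, post = ep, target = 1L, weight = -p$w_label),
    synapse_table(pre = n_neu + ch_lab, post = em, target = 1L, weight = p$w_label),
    # one-to-one error feedback to prediction modulators (m ~ -error)
    synapse_table(pre = ep, post = prd, target = 2L, weight = -p$g_pred),
    synapse_table(pre = em, post = prd, target = 2L, weight = p$g_pred)
  )
  gmat <- matrix(0L, n_e, n_h)
  for (h in seq_len(n_h)) {
    gmat[seq(1, n_e, 2), h] <- -wts$gsign[, h] * p$g_hidden
    gmat[seq(2, n_e, 2), h] <- wts$gsign[, h] * p$g_hidden
  }
  idx <- which(gmat != 0, arr.ind = TRUE)
  syn <- rbind(syn, synapse_table(pre = err[idx[, 1]], post = hid[idx[, 2]],
                                  target = 2L, weight = gmat[idx]))
  cfg <- run_config(list(g_hid, g_prd, g_err),
                    group_of = c(rep(1L, n_h), rep(2L, n_p), rep(3L, n_e)),
                    n_ext = p$n_in + p$n_class, synapses = syn,
                    plasticity = list(pl),
                    learn_period = if (frozen) 1L else p$period,
                    learn_freeze = if (frozen) 1L else p$freeze)
  cfg$layers <- list(hidden = hid, prediction = prd, err_plus = ep,
                     err_minus = em, ch_data = ch_data, ch_label = ch_lab)
  cfg
}

#' Synthetic two-class Poisson rate-pattern task
#'
#' Each class is a fixed rate pattern over the input channels (half the
#' channels at the high rate, the rest at the low rate, drawn once per
#' class); presentations are fresh Poisson draws from the class pattern
#' plus a regular label spike train on the class's label channel.
#'
#' @param labels integer class sequence, one entry per presentation.
#' @param params parameter list.
#' @param seed generator seed for the per-presentation Poisson draws.
#' @param proto_seed seed of the class rate prototypes themselves; keep it
#'   fixed across training and evaluation so both draw from the same task.
#' @return event `data.frame` covering `length(labels)` presentations.
#' @export
erbp_task_events <- function(labels, params = erbp_params(), seed = 1L,
                             proto_seed = seed) {
  p <- params
  proto <- .with_seed(proto_seed + 131L, {
    vapply(seq_len(p$n_class), function(cc) {
      r <- rep(p$rate_lo, p$n_in)
      r[sample(p$n_in, p$n_in %/% 2)] <- p$rate_hi
      r
    }, numeric(p$n_in))
  })
  evs <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    t0 <- (i - 1L) * p$period
    sched <- data.frame(from = t0, to = t0 + p$period,
                        ch_from = seq_len(p$n_in), ch_to = seq_len(p$n_in),
                        rate = proto[, labels[i]])
    e <- poisson_trains(sched, seed = seed + i)
    lab <- data.frame(tick = seq(t0, t0 + p$period - 1L, by = p$refr),
                      channel = p$n_in + labels[i])
    evs[[i]] <- rbind(e, lab)
  }
  ev <- do.call(rbind, evs)
  ev[order(ev$tick, ev$channel), ]
}

.erbp_predictions <- function(raster, layers, n_pres, period, freeze) {
  vapply(seq_len(n_pres), function(i) {
    t0 <- (i - 1L) * period
    cnt <- vapply(layers$prediction, function(n) {
      sum(raster$neuron == n & raster$tick >= t0 + freeze & raster$tick < t0 + period)
    }, numeric(1))
    if (all(cnt == 0)) 0L else which.max(cnt)
  }, integer(1))
}

#' Train the eRBP classifier on the synthetic task
#'
#' Runs `n_pres` training presentations with online learning, then
#' `n_eval` presentations with frozen weights to measure final accuracy.
#'
#' @param n_pres training presentations.
#' @param n_eval frozen evaluation presentations.
#' @param seed seed for network init, task generation and runs.
#' @param n_blocks the training error curve is reported as the
#'   misclassification rate of the online predictions in this many
#'   consecutive blocks.
#' @param params parameter list.
#' @return list with `block_error`, `final_accuracy`, per-presentation
#'   online predictions/labels, trained weights, and SynOp count.
#' @export
erbp_train <- function(n_pres = 500L, n_eval = 50L, seed = 1L, n_blocks = 5L,
                       params = erbp_params()) {
  p <- params
  labels <- .with_seed(seed + 991L, sample(seq_len(p$n_class), n_pres, replace = TRUE))
  ev <- erbp_task_events(labels, params = p, seed = seed)
  cfg <- build_erbp(params = p, seed = seed)
  res <- sim_run(cfg, n_pres * p$period, seed = seed, events = ev)
  pred <- .erbp_predictions(res$raster, cfg$layers, n_pres, p$period, p$freeze)
  blocks <- split(seq_len(n_pres), cut(seq_len(n_pres), n_blocks, labels = FALSE))
  block_error <- vapply(blocks, function(ix) mean(pred[ix] != labels[ix]), numeric(1))
  # frozen evaluation on fresh presentations
  lab_ev <- .with_seed(seed + 992L, sample(seq_len(p$n_class), n_eval, replace = TRUE))
  ev2 <- erbp_task_events(lab_ev, params = p, seed = seed + 5000L, proto_seed = seed)
  cfg_f <- build_erbp(params = p, seed = seed, frozen = TRUE)
  st <- sim_state(cfg_f)
  st$w <- res$state$w
  res2 <- sim_run(cfg_f, n_eval * p$period, seed = seed + 1L, state = st, events = ev2)
  pred2 <- .erbp_predictions(res2$raster, cfg_f$layers, n_eval, p$period, p$freeze)
  list(block_error = block_error,
       final_accuracy = mean(pred2 == lab_ev),
       train_pred = pred, train_labels = labels,
       eval_pred = pred2, eval_labels = lab_ev,
       w = res$state$w, synops = res$synops, raster = res$raster,
       cfg = cfg)
}

#' Error-neuron silence under matched prediction and label rates
#'
#' Wires a label channel and a prediction-proxy channel carrying identical
#' regular spike trains into an error pair with opposing signs and runs the
#' network: the error neurons must stay silent and no weight may change.
#'
#' @param ticks run length.
#' @param seed run seed.
#' @return list with `err_spikes` and `weight_changed`.
#' @export
erbp_matched_error_check <- function(ticks = 3000L, seed = 1L) {
  p <- erbp_params()
  g_err <- neuron_group(k = 1, theta = p$vt_err, Xr = 0L, x_min = 0L,
                        refractory = 0L, gain = 0L)
  syn <- rbind(
    synapse_table(pre = 3L, post = 1L, target = 1L, weight = p$w_label),   # prediction proxy
    synapse_table(pre = 3L, post = 2L, target = 1L, weight = -p$w_label),
    synapse_table(pre = 4L, post = 1L, target = 1L, weight = -p$w_label),  # label
    synapse_table(pre = 4L, post = 2L, target = 1L, weight = p$w_label)
  )
  cfg <- run_config(list(g_err), group_of = c(1L, 1L), n_ext = 2L, synapses = syn)
  ticks_seq <- seq(0L, ticks - 1L, by = p$refr)
  ev <- rbind(data.frame(tick = ticks_seq, channel = 1L),
              data.frame(tick = ticks_seq, channel = 2L))
  w0 <- sim_state(cfg)$w
  res <- sim_run(cfg, ticks, seed = seed, events = ev)
  list(err_spikes = nrow(res$raster), weight_changed = !identical(res$state$w, w0))
}
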