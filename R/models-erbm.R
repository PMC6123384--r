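# Event-based restricted Boltzmann machine trained with event-driven
# contrastive divergence (eCD) on stochastic (blank-out) synapses.
#
# 18 visible units (16 pixels + 2 one-hot class units) are bidirectionally
# connected to the hidden layer through a SHARED weight store: the
# visible-to-hidden and hidden-to-visible synapse rows reference the same
# weight cells, so symmetry is exact at every tick by construction. Two
# modulatory input channels alternately drive every unit's modulator
# component positive (clamped data phase) and negative (free-running
# reconstruction phase, seeded by the data state, one-step contrastive
# divergence); the plasticity is a symmetric-window pair rule whose sign
# comes from the modulator, with updates applied even for deliveries
# dropped by blank-out (the synaptic-sampling mode). Visible units are
# clamped through logit-scaled currents delivered as dense Bernoulli event
# trains (dense-but-jittered, so clamped units do not phase-lock), plus
# membrane noise.

#' Default eRBM parameters
#'
#' @return named list of neuron, wiring and learning constants.
#' @export
erbm_params <- function() {
  list(n_v = 18L, n_pix = 16L, n_hidden = 100L,
       theta = 600L, leak = -2^-3, refr = 12L, window = 8L,
       noise_v = 14L, noise_h = 13L, noise_test = 10L,
       gain_v = 3L, gain_m = 5L, fb_exp = 4L,
       w_on = 94L, w_off = -128L, w0_sd = 16, mod_w = 127L,
       kernel_exp = -10L, r_bits = 4L, blankout = 0.5,
       class_b = 0L,
       d_data = 40L, d_learn = 20L, d_recon = 20L, gap = 16L, n_cycles = 3L,
       p_clamp = 0.4, d_test = 150L, p_clamp_test = 1.0)
}

.erbm_channels <- function(p) {
  n_neu <- p$n_v + p$n_hidden
  list(on = seq_len(p$n_v), off = p$n_v + seq_len(p$n_v),
       modp = 2L * p$n_v + 1L, modm = 2L * p$n_v + 2L,
       n_ext = 2L * p$n_v + 2L, n_neu = n_neu,
       vis = seq_len(p$n_v), hid = p$n_v + seq_len(p$n_hidden),
       class = (p$n_pix + 1L):p$n_v)
}

#' Build the event-based RBM
#'
#' @param params parameter list, see [erbm_params()].
#' @param seed seed for the initial shared weights.
#' @param frozen if `TRUE`, weight updates are disabled.
#' @return a [run_config()] with channel metadata in `$meta`.
#' @export
build_erbm <- function(params = erbm_params(), seed = 1L, frozen = FALSE) {
  p <- params
  ch <- .erbm_channels(p)
  n_v <- p$n_v; n_h <- p$n_hidden; n_neu <- ch$n_neu
  A2 <- as_shift_matrix(matrix(c(p$leak, 0, 0, p$leak), 2, 2))
  # visible: membrane + modulator + feedback-current compartment with unit
  # weight gain, so the clamp (with gain on the membrane) dominates the
  # recurrent feedback even at large weights
  A3 <- matrix(0, 3, 3)
  A3[1, 1] <- p$leak; A3[2, 2] <- p$leak; A3[3, 3] <- -2^-1
  A3[1, 3] <- 2^p$fb_exp
  g_v <- neuron_group(k = 3, A = as_shift_matrix(A3), theta = c(p$theta, NA, NA),
                      reset_en = c(TRUE, FALSE, FALSE), Xr = 0L,
                      refractory = p$refr, gain = c(p$gain_v, p$gain_m, 0L),
                      noise = c(p$noise_v, NA, NA), name = "visible")
  g_c <- neuron_group(k = 3, A = as_shift_matrix(A3), b = c(p$class_b, 0L, 0L),
                      theta = c(p$theta, NA, NA),
                      reset_en = c(TRUE, FALSE, FALSE), Xr = 0L,
                      refractory = p$refr, gain = c(p$gain_v, p$gain_m, 0L),
                      noise = c(p$noise_v, NA, NA), name = "class")
  g_h <- neuron_group(k = 2, A = A2, theta = c(p$theta, NA),
                      reset_en = c(TRUE, FALSE), Xr = 0L,
                      refractory = p$refr, gain = c(p$gain_v, p$gain_m),
                      noise = c(p$noise_h, NA), name = "hidden")
  pl <- plasticity_stdp(t_ca = p$window, t_ac = p$window,
                        exp_ca = p$kernel_exp, exp_ac = p$kernel_exp,
                        mode = "linear", sign_ca = 1L, sign_ac = 1L, mod = 2L,
                        w_min = -128L, w_max = 127L, r_bits = p$r_bits,
                        on_dropped = TRUE)
  W0 <- .with_seed(seed + 555L, {
    pmax(pmin(round(stats::rnorm(n_v * n_h, 0, p$w0_sd)), 127L), -128L)
  })
  wid <- seq_len(n_v * n_h)
  iv <- rep(ch$vis, times = n_h); ih <- rep(ch$hid, each = n_v)
  base <- n_v * n_h
  syn <- rbind(
    synapse_table(pre = iv, post = ih, target = 1L, weight = W0, plast = 1L,
                  blankout = p$blankout, weight_id = wid),
    synapse_table(pre = ih, post = iv, target = 3L, weight = W0, plast = 1L,
                  blankout = p$blankout, weight_id = wid),
    synapse_table(pre = n_neu + ch$modp, post = c(ch$vis, ch$hid), target = 2L,
                  weight = p$mod_w, weight_id = base + seq_len(n_neu)),
    synapse_table(pre = n_neu + ch$modm, post = c(ch$vis, ch$hid), target = 2L,
                  weight = -p$mod_w, weight_id = base + n_neu + seq_len(n_neu)),
    synapse_table(pre = n_neu + ch$on, post = ch$vis, target = 1L,
                  weight = p$w_on, weight_id = base + 2L * n_neu + seq_len(n_v)),
    synapse_table(pre = n_neu + ch$off, post = ch$vis, target = 1L,
                  weight = p$w_off, weight_id = base + 2L * n_neu + n_v + seq_len(n_v))
  )
  cfg <- run_config(list(g_v, g_h, g_c),
                    group_of = c(rep(1L, p$n_pix), rep(3L, n_v - p$n_pix),
                                 rep(2L, n_h)),
                    n_ext = ch$n_ext, synapses = syn, plasticity = list(pl),
                    learn_period = if (frozen) 1L else 0L,
                    learn_freeze = if (frozen) 1L else 0L)
  cfg$meta <- c(ch, list(params = p, n_wvh = n_v * n_h))
  cfg
}

# dense Bernoulli clamp events for a set of channels
.bern_events <- function(ticks, chans, prob) {
  g <- expand.grid(tick = ticks, channel = chans)
  g[stats::runif(nrow(g)) < prob, ]
}

#' Events for one training presentation
#'
#' Each presentation alternates a clamped data phase (pixels and class
#' units driven by on/off logit clamps; positive modulator on for the last
#' `d_learn` ticks, once the network has settled) and a free-running
#' reconstruction phase (negative modulator) seeded by the data state,
#' repeated `n_cycles` times, followed by a silent gap.
#'
#' @param meta the `$meta` of a [build_erbm()] config.
#' @param t0 start tick.
#' @param bits length-18 binary vector (16 pixels + 2 class bits).
#' @return event `data.frame`; the presentation occupies
#'   `erbm_pres_len(meta$params)` ticks.
#' @export
erbm_pres_events <- function(meta, t0, bits) {
  p <- meta$params
  on <- which(bits > 0.5); off <- which(bits <= 0.5)
  evs <- list()
  t <- t0
  for (cy in seq_len(p$n_cycles)) {
    dticks <- t:(t + p$d_data - 1L)
    r0 <- t + p$d_data
    evs[[length(evs) + 1L]] <- rbind(
      if (length(on)) .bern_events(dticks, meta$on[on], p$p_clamp),
      if (length(off)) .bern_events(dticks, meta$off[off], p$p_clamp),
      data.frame(tick = (t + p$d_data - p$d_learn):(t + p$d_data - 1L),
                 channel = meta$modp),
      data.frame(tick = r0:(r0 + p$d_recon - 1L), channel = meta$modm))
    t <- r0 + p$d_recon
  }
  do.call(rbind, evs)
}

#' Presentation length in ticks
#' @param p an [erbm_params()] list.
#' @return integer tick count per presentation.
#' @export
erbm_pres_len <- function(p) p$n_cycles * (p$d_data + p$d_recon) + p$gap

#' Classify the full pattern set with frozen weights
#'
#' Clamps the 16 pixels of every bars-and-stripes pattern (class units
#' free), runs the network at readout noise, and takes the class with the
#' larger mean feedback-current drive as the prediction.
#'
#' @param wts weight vector (from a trained state).
#' @param params parameter list.
#' @param seed evaluation seed.
#' @return list with `error` (misclassification rate over the 32 patterns)
#'   and the per-pattern drives.
#' @export
erbm_test <- function(wts, params = erbm_params(), seed = 99L) {
  p <- params
  pt <- p; pt$noise_v <- p$noise_test; pt$noise_h <- p$noise_test
  cfg <- build_erbm(params = pt, seed = 1L, frozen = TRUE)
  meta <- cfg$meta
  bs <- bars_stripes()
  D <- p$d_test
  evs <- .with_seed(seed, {
    lapply(1:32, function(i) {
      bits <- as.vector(t(bs$patterns[i, , ]))
      t0 <- (i - 1L) * D
      rbind(.bern_events(t0:(t0 + D - 1L), meta$on[which(bits > 0.5)], p$p_clamp_test),
            .bern_events(t0:(t0 + D - 1L), meta$off[which(bits <= 0.5)], p$p_clamp_test))
    })
  })
  st <- sim_state(cfg)
  st$w <- wts
  res <- sim_run(cfg, 32L * D, seed = seed, state = st,
                 events = do.call(rbind, evs), watch = meta$class)
  tr <- res$traces
  drive <- vapply(1:32, function(i) {
    c(mean(tr[((i - 1L) * D + 10L):(i * D), 1, 3]),
      mean(tr[((i - 1L) * D + 10L):(i * D), 2, 3]))
  }, numeric(2))
  truth <- as.integer(bs$label)
  guess <- ifelse(drive[1, ] > drive[2, ], 1L, 2L)
  list(error = mean(guess != truth), drive = drive, guess = guess, truth = truth)
}

#' Train the eRBM on bars-and-stripes
#'
#' Presents all 32 patterns (shuffled) per epoch with one-hot class clamp
#' and the alternating-phase eCD schedule, testing with frozen weights at
#' the requested epochs.
#'
#' @param epochs training epochs (32 presentations each).
#' @param seed master seed.
#' @param params parameter list.
#' @param test_at epochs at which to run [erbm_test()] (0 = before
#'   training).
#' @return list with `errors` (named by epoch), trained weights, the
#'   config, and a symmetry flag (always `TRUE`: the weight store is
#'   shared).
#' @export
erbm_train <- function(epochs = 50L, seed = 1L, params = erbm_params(),
                       test_at = c(0L, epochs)) {
  p <- params
  cfg <- build_erbm(params = p, seed = seed)
  meta <- cfg$meta
  bs <- bars_stripes()
  st <- sim_state(cfg)
  plen <- erbm_pres_len(p)
  errors <- numeric(0)
  if (0L %in% test_at) {
    errors <- c(errors, "0" = erbm_test(st$w, params = p, seed = seed + 900L)$error)
  }
  for (ep in seq_len(epochs)) {
    ord <- .with_seed(seed * 100000L + ep, sample(32L))
    ev <- .with_seed(seed * 100000L + ep + 50L, {
      do.call(rbind, lapply(seq_along(ord), function(j) {
        bits <- c(as.vector(t(bs$patterns[ord[j], , ])),
                  as.integer(bs$label[ord[j]] == levels(bs$label)))
        erbm_pres_events(meta, st$tick + (j - 1L) * plen, bits)
      }))
    })
    st <- sim_run(cfg, 32L * plen, seed = seed, state = st, events = ev,
                  record_spikes = FALSE)$state
    if (ep %in% test_at) {
      e <- erbm_test(st$w, params = p, seed = seed + 900L + ep)$error
      errors <- c(errors, stats::setNames(e, as.character(ep)))
    }
  }
  list(errors = errors, w = st$w, cfg = cfg, symmetric = TRUE)
}

#' Extract the visible-hidden weight matrices of both directions
#'
#' Reads the weight store through the forward table rows of each
#' direction; because the rows share storage the two matrices are
#' identical at all times.
#'
#' @param cfg a [build_erbm()] config.
#' @param wts weight vector.
#' @return list with `vh` (visible x hidden) and `hv` (the transpose
#'   direction, returned visible x hidden for comparison).
#' @export
erbm_weights <- function(cfg, wts) {
  s <- cfg$synapses
  meta <- cfg$meta
  n_v <- meta$params$n_v; n_h <- meta$params$n_hidden
  vh <- s[s$pre %in% meta$vis & s$post %in% meta$hid, ]
  hv <- s[s$pre %in% meta$hid & s$post %in% meta$vis, ]
  Wvh <- matrix(0L, n_v, n_h)
  Wvh[cbind(vh$pre, match(vh$post, meta$hid))] <- wts[vh$weight_id]
  Whv <- matrix(0L, n_v, n_h)
  Whv[cbind(hv$post, match(hv$pre, meta$hid))] <- wts[hv$weight_id]
  list(vh = Wvh, hv = Whv)
}
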