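# Shared fixtures and independent oracles, built in code at test time.

# Brute-force nearest-neighbour STDP over a complete spike record.
# Causal: every post spike pairs with the nearest pre spike at or before it
# (lag 0 is causal); acausal: every pre spike pairs with the nearest post
# spike strictly before it. Kernel staircases are given explicitly; the
# modulated contribution of a pair at lag dt is sign * fx_shift(exp[dt], xm).
nn_stdp_oracle <- function(pre, post, ca_exp, ac_exp, t_ca, t_ac, xm,
                           sign_ca = 1L, sign_ac = -1L) {
  tot <- 0L
  for (s in post) {
    p <- pre[pre <= s]
    if (length(p)) {
      dt <- s - max(p)
      if (dt <= t_ca) tot <- tot + sign_ca * fx_shift(ca_exp[dt + 1L], xm)
    }
  }
  for (q in pre) {
    s <- post[post <= q - 1L]
    if (length(s)) {
      dt <- q - max(s)
      if (dt <= t_ac) tot <- tot + sign_ac * fx_shift(ac_exp[dt + 1L], xm)
    }
  }
  tot
}

# One post neuron with a frozen modulator, one plastic external pre channel
# and one strong external forcing channel that makes the post spike.
# Returns the post raster and the engine's total weight change.
run_stdp_pair <- function(pre_ticks, force_ticks, ticks, seed = 1L,
                          half = 4L, t_ca = 16L, t_ac = 16L,
                          exp_ca = 2L, exp_ac = 1L, refr = 20L, xm = 64L) {
  g <- neuron_group(k = 2, A = as_shift_matrix(matrix(c(-2^-2, 0, 0, 0), 2, 2)),
                    theta = c(1000L, NA), reset_en = c(TRUE, FALSE), Xr = 0L,
                    refractory = refr, gain = c(4L, 0L), x_init = c(0L, xm))
  pl <- plasticity_stdp(t_ca = t_ca, t_ac = t_ac, exp_ca = exp_ca,
                        exp_ac = exp_ac, mode = "exponential", half_step = half,
                        mod = 2L, w_min = -100000000L, w_max = 100000000L, r_bits = 0L)
  syn <- rbind(
    synapse_table(pre = 2L, post = 1L, target = 1L, weight = 0L, plast = 1L),
    synapse_table(pre = 3L, post = 1L, target = 1L, weight = 120L)
  )
  cfg <- run_config(list(g), group_of = 1L, n_ext = 2L, synapses = syn,
                    plasticity = list(pl))
  ev <- rbind(data.frame(tick = pre_ticks, channel = 1L),
              data.frame(tick = force_ticks, channel = 2L))
  res <- sim_run(cfg, ticks, seed = seed, events = ev)
  kern <- cfg$plasticity[[1]]
  list(post = res$raster$tick, dw = res$state$w[1],
       ca_exp = kern$ca_exp, ac_exp = kern$ac_exp)
}

# Bernoulli-per-tick spike train on one channel (unique ticks).
poisson_ticks <- function(rate_hz, ticks, seed) {
  set.seed(seed)
  which(stats::runif(ticks) < rate_hz / 1000) - 1L
}

# A random heterogeneous network used for the partition-invariance and
# determinism checks: leaky two-component neurons with noise, sparse random
# connectivity with mixed delays, blank-out on half the synapses, and a
# plastic subset, driven by external Poisson channels.
random_network <- function(seed, n = 200L, cores = 1L, p_conn = 0.03) {
  set.seed(seed)
  g <- neuron_group(k = 2, A = as_shift_matrix(matrix(c(-2^-3, 0, 2^-2, -2^-2), 2, 2)),
                    b = c(60L, 0L), theta = c(600L, NA),
                    reset_en = c(TRUE, FALSE), Xr = 0L, refractory = 5L,
                    gain = c(2L, 0L), noise = c(8L, 6L))
  m <- matrix(stats::runif(n * n) < p_conn, n, n)
  diag(m) <- FALSE
  idx <- which(m, arr.ind = TRUE)
  w <- sample(c(-30:-10, 10:40), nrow(idx), replace = TRUE)
  pl <- plasticity_stdp(t_ca = 8L, t_ac = 8L, exp_ca = -2L, exp_ac = -2L,
                        mode = "linear", mod = 2L, w_min = -128L, w_max = 127L,
                        r_bits = 2L)
  syn_rec <- synapse_table(pre = idx[, 2], post = idx[, 1], target = 1L,
                           weight = w,
                           plast = ifelse(stats::runif(nrow(idx)) < 0.3, 1L, NA),
                           delay = sample(0:3, nrow(idx), replace = TRUE),
                           blankout = ifelse(stats::runif(nrow(idx)) < 0.5, 0.5, NA))
  n_ext <- 20L
  syn_in <- synapse_table(pre = n + sample(n_ext, n, replace = TRUE),
                          post = seq_len(n), target = 1L,
                          weight = sample(30:60, n, replace = TRUE))
  cfg <- run_config(list(g), group_of = rep(1L, n), n_ext = n_ext,
                    synapses = rbind(syn_rec, syn_in), plasticity = list(pl),
                    cores = cores, max_delay = 3L)
  ev <- poisson_trains(data.frame(from = 0, to = 5000, ch_from = 1, ch_to = n_ext,
                                  rate = 30), seed = seed + 1L)
  list(cfg = cfg, events = ev)
}
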