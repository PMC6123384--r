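# Network configuration: neuron parameter groups, shift-coefficient
# transition matrices, synapse tables, plasticity configs, and the validated
# run configuration handed to the compiled core.

#' Shift-coefficient matrix
#'
#' The transition matrix of a neuron group: every entry is a signed power of
#' two, stored as a sign in `{-1, 0, 1}` and an exponent in `[-15, 15]`
#' (sign 0 is the exact-zero sentinel). Entry `(i, j)` couples source
#' component `j` into target component `i`.
#'
#' @param sign integer matrix of signs.
#' @param exp integer matrix of exponents.
#' @return an object of class `shift_matrix`.
#' @seealso [as_shift_matrix()] to convert a numeric matrix whose entries
#'   are already signed powers of two, [nearest_shift()] to snap arbitrary
#'   reals.
#' @export
shift_matrix <- function(sign, exp) {
  sign <- as.matrix(sign); exp <- as.matrix(exp)
  storage.mode(sign) <- "integer"; storage.mode(exp) <- "integer"
  if (!identical(dim(sign), dim(exp))) stop("sign and exp dimensions differ")
  if (any(!sign %in% c(-1L, 0L, 1L))) stop("signs must be -1, 0 or +1")
  if (any(abs(exp[sign != 0L]) > 15L)) stop("|exponent| must be <= 15")
  exp[sign == 0L] <- 0L
  structure(list(sign = sign, exp = exp), class = "shift_matrix")
}

#' Convert a numeric matrix of signed powers of two
#'
#' @param m numeric matrix; entries must be 0 or `±2^e` with integer
#'   `e` in `[-15, 15]`.
#' @return a [shift_matrix()].
#' @export
as_shift_matrix <- function(m) {
  if (inherits(m, "shift_matrix")) return(m)
  m <- as.matrix(m)
  sgn <- sign(m)
  e <- matrix(0L, nrow(m), ncol(m))
  nz <- which(sgn != 0)
  if (length(nz)) {
    le <- log2(abs(m[nz]))
    if (any(abs(le - round(le)) > 1e-9)) {
      stop("entries must be exact signed powers of two; use nearest_shift() to snap")
    }
    e[nz] <- as.integer(round(le))
  }
  shift_matrix(sgn, e)
}

#' Snap real coefficients to the nearest signed power of two
#'
#' Model builders use this to map continuous-model constants onto the
#' logarithmic coefficient scale of the framework. Magnitudes below
#' `zero_tol` map to the exact-zero sentinel.
#'
#' @param x numeric vector or matrix.
#' @param zero_tol magnitudes below this snap to zero (default `2^-16`).
#' @return numeric object of the same shape with entries 0 or signed powers
#'   of two (exponents clamped to `[-15, 15]`).
#' @export
nearest_shift <- function(x, zero_tol = 2^-16) {
  out <- x
  z <- abs(x) < zero_tol
  out[z] <- 0
  nz <- !z
  e <- pmin(15, pmax(-15, round(log2(abs(x[nz])))))
  out[nz] <- sign(x[nz]) * 2^e
  out
}

#' Neuron parameter group
#'
#' All per-group neuron constants: the transition matrix of shift
#' coefficients, constant inputs, thresholds, resets, noise, refractory
#' period, and synaptic gain exponents.
#'
#' @param k number of state components (1-8). Component 1 is the spiking
#'   component: the neuron emits a spike when it reaches `theta[1]`.
#' @param A a [shift_matrix()] (or numeric matrix of exact signed powers of
#'   two) of couplings; entry `(i, j)` couples component `j` into `i`.
#' @param b integer constant input per component.
#' @param theta integer thresholds; component 1's is the firing threshold,
#'   others trigger the conditional reset when `reset_en` is set. Defaults
#'   to the width maximum (never reached).
#' @param reset_en logical per component: reset to `Xr` on reaching `theta`.
#' @param Xr integer reset values.
#' @param x_min optional integer lower clamp per component (e.g. 0 for
#'   rectified error integrators); defaults to the width minimum.
#' @param noise variance exponents per component (`NA` = noise off):
#'   additive zero-mean noise of variance `2^noise`.
#' @param refractory ticks the spiking component is clamped at its reset
#'   value after a spike.
#' @param gain per-component synaptic gain exponents: incoming weights are
#'   shifted by `2^gain` before accumulation.
#' @param x_init integer initial state per component.
#' @param derived optional derived-component rule, see [derived_vcal()].
#' @param name optional label used in printouts.
#' @return an object of class `neuron_group`.
#' @export
neuron_group <- function(k, A = NULL, b = 0L, theta = NULL, reset_en = TRUE,
                         Xr = 0L, x_min = NULL, noise = NA, refractory = 0L,
                         gain = 0L, x_init = 0L, derived = NULL, name = NULL) {
  k <- as.integer(k)
  if (k < 1L || k > 8L) stop("k must be in 1..8")
  if (is.null(A)) A <- shift_matrix(matrix(0L, k, k), matrix(0L, k, k))
  A <- as_shift_matrix(A)
  if (!identical(dim(A$sign), c(k, k))) stop("A must be k x k")
  rec <- function(v, default) {
    if (is.null(v)) v <- default
    v <- rep_len(v, k)
    v
  }
  g <- structure(list(
    k = k, A = A,
    b = as.integer(rec(b, 0L)),
    theta = rec(theta, NA),
    reset_en = as.logical(rec(reset_en, TRUE)),
    Xr = as.integer(rec(Xr, 0L)),
    x_min = rec(x_min, NA),
    noise = rec(noise, NA),
    refractory = as.integer(refractory),
    gain = as.integer(rec(gain, 0L)),
    x_init = as.integer(rec(x_init, 0L)),
    derived = derived, name = name
  ), class = "neuron_group")
  if (g$refractory < 0L) stop("refractory must be >= 0")
  if (any(abs(g$gain) > 15L)) stop("|gain exponent| must be <= 15")
  g
}

#' Voltage/calcium derived-component rule
#'
#' A per-group modulator update executed every tick after synaptic
#' accumulation: the comparator component `th` is set to `eta_plus` when
#' the membrane component exceeds `v_lth` and to `eta_minus` otherwise, and
#' the modulator component `mod` to the comparator plus a homeostatic term
#' `eta_h_sign * 2^eta_h_exp * (ca_target - Ca)` driving the calcium
#' component toward its set point. Used by the sequence-learning rule, where
#' the per-pre-spike weight update simply reads the modulator.
#'
#' @param v,ca,th,mod 1-based component indices of membrane, calcium,
#'   comparator and modulator.
#' @param v_lth membrane threshold separating potentiation from depression.
#' @param eta_plus,eta_minus integer LTP/LTD magnitudes.
#' @param eta_h_exp homeostasis shift exponent; `eta_h_sign = 0` disables
#'   the homeostatic term.
#' @param eta_h_sign sign of the homeostatic term.
#' @param ca_target calcium set point.
#' @return a list describing the rule.
#' @export
derived_vcal <- function(v = 1L, ca = 2L, th = 3L, mod = 4L, v_lth = 0L,
                         eta_plus = 8L, eta_minus = -2L, eta_h_exp = 0L,
                         eta_h_sign = 1L, ca_target = 0L) {
  list(type = "vcal", v = as.integer(v), ca = as.integer(ca),
       th = as.integer(th), mod = as.integer(mod), v_lth = as.integer(v_lth),
       eta_p = as.integer(eta_plus), eta_m = as.integer(eta_minus),
       eta_h_exp = as.integer(eta_h_exp), eta_h_sign = as.integer(eta_h_sign),
       ca_target = as.integer(ca_target))
}

.kernel_staircase <- function(amp_exp, window, half_step, stairs) {
  if (!is.null(stairs)) {
    stairs <- as.integer(stairs)
    if (length(stairs) != window + 1L) {
      stop("stairs must have one exponent per lag 0..window")
    }
    return(stairs)
  }
  if (is.finite(half_step)) {
    as.integer(amp_exp - (0:window) %/% as.integer(half_step))
  } else {
    rep(as.integer(amp_exp), window + 1L)
  }
}

#' Spike-timing plasticity configuration
#'
#' Three-factor nearest-neighbour STDP: on each triggering event the kernel
#' contributes a shift exponent at the spike-pair lag, the post-synaptic
#' modulator component is shifted by that exponent (update linear in the
#' modulator, logarithmic in the kernel), the kernel sign is applied, and
#' the result is clipped into `[w_min, w_max]` after randomized rounding
#' with `r_bits` probability bits. Kernels are exponent staircases: in
#' `exponential` mode the amplitude exponent drops by one every `half_step`
#' lags (a multiplier-free approximation of an exponential window); in
#' `linear` mode an explicit staircase can be given via `stairs_ca` /
#' `stairs_ac` (default: flat at the amplitude exponent).
#'
#' @param t_ca,t_ac causal / acausal window lengths in ticks (>= 1).
#' @param exp_ca,exp_ac amplitude shift exponents at lag 0.
#' @param mode kernel approximation mode.
#' @param half_step lags per one-exponent decay step (exponential mode).
#' @param stairs_ca,stairs_ac explicit exponent staircases (length
#'   `window + 1`, lag 0 first).
#' @param sign_ca,sign_ac kernel signs (causal potentiates, acausal
#'   depresses by default).
#' @param mod 1-based modulator component index on the post neuron.
#' @param w_min,w_max weight bounds (8-bit by default).
#' @param r_bits randomized-rounding bits.
#' @param gate optional boxcar gate `list(comp, min, max)`: updates are
#'   committed only while the gated post component lies in `[min, max]`.
#' @param on_dropped if `TRUE`, updates are computed even for deliveries
#'   dropped by blank-out (the stochastic-sampling mode); otherwise dropped
#'   deliveries do not update.
#' @return an object of class `plasticity_config`.
#' @export
plasticity_stdp <- function(t_ca, t_ac, exp_ca = 0L, exp_ac = 0L,
                            mode = c("exponential", "linear"), half_step = Inf,
                            stairs_ca = NULL, stairs_ac = NULL,
                            sign_ca = 1L, sign_ac = -1L, mod = 1L,
                            w_min = -128L, w_max = 127L, r_bits = 0L,
                            gate = NULL, on_dropped = FALSE) {
  mode <- match.arg(mode)
  t_ca <- as.integer(t_ca); t_ac <- as.integer(t_ac)
  if (t_ca < 1L || t_ac < 1L) stop("STDP windows must be >= 1 tick")
  if (mode == "exponential" && !is.finite(half_step) &&
      (is.null(stairs_ca) && is.null(stairs_ac))) {
    half_step <- Inf # flat staircase: exponential with infinite half-decay
  }
  structure(list(
    type = "stdp", mod = as.integer(mod),
    t_ca = t_ca, t_ac = t_ac,
    ca_exp = .kernel_staircase(exp_ca, t_ca, half_step, stairs_ca),
    ac_exp = .kernel_staircase(exp_ac, t_ac, half_step, stairs_ac),
    sign_ca = as.integer(sign_ca), sign_ac = as.integer(sign_ac),
    w_min = as.integer(w_min), w_max = as.integer(w_max),
    r_bits = as.integer(r_bits), gate = gate,
    on_dropped = isTRUE(on_dropped), state_exp = 0L
  ), class = "plasticity_config")
}

#' State-modulated plasticity configuration
#'
#' The acausal-only, state-dependent rule: on every pre-synaptic spike the
#' weight changes by the post neuron's modulator component shifted by
#' `gain_exp`, optionally gated by a boxcar on another component. This is
#' the rule used for error-modulated membrane-gated learning and for the
#' voltage/calcium sequence-learning rule.
#'
#' @inheritParams plasticity_stdp
#' @param gain_exp shift exponent applied to the modulator (the learning
#'   rate, on the logarithmic scale).
#' @return an object of class `plasticity_config`.
#' @export
plasticity_state <- function(mod, gain_exp = 0L, w_min = -128L, w_max = 127L,
                             r_bits = 0L, gate = NULL, on_dropped = FALSE) {
  structure(list(
    type = "state", mod = as.integer(mod),
    t_ca = 1L, t_ac = 1L, ca_exp = c(0L, 0L), ac_exp = c(0L, 0L),
    sign_ca = 1L, sign_ac = -1L,
    w_min = as.integer(w_min), w_max = as.integer(w_max),
    r_bits = as.integer(r_bits), gate = gate,
    on_dropped = isTRUE(on_dropped), state_exp = as.integer(gain_exp)
  ), class = "plasticity_config")
}

#' Synapse table
#'
#' Forward-indexed adjacency rows: pre-synaptic source, post-synaptic
#' neuron, target state component, signed low-precision weight, optional
#' plasticity config id, axonal delay and blank-out probability.
#'
#' Internal neurons are numbered `1..n_neurons`; external input channels
#' follow at `n_neurons + 1 .. n_neurons + n_ext`.
#'
#' @param pre,post integer ids (post must be internal).
#' @param target 1-based target state component on the post neuron.
#' @param weight integer weight within the plasticity (or default 8-bit)
#'   bounds.
#' @param plast plasticity config id (index into the `plasticity` list of
#'   [run_config()]), or `NA` for a static synapse.
#' @param delay axonal delay in ticks (>= 0).
#' @param blankout blank-out survival probability in `[0, 1]`, quantized to
#'   `n/256`; `NA` disables blank-out.
#' @param weight_id optional shared weight-store index: rows with the same
#'   id read and write the same weight (used for symmetric connections);
#'   defaults to one weight per row.
#' @return a `data.frame` with class `synapse_table`; rows may be combined
#'   with `rbind()`.
#' @export
synapse_table <- function(pre, post, target = 1L, weight = 0L, plast = NA,
                          delay = 0L, blankout = NA, weight_id = NA) {
  n <- max(length(pre), length(post))
  d <- data.frame(
    pre = as.integer(rep_len(pre, n)),
    post = as.integer(rep_len(post, n)),
    target = as.integer(rep_len(target, n)),
    weight = as.integer(rep_len(weight, n)),
    plast = as.integer(rep_len(plast, n)),
    delay = as.integer(rep_len(delay, n)),
    blankout = as.numeric(rep_len(blankout, n)),
    weight_id = as.integer(rep_len(weight_id, n))
  )
  class(d) <- c("synapse_table", "data.frame")
  d
}

#' Assemble and validate a run configuration
#'
#' Collects neuron groups, the per-neuron group assignment, synapse tables
#' and plasticity configurations into a validated network description. All
#' validation failures are reported together.
#'
#' @param groups list of [neuron_group()] objects.
#' @param group_of integer vector: group id (1-based) of every internal
#'   neuron; its length is the network size.
#' @param n_ext number of external input channels.
#' @param synapses a [synapse_table()] (or `rbind` of several), or `NULL`.
#' @param plasticity list of plasticity configurations referenced by the
#'   synapse table's `plast` column.
#' @param cores number of simulated cores (neurons are split contiguously),
#'   or an explicit per-neuron core assignment vector (1-based).
#' @param state_bits state width in bits (default 16).
#' @param max_delay maximum axonal delay the delivery buffer must hold;
#'   defaults to the largest delay in the synapse table.
#' @param learn_period,learn_freeze optional global plasticity schedule:
#'   with a period `P > 0`, weight updates are disabled during the first
#'   `learn_freeze` ticks of every `P`-tick block (used to blank learning
#'   during stimulus transitions).
#' @return an object of class `run_config`.
#' @export
run_config <- function(groups, group_of, n_ext = 0L, synapses = NULL,
                       plasticity = list(), cores = 1L, state_bits = 16L,
                       max_delay = NULL, learn_period = 0L, learn_freeze = 0L) {
  if (inherits(groups, "neuron_group")) groups <- list(groups)
  group_of <- as.integer(group_of)
  n <- length(group_of)
  if (is.null(synapses)) synapses <- synapse_table(integer(), integer())
  if (length(cores) == 1L) {
    core_of <- ((seq_len(n) - 1L) * as.integer(cores)) %/% max(n, 1L) + 1L
  } else {
    core_of <- as.integer(rep_len(cores, n))
  }
  cfg <- structure(list(
    groups = groups, group_of = group_of, n_neurons = n,
    n_ext = as.integer(n_ext), synapses = synapses,
    plasticity = plasticity, core_of = core_of,
    n_cores = if (length(core_of)) max(core_of) else 1L,
    state_bits = as.integer(state_bits),
    max_delay = if (is.null(max_delay)) {
      if (nrow(synapses)) max(synapses$delay) else 0L
    } else as.integer(max_delay),
    learn_period = as.integer(learn_period),
    learn_freeze = as.integer(learn_freeze)
  ), class = "run_config")
  errs <- validate_config(cfg)
  if (length(errs)) {
    stop(paste0("invalid configuration:\n  - ", paste(errs, collapse = "\n  - ")))
  }
  cfg$core <- .build_core_cfg(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Returns all validation failures (empty character vector when valid);
#' [run_config()] calls this and stops on any failure.
#'
#' @param cfg a (possibly not yet validated) `run_config` structure.
#' @return character vector of problems.
#' @export
validate_config <- function(cfg) {
  errs <- character()
  add <- function(...) errs <<- c(errs, sprintf(...))
  smax <- 2^(cfg$state_bits - 1) - 1
  smin <- -2^(cfg$state_bits - 1)
  ng <- length(cfg$groups)
  if (any(cfg$group_of < 1L | cfg$group_of > ng)) {
    add("group_of references an undefined group (valid ids 1..%d)", ng)
  }
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    inrange <- function(v) all(is.na(v) | (v >= smin & v <= smax))
    if (!inrange(g$b)) add("group %d: bias outside the %d-bit width", gi, cfg$state_bits)
    if (!inrange(g$theta)) add("group %d: threshold outside the state width", gi)
    if (!inrange(g$Xr)) add("group %d: reset value outside the state width", gi)
    if (!inrange(g$x_init)) add("group %d: initial state outside the state width", gi)
    if (any(abs(g$A$exp[g$A$sign != 0L]) > 15L)) {
      add("group %d: |transition exponent| must be <= 15", gi)
    }
    if (!is.null(g$derived)) {
      idx <- c(g$derived$v, g$derived$ca, g$derived$th, g$derived$mod)
      if (any(idx < 1L | idx > g$k)) add("group %d: derived rule references component > k", gi)
      if (any(g$reset_en[c(g$derived$th, g$derived$mod)])) {
        add("group %d: derived components must have reset disabled", gi)
      }
    }
  }
  s <- cfg$synapses
  if (nrow(s)) {
    npre <- cfg$n_neurons + cfg$n_ext
    if (any(s$pre < 1L | s$pre > npre)) {
      add("synapse pre ids must be in 1..%d (internal then external)", npre)
    }
    bad_post <- s$post < 1L | s$post > cfg$n_neurons
    if (any(bad_post)) add("synapse post ids must reference internal neurons 1..%d", cfg$n_neurons)
    kp <- ifelse(bad_post, NA,
                 vapply(cfg$groups, function(g) g$k, 1L)[cfg$group_of[pmin(pmax(s$post, 1L), cfg$n_neurons)]])
    if (any(!is.na(kp) & s$target > kp)) add("synapse target component exceeds the post group's k")
    if (any(s$target < 1L)) add("synapse target component must be >= 1")
    if (any(s$delay < 0L)) add("synaptic delays must be >= 0")
    if (any(s$delay > cfg$max_delay)) add("synaptic delay exceeds max_delay")
    pl_ok <- is.na(s$plast) | (s$plast >= 1L & s$plast <= length(cfg$plasticity))
    if (!all(pl_ok)) add("synapse references an undefined plasticity config")
    for (i in which(!is.na(s$plast) & pl_ok)) {
      p <- cfg$plasticity[[s$plast[i]]]
      if (s$weight[i] < p$w_min || s$weight[i] > p$w_max) {
        add("synapse %d: weight %d outside plasticity bounds [%d, %d]",
            i, s$weight[i], p$w_min, p$w_max)
      }
    }
    static <- is.na(s$plast)
    if (any(static & (s$weight < -128L | s$weight > 127L))) {
      add("static synapse weight outside the 8-bit range [-128, 127]")
    }
    if (any(!is.na(s$blankout) & (s$blankout < 0 | s$blankout > 1))) {
      add("blank-out probabilities must lie in [0, 1]")
    }
  }
  for (pi in seq_along(cfg$plasticity)) {
    p <- cfg$plasticity[[pi]]
    if (p$w_min >= p$w_max) add("plasticity %d: w_min must be < w_max", pi)
    if (p$r_bits < 0L) add("plasticity %d: r_bits must be >= 0", pi)
    if (any(abs(c(p$ca_exp, p$ac_exp, p$state_exp)) > 15L)) {
      add("plasticity %d: |kernel exponent| must be <= 15", pi)
    }
  }
  errs
}

# flatten a validated config into the integer-only form the C++ core reads
.build_core_cfg <- function(cfg) {
  smin <- -2^(cfg$state_bits - 1)
  smax <- 2^(cfg$state_bits - 1) - 1
  k_max <- max(vapply(cfg$groups, function(g) g$k, 1L))
  groups <- lapply(cfg$groups, function(g) {
    # NA thresholds default to the width maximum (only reachable at saturation)
    theta <- as.integer(pmin(pmax(ifelse(is.na(g$theta), smax, g$theta), smin), smax))
    xm <- ifelse(is.na(g$x_min), smin, g$x_min)
    noise_a <- vapply(g$noise, function(v) {
      if (is.na(v)) 0L else fx_noise_config_cpp(as.integer(v))
    }, 1L)
    list(k = g$k, a_sign = g$A$sign, a_exp = g$A$exp,
         b = g$b, theta = theta, reset_en = as.integer(g$reset_en),
         xr = g$Xr, x_min = as.integer(pmax(xm, smin)),
         noise_a = as.integer(noise_a), refr = g$refractory,
         gain_exp = g$gain,
         derived = if (is.null(g$derived)) NULL else {
           d <- g$derived
           list(v = d$v - 1L, ca = d$ca - 1L, th = d$th - 1L, mod = d$mod - 1L,
                v_lth = d$v_lth, eta_p = d$eta_p, eta_m = d$eta_m,
                eta_h_exp = d$eta_h_exp, eta_h_sign = d$eta_h_sign,
                ca_target = d$ca_target)
         })
  })
  plast <- lapply(cfg$plasticity, function(p) {
    gate <- p$gate
    list(type = if (p$type == "stdp") 0L else 1L,
         mod = p$mod - 1L,
         gate = if (is.null(gate)) -1L else as.integer(gate$comp) - 1L,
         gmin = if (is.null(gate)) 0L else as.integer(gate$min),
         gmax = if (is.null(gate)) 0L else as.integer(gate$max),
         wmin = p$w_min, wmax = p$w_max, rbits = p$r_bits,
         on_dropped = as.integer(p$on_dropped),
         tca = p$t_ca, tac = p$t_ac,
         ca_exp = p$ca_exp, ac_exp = p$ac_exp,
         ca_sign = p$sign_ca, ac_sign = p$sign_ac,
         state_exp = p$state_exp)
  })
  s <- cfg$synapses
  n_pre <- cfg$n_neurons + cfg$n_ext
  ord <- order(s$pre)
  s <- s[ord, , drop = FALSE]
  widx <- s$weight_id
  if (all(is.na(widx))) {
    widx <- seq_len(nrow(s))
  } else {
    widx[is.na(widx)] <- if (any(!is.na(s$weight_id))) {
      max(s$weight_id, na.rm = TRUE) + seq_len(sum(is.na(widx)))
    } else seq_len(sum(is.na(widx)))
  }
  n_w <- if (nrow(s)) max(widx) else 0L
  w0 <- integer(n_w)
  if (nrow(s)) w0[widx] <- s$weight # last writer wins; shared rows carry equal weights
  bo_num <- ifelse(is.na(s$blankout), 0L, as.integer(round(s$blankout * 256)))
  bo_den <- ifelse(is.na(s$blankout), -1L, 8L)
  pl0 <- ifelse(is.na(s$plast), -1L, s$plast - 1L)
  row_ptr <- integer(n_pre + 1L)
  counts <- tabulate(s$pre, nbins = n_pre)
  row_ptr <- c(0L, cumsum(counts))
  max_tca_of <- integer(n_pre); has_pl <- integer(n_pre); has_stdp <- integer(n_pre)
  if (nrow(s)) {
    ppl <- which(pl0 >= 0L)
    for (i in ppl) {
      p <- cfg$plasticity[[s$plast[i]]]
      pre <- s$pre[i]
      has_pl[pre] <- 1L
      if (p$type == "stdp") {
        has_stdp[pre] <- 1L
        max_tca_of[pre] <- max(max_tca_of[pre], p$t_ca)
      }
    }
  }
  list(
    n_neurons = cfg$n_neurons, n_ext = cfg$n_ext, k_max = k_max,
    state_bits = cfg$state_bits, max_delay = cfg$max_delay,
    learn_period = cfg$learn_period, learn_freeze = cfg$learn_freeze,
    group_of = cfg$group_of - 1L, core_of = cfg$core_of - 1L,
    n_cores = cfg$n_cores,
    groups = groups, plast = plast,
    syn = list(pre = s$pre - 1L, post = s$post - 1L, tgt = s$target - 1L,
               widx = as.integer(widx) - 1L, pl = as.integer(pl0),
               delay = s$delay, bo_num = as.integer(bo_num),
               bo_den = as.integer(bo_den)),
    row_ptr = row_ptr, n_weights = n_w, w0 = w0,
    max_tca_of = max_tca_of, has_pl = has_pl, has_stdp = has_stdp
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d neurons in %d group(s), %d external channel(s), %d synapse(s), %d core(s)\n",
              x$n_neurons, length(x$groups), x$n_ext, nrow(x$synapses), x$n_cores))
  invisible(x)
}
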