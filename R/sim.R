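# Running a configured network: state containers, the tick loop wrapper,
# and run records (raster, watched-state traces, SynOp counts).

#' Create the initial simulator state for a configuration
#'
#' State holds everything that evolves during a run: per-neuron state
#' vectors, refractory counters, spike timers, the double-buffered synaptic
#' accumulators, the weight store and scheduled future deliveries. A run is
#' a pure function of (configuration, state, events, seed), so runs can be
#' chunked: feeding the returned state into the next [sim_run()] call
#' continues the simulation exactly.
#'
#' @param cfg a [run_config()].
#' @return a list of class `sim_state`.
#' @export
sim_state <- function(cfg) {
  core <- cfg$core
  n <- core$n_neurons
  x <- matrix(0L, n, core$k_max)
  for (i in seq_len(n)) {
    g <- cfg$groups[[cfg$group_of[i]]]
    x[i, seq_len(g$k)] <- g$x_init
  }
  structure(list(
    x = x,
    refr = integer(n),
    last_spike = rep.int(-1000000000L, n + core$n_ext),
    pending = integer(n + core$n_ext),
    acc = matrix(0L, n, core$k_max),
    w = core$w0,
    synops = 0,
    tick = 0L,
    future = matrix(0L, 0L, 2L)
  ), class = "sim_state")
}

#' Run the two-stage tick loop
#'
#' Each tick runs in two stages with barriers between them: every core
#' integrates its neurons' dynamics and detects threshold crossings
#' (stage 1); detected spikes are routed, becoming available to their
#' targets at `tick + 1 + delay`; then every core accumulates the
#' deliveries due this tick, runs the plasticity engine, updates derived
#' modulator components and applies conditional resets (stage 2). The
#' result is independent of how neurons are partitioned across cores.
#'
#' @param cfg a [run_config()].
#' @param ticks number of ticks to simulate.
#' @param seed integer seed keying every random draw of the run.
#' @param state a [sim_state()] to continue from, or `NULL` to start fresh.
#' @param events external input events: a `data.frame` with columns `tick`
#'   (0-based), `channel` (1-based external channel) and optionally
#'   `delay`. Events outside the simulated window are ignored.
#' @param watch integer ids of neurons whose full state vector is recorded
#'   every tick.
#' @param record_spikes set `FALSE` to skip raster recording in long
#'   training runs.
#' @return an object of class `sim_result`: `raster` (data.frame with
#'   `tick`, `core`, `neuron`), `traces` (ticks x watched x components
#'   array, if `watch` was given), `synops` (deliveries accumulated during
#'   this run, after blank-out), `state` (final state), `ticks`.
#' @export
sim_run <- function(cfg, ticks, seed = 1L, state = NULL, events = NULL,
                    watch = NULL, record_spikes = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  ticks <- as.integer(ticks)
  if (ticks < 0L) stop("ticks must be >= 0")
  if (is.null(state)) state <- sim_state(cfg)
  ev <- .events_matrix(events, cfg, from = state$tick, to = state$tick + ticks)
  if (is.null(watch)) watch <- integer()
  watch <- as.integer(watch)
  if (length(watch) && any(watch < 1L | watch > cfg$n_neurons)) {
    stop("watch ids must reference internal neurons")
  }
  synops0 <- state$synops
  out <- sim_run_cpp(cfg$core, unclass(state), ev, ticks, as.integer(seed),
                     watch - 1L, isTRUE(record_spikes))
  st <- out$state
  class(st) <- "sim_state"
  raster <- data.frame(tick = out$raster[, 1],
                       neuron = out$raster[, 2] + 1L)
  raster$core <- if (nrow(raster)) cfg$core_of[raster$neuron] else integer()
  raster <- raster[, c("tick", "core", "neuron")]
  res <- structure(list(
    raster = raster,
    synops = st$synops - synops0,
    state = st,
    ticks = ticks,
    seed = as.integer(seed)
  ), class = "sim_result")
  if (length(watch)) {
    tr <- out$traces
    dimnames(tr) <- list(NULL, paste0("n", watch), paste0("x", seq_len(dim(tr)[3]) - 1L))
    res$traces <- tr
    res$watch <- watch
  }
  res
}

.events_matrix <- function(events, cfg, from, to) {
  if (is.null(events) || NROW(events) == 0L) {
    return(matrix(0L, 0L, 3L))
  }
  ev <- as.data.frame(events)
  if (!all(c("tick", "channel") %in% names(ev))) {
    stop("events need columns tick and channel")
  }
  if (is.null(ev$delay)) ev$delay <- 0L
  if (any(ev$channel < 1L | ev$channel > cfg$n_ext)) {
    stop(sprintf("event channels must be in 1..%d", cfg$n_ext))
  }
  if (any(ev$tick < 0L)) stop("event ticks must be >= 0")
  if (any(ev$delay < 0L | ev$delay > cfg$max_delay)) {
    stop("event delays must be in [0, max_delay]")
  }
  keep <- ev$tick >= from & ev$tick < to
  ev <- ev[keep, , drop = FALSE]
  ev <- ev[order(ev$tick, ev$channel), , drop = FALSE]
  cbind(as.integer(ev$tick), as.integer(ev$channel) - 1L, as.integer(ev$delay))
}

#' Total synaptic operations of a run
#'
#' One SynOp is one spike delivery accumulated onto a post-synaptic state
#' component (after blank-out); it is the framework's unit of computational
#' cost, the event-driven counterpart of a multiply-accumulate.
#'
#' @param record a [sim_run()] result.
#' @return numeric SynOp count.
#' @export
count_synops <- function(record) {
  stopifnot(inherits(record, "sim_result"))
  record$synops
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d ticks, %d spikes, %.0f SynOps (seed %d)\n",
              x$ticks, nrow(x$raster), x$synops, x$seed))
  invisible(x)
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> at tick %d: %d neurons, %d weights, %.0f SynOps so far\n",
              x$tick, nrow(x$x), length(x$w), x$synops))
  invisible(x)
}

#' Per-neuron spike counts from a raster
#'
#' @param raster a raster `data.frame` (from [sim_run()]).
#' @param n_neurons network size.
#' @param from,to optional tick window `[from, to)`.
#' @return integer vector of counts per neuron id.
#' @export
spike_counts <- function(raster, n_neurons, from = -Inf, to = Inf) {
  r <- raster[raster$tick >= from & raster$tick < to, , drop = FALSE]
  tabulate(r$neuron, nbins = n_neurons)
}
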