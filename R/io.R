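# Event and raster file IO.  Events use a plain tabular text format
# (address-event style: tick, channel, optional delay) so files are
# inspectable and diffable; rasters are written as tick,core,neuron CSV.

#' Read an event file
#'
#' Parses a comma-separated event table with columns `tick, channel[,
#' delay]` (header optional). Events are returned sorted by tick. Malformed
#' fields are reported with their line number.
#'
#' @param path file path.
#' @return `data.frame` with columns `tick`, `channel`, `delay`.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(tick = integer(), channel = integer(), delay = integer()))
  }
  start <- 1L
  if (grepl("[A-Za-z]", lines[1])) start <- 2L # header row
  if (start > length(lines)) {
    return(data.frame(tick = integer(), channel = integer(), delay = integer()))
  }
  parts <- strsplit(lines[start:length(lines)], ",")
  out <- matrix(NA_integer_, length(parts), 3L)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    lineno <- start + i - 1L
    if (length(p) < 2L || length(p) > 3L) {
      stop(sprintf("line %d: expected 2 or 3 comma-separated fields", lineno))
    }
    v <- suppressWarnings(as.numeric(p))
    if (any(is.na(v)) || any(v != floor(v))) {
      stop(sprintf("line %d: non-integer field", lineno))
    }
    if (v[1] < 0) stop(sprintf("line %d: negative tick", lineno))
    out[i, seq_along(v)] <- as.integer(v)
  }
  out[is.na(out[, 3]), 3] <- 0L
  d <- data.frame(tick = out[, 1], channel = out[, 2], delay = out[, 3])
  d[order(d$tick, d$channel), , drop = FALSE]
}

#' Write an event file
#'
#' Events are sorted by tick on write; `read_events(write_events(x))`
#' round-trips exactly.
#'
#' @param events `data.frame` with columns `tick`, `channel` and optionally
#'   `delay`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- as.data.frame(events)
  if (is.null(ev$delay)) ev$delay <- 0L
  ev <- ev[order(ev$tick, ev$channel), c("tick", "channel", "delay")]
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a spike raster
#'
#' @param result a [sim_run()] result.
#' @param path file path; a `tick,core,neuron` CSV is written.
#' @return `path`, invisibly.
#' @export
write_raster <- function(result, path) {
  utils::write.csv(result$raster, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run summary log line
#'
#' One line with the package version, a content hash of the configuration
#' and the seed, so any raster can be traced back to the run that produced
#' it.
#'
#' @param cfg a [run_config()].
#' @param seed run seed.
#' @return the log string, invisibly; it is also emitted via `message()`.
#' @export
log_run <- function(cfg, seed) {
  h <- config_hash(cfg)
  msg <- sprintf("spikefix %s | config %s | seed %d",
                 as.character(utils::packageVersion("spikefix")), h, as.integer(seed))
  message(msg)
  invisible(msg)
}

#' Content hash of a configuration
#'
#' A short FNV-1a hash over the serialized configuration, for logging.
#'
#' @param cfg a [run_config()].
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg[setdiff(names(cfg), "core")], NULL, version = 2))
  # two rolling hashes over small prime moduli (kept < 2^26 so the double
  # arithmetic stays exact), concatenated
  h1 <- 17; h2 <- 29
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 67108859
    h2 <- (h2 * 137 + b) %% 67108837
  }
  sprintf("%07x%07x", h1, h2)
}
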