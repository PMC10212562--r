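#' Stimulus protocol metadata
#'
#' Describes the light stimulus attached to a sweep set: when within the sweep
#' the light pulse starts, how long it lasts, its intensity as a fraction of
#' the maximal output, and the inter-trial interval. All analysis latencies in
#' the package are reported relative to `onset_ms` ("from light onset").
#'
#' @param onset_ms Pulse onset, ms from the start of the sweep (>= 0).
#' @param duration_ms Pulse duration in ms (typically 1-10).
#' @param intensity_frac Light intensity as a fraction of maximum, in (0, 1].
#' @param iti_s Inter-trial interval in seconds.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(onset_ms = 10, duration_ms = 5,
                              intensity_frac = 0.9, iti_s = 8) {
  stopifnot(is.numeric(onset_ms), length(onset_ms) == 1L, onset_ms >= 0)
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop("stimulus duration must be positive", call. = FALSE)
  if (!is.numeric(intensity_frac) || intensity_frac <= 0 || intensity_frac > 1)
    stop("stimulus intensity must be in (0, 1]", call. = FALSE)
  structure(
    list(onset_ms = as.numeric(onset_ms),
         duration_ms = as.numeric(duration_ms),
         intensity_frac = as.numeric(intensity_frac),
         iti_s = as.numeric(iti_s)),
    class = "stimulus_protocol")
}

#' A single sampled trace
#'
#' One uniformly sampled recording: an LFP (mV), a current-clamp voltage
#' record (mV), or a voltage-clamp current record (pA). Sample 0 is the
#' start of the sweep; times are in ms.
#'
#' @param samples Numeric vector of samples (mV for lfp/current_clamp,
#'   pA for voltage_clamp).
#' @param rate_hz Sampling rate in samples per second (default 20000).
#' @param kind One of `"lfp"`, `"current_clamp"`, `"voltage_clamp"`.
#' @param holding_mv Holding potential in mV; required iff
#'   `kind == "voltage_clamp"`.
#' @return An object of class `trace`.
#' @export
trace <- function(samples, rate_hz = 20000,
                  kind = c("lfp", "current_clamp", "voltage_clamp"),
                  holding_mv = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(samples), length(samples) >= 1L)
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    stop("sampling rate must be positive", call. = FALSE)
  if (kind == "voltage_clamp" && is.null(holding_mv))
    stop("voltage_clamp traces require a holding potential", call. = FALSE)
  if (kind != "voltage_clamp" && !is.null(holding_mv))
    stop("holding potential is only meaningful for voltage_clamp traces",
         call. = FALSE)
  structure(
    list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
         kind = kind,
         holding_mv = if (is.null(holding_mv)) NULL else as.numeric(holding_mv)),
    class = "trace")
}

#' @export
length.trace <- function(x) length(x$samples)

#' Sample times of a trace in ms
#'
#' @param t A [trace()].
#' @return Numeric vector of sample times in ms from sweep start.
#' @export
trace_times_ms <- function(t) {
  stopifnot(inherits(t, "trace"))
  (seq_along(t$samples) - 1) * 1000 / t$rate_hz
}

.known_conditions <- c("control", "cnqx_apv", "ttx", "gabazine")

#' A set of repeated stimulus-aligned sweeps
#'
#' The universal input container: a list of equal-length, equal-rate,
#' equal-kind [trace()] objects recorded under one stimulus protocol and one
#' pharmacological condition.
#'
#' @param sweeps List of [trace()] objects sharing kind, rate and length.
#' @param protocol A [stimulus_protocol()].
#' @param condition One of `"control"`, `"cnqx_apv"`, `"ttx"`, `"gabazine"`.
#' @param labels Named list of free-form metadata (animal/slice/cell ids,
#'   per-sweep current steps, ...). Values must be length-1 atomic or
#'   numeric vectors.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, protocol, condition = "control", labels = list()) {
  if (!is.list(sweeps) || length(sweeps) < 1L)
    stop("a sweep set needs at least one sweep", call. = FALSE)
  if (!all(vapply(sweeps, inherits, logical(1), "trace")))
    stop("all sweeps must be trace objects", call. = FALSE)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (!condition %in% .known_conditions)
    stop("unknown condition: ", condition, call. = FALSE)
  kinds <- vapply(sweeps, function(s) s$kind, character(1))
  rates <- vapply(sweeps, function(s) s$rate_hz, numeric(1))
  lens <- vapply(sweeps, length, integer(1))
  if (length(unique(kinds)) != 1L || length(unique(rates)) != 1L ||
      length(unique(lens)) != 1L)
    stop("all sweeps must share kind, rate and length", call. = FALSE)
  sweep_ms <- lens[1] * 1000 / rates[1]
  if (protocol$onset_ms + protocol$duration_ms >= sweep_ms)
    stop("stimulus must end before the sweep does", call. = FALSE)
  structure(
    list(sweeps = sweeps, protocol = protocol, condition = condition,
         labels = labels),
    class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  s <- x$sweeps[[1]]
  cat(sprintf("<sweep_set> %d x %s sweep(s), %d samples @ %g kHz, condition=%s\n",
              length(x$sweeps), s$kind, length(s), s$rate_hz / 1000,
              x$condition))
  cat(sprintf("  stimulus: onset %g ms, duration %g ms, intensity %.0f%%\n",
              x$protocol$onset_ms, x$protocol$duration_ms,
              100 * x$protocol$intensity_frac))
  invisible(x)
}

#' Pointwise average of the sweeps in a set
#'
#' Arithmetic mean across sweeps at every sample, preserving kind and rate.
#' This is the "average of 20-100 trials" step that precedes LFP feature
#' extraction.
#'
#' @param s A [sweep_set()].
#' @return A [trace()] with the pointwise mean.
#' @export
average_sweeps <- function(s) {
  stopifnot(inherits(s, "sweep_set"))
  m <- vapply(s$sweeps, function(tr) tr$samples,
              numeric(length(s$sweeps[[1]])))
  avg <- if (is.matrix(m)) rowMeans(m) else m
  t1 <- s$sweeps[[1]]
  trace(avg, rate_hz = t1$rate_hz, kind = t1$kind, holding_mv = t1$holding_mv)
}
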