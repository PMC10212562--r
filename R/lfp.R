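# Decomposition of averaged LFPs into artifact / presynaptic /
# postsynaptic components and extraction of ripplet features.

#' Remove the stimulus artifact from an averaged LFP
#'
#' The response remaining under TTX is a square optoelectrical artifact
#' coincident with the light pulse; subtracting the TTX average removes it
#' from every other condition.
#'
#' @param control_avg,ttx_avg Averaged [trace()]s of equal rate and length.
#' @return A [trace()] with the pointwise difference.
#' @export
subtract_artifact <- function(control_avg, ttx_avg) {
  .check_same_shape(control_avg, ttx_avg)
  trace(control_avg$samples - ttx_avg$samples,
        rate_hz = control_avg$rate_hz, kind = control_avg$kind,
        holding_mv = control_avg$holding_mv)
}

#' Isolate the postsynaptic component of an averaged LFP
#'
#' Subtracting the iGluR-blocked (CNQX+APV) average from the control average
#' removes the presynaptic volley component and the artifact, leaving the
#' purely postsynaptic ripplet waveform.
#'
#' @param control_avg,blocked_avg Averaged [trace()]s of equal rate/length.
#' @return A [trace()] with the pointwise difference.
#' @export
isolate_postsynaptic <- function(control_avg, blocked_avg) {
  .check_same_shape(control_avg, blocked_avg)
  trace(control_avg$samples - blocked_avg$samples,
        rate_hz = control_avg$rate_hz, kind = control_avg$kind,
        holding_mv = control_avg$holding_mv)
}

.check_same_shape <- function(a, b) {
  stopifnot(inherits(a, "trace"), inherits(b, "trace"))
  if (length(a) != length(b) || a$rate_hz != b$rate_hz)
    stop("traces must have equal length and sampling rate", call. = FALSE)
  invisible(NULL)
}

#' Configuration for ripplet feature detection
#'
#' @param amp_threshold_mv Minimum (absolute) amplitude for a transient
#'   candidate, mV.
#' @param inclusion_mv Slice-level inclusion criterion: the largest
#'   transient must reach this amplitude, else the slice is flagged below
#'   criterion.
#' @param min_period_ms Minimum separation between transients.
#' @param volley_window_ms Search window for the presynaptic volley on
#'   control traces, ms from light onset.
#' @param transient_window_ms Search window for transients, ms from onset.
#' @param lowpass_hz Zero-phase pre-smoothing cutoff (the acquisition
#'   filter's 1.3 kHz).
#' @return A list of detection settings.
#' @export
ripplet_config <- function(amp_threshold_mv = 0.1, inclusion_mv = 0.5,
                           min_period_ms = 1.5,
                           volley_window_ms = c(1, 3.5),
                           transient_window_ms = c(3, 20),
                           lowpass_hz = 1300) {
  list(amp_threshold_mv = amp_threshold_mv, inclusion_mv = inclusion_mv,
       min_period_ms = min_period_ms, volley_window_ms = volley_window_ms,
       transient_window_ms = transient_window_ms, lowpass_hz = lowpass_hz)
}

#' Detect ripplet features in an averaged LFP
#'
#' Transients are the negative maxima exceeding the amplitude threshold in
#' the post-onset transient window, separated by at least `min_period_ms`;
#' troughs are the positive maxima between consecutive transients, plus a
#' leading trough before the first transient and a trailing trough after
#' the last (so trough count = transient count + 1). The presynaptic
#' volley(s) are measured on the blocked (CNQX+APV) average when supplied -
#' there, all negative peaks across the full response window are volleys -
#' otherwise the first volley is taken from the early segment of the
#' control average. All times are sub-sample (parabolic interpolation) and
#' reported in ms from light onset.
#'
#' @param avg Averaged LFP [trace()] (artifact-subtracted control, or the
#'   isolated postsynaptic component).
#' @param protocol The [stimulus_protocol()].
#' @param config A [ripplet_config()].
#' @param blocked_avg Optional averaged blocked-condition [trace()] for
#'   volley measurement.
#' @return An object of class `ripplet_features` with fields
#'   `presyn_volley_times_ms`, `transient_times_ms`, `trough_times_ms`,
#'   `transient_amplitudes_mv`, `frequency_hz`, `n_transients` and `flag`
#'   (`"ok"` or `"below_amplitude_criterion"`).
#' @export
detect_ripplet_features <- function(avg, protocol, config = ripplet_config(),
                                    blocked_avg = NULL) {
  stopifnot(inherits(avg, "trace"))
  if (avg$kind != "lfp") stop("expected an lfp trace", call. = FALSE)
  rate <- avg$rate_hz
  on_ms <- protocol$onset_ms
  y <- .lowpass(avg$samples, rate, config$lowpass_hz)
  yb <- NULL
  if (!is.null(blocked_avg)) {
    .check_same_shape(avg, blocked_avg)
    yb <- .lowpass(blocked_avg$samples, blocked_avg$rate_hz,
                   config$lowpass_hz)
    # transients and troughs are measured on the isolated postsynaptic
    # component, free of presynaptic-volley contamination
    y <- y - yb
  }
  t_ms <- trace_times_ms(avg) - on_ms
  sep <- max(1L, round(config$min_period_ms * rate / 1000))

  win <- t_ms >= config$transient_window_ms[1] &
    t_ms <= config$transient_window_ms[2]
  idx_all <- .local_maxima(-y, threshold = config$amp_threshold_mv,
                           min_sep = sep)
  idx <- idx_all[win[idx_all]]

  empty <- function(flag) structure(
    list(presyn_volley_times_ms = numeric(0),
         transient_times_ms = numeric(0), trough_times_ms = numeric(0),
         transient_amplitudes_mv = numeric(0), frequency_hz = NA_real_,
         n_transients = 0L, flag = flag),
    class = "ripplet_features")

  if (!length(idx)) return(empty("below_amplitude_criterion"))
  amps <- -y[idx]
  if (max(amps) < config$inclusion_mv)
    return(empty("below_amplitude_criterion"))

  tr_times <- vapply(idx, function(i) .interp_time_ms(-y, i, rate), numeric(1)) - on_ms
  n <- length(idx)
  period <- if (n >= 2) mean(diff(tr_times)) else 2.4

  # troughs: positive maxima between transients, plus leading and trailing
  trough_at <- function(lo_ms, hi_ms) {
    sel <- which(t_ms >= lo_ms & t_ms <= hi_ms)
    if (length(sel) < 3L) return(NA_real_)
    i <- sel[which.max(y[sel])]
    .interp_time_ms(y, i, rate) - on_ms
  }
  troughs <- numeric(0)
  lead <- trough_at(tr_times[1] - period, tr_times[1] - 0.1)
  if (!is.na(lead)) troughs <- lead
  if (n >= 2)
    for (j in seq_len(n - 1))
      troughs <- c(troughs, trough_at(tr_times[j] + 0.1, tr_times[j + 1] - 0.1))
  trail <- trough_at(tr_times[n] + 0.1,
                     min(tr_times[n] + period, max(t_ms)))
  if (!is.na(trail)) troughs <- c(troughs, trail)
  troughs <- troughs[!is.na(troughs)]

  # presynaptic volleys
  if (!is.null(yb)) {
    tb <- trace_times_ms(blocked_avg) - on_ms
    vwin <- tb >= config$volley_window_ms[1] &
      tb <= config$transient_window_ms[2]
    vidx <- .local_maxima(-yb, threshold = config$amp_threshold_mv / 2,
                          min_sep = sep)
    vidx <- vidx[vwin[vidx]]
    volleys <- vapply(vidx, function(i)
      .interp_time_ms(-yb, i, blocked_avg$rate_hz), numeric(1)) - on_ms
  } else {
    vwin <- t_ms >= config$volley_window_ms[1] &
      t_ms <= config$volley_window_ms[2]
    vidx <- idx_all[vwin[idx_all] & !win[idx_all]]
    volleys <- vapply(vidx, function(i)
      .interp_time_ms(-y, i, rate), numeric(1)) - on_ms
  }

  structure(
    list(presyn_volley_times_ms = sort(volleys),
         transient_times_ms = tr_times, trough_times_ms = sort(troughs),
         transient_amplitudes_mv = amps,
         frequency_hz = if (n >= 2) oscillation_frequency(tr_times) else NA_real_,
         n_transients = n, flag = "ok"),
    class = "ripplet_features")
}

#' @export
print.ripplet_features <- function(x, ...) {
  cat(sprintf("<ripplet_features> %d transient(s), flag=%s\n",
              x$n_transients, x$flag))
  if (x$n_transients) {
    cat("  transients (ms):", paste(sprintf("%.2f", x$transient_times_ms),
                                    collapse = " "), "\n")
    cat("  troughs    (ms):", paste(sprintf("%.2f", x$trough_times_ms),
                                    collapse = " "), "\n")
    if (!is.na(x$frequency_hz))
      cat(sprintf("  frequency: %.1f Hz\n", x$frequency_hz))
  }
  invisible(x)
}

#' Oscillation frequency as the reciprocal of the mean inter-event interval
#'
#' `frequency = (n - 1) / (t_n - t_1)`, expressed in Hz for times in ms.
#'
#' @param times_ms Strictly increasing event times (>= 2), ms.
#' @return Frequency in Hz.
#' @export
oscillation_frequency <- function(times_ms) {
  if (length(times_ms) < 2L)
    stop("need at least two event times", call. = FALSE)
  if (is.unsorted(times_ms, strictly = TRUE))
    stop("event times must be strictly increasing", call. = FALSE)
  n <- length(times_ms)
  (n - 1) / (times_ms[n] - times_ms[1]) * 1000
}

#' Model per-order event-time histograms as Gaussian components
#'
#' Each event order's times are summarized as a normal with the sample mean,
#' sample SD (n-1 denominator) and an area equal to the histogram mass
#' (count x bin width), i.e. a Gaussian with the same mean, SD and integral
#' as the histogram peak.
#'
#' @param times_by_order Named list mapping order to times (ms).
#' @param bin_width_ms Histogram bin width (> 0).
#' @return A data.frame with columns `order`, `mean_ms`, `sd_ms`, `area`,
#'   `n` and `degenerate` (TRUE when all times coincide). Orders with fewer
#'   than two times are dropped with a warning.
#' @export
gaussian_components <- function(times_by_order, bin_width_ms = 0.5) {
  if (bin_width_ms <= 0) stop("bin width must be positive", call. = FALSE)
  keep <- vapply(times_by_order, length, integer(1)) >= 2L
  if (any(!keep))
    warning("dropping order(s) with fewer than two events: ",
            paste(names(times_by_order)[!keep], collapse = ", "))
  times_by_order <- times_by_order[keep]
  out <- data.frame(
    order = names(times_by_order),
    mean_ms = vapply(times_by_order, mean, numeric(1)),
    sd_ms = vapply(times_by_order, stats::sd, numeric(1)),
    area = vapply(times_by_order, length, integer(1)) * bin_width_ms,
    n = vapply(times_by_order, length, integer(1)),
    row.names = NULL)
  out$degenerate <- out$sd_ms == 0
  out
}
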