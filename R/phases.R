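# Phase assignment of spikes relative to the LFP ripplet cycle (troughs at
# 0 degrees, transients at +/-180) or the EPSC-IPSC cycle (EPSC onsets at
# 0, IPSC onsets at 180), with linear-scale summaries.

#' Construct phase anchors
#'
#' @param anchor_times_ms Strictly increasing anchor times.
#' @param anchor_phases_deg Unwrapped phases; consecutive anchors must
#'   differ by exactly 180 degrees. Phases that are 0 mod 360 mark the
#'   cycle-reference events (troughs or EPSC onsets).
#' @return An object of class `phase_anchors`.
#' @export
phase_anchors <- function(anchor_times_ms, anchor_phases_deg) {
  if (length(anchor_times_ms) < 2L)
    stop("need at least two anchors", call. = FALSE)
  if (is.unsorted(anchor_times_ms, strictly = TRUE))
    stop("anchor times must be strictly increasing", call. = FALSE)
  if (any(diff(anchor_phases_deg) != 180))
    stop("consecutive anchor phases must differ by 180 degrees",
         call. = FALSE)
  structure(list(anchor_times_ms = as.numeric(anchor_times_ms),
                 anchor_phases_deg = as.numeric(anchor_phases_deg)),
            class = "phase_anchors")
}

#' Phase anchors from LFP ripplet features
#'
#' Troughs are assigned phases 0 (mod 360) and transients +/-180 (mod 360),
#' merged into one strictly interleaved, unwrapped sequence. The leading
#' trough receives phase 0.
#'
#' @param f A `ripplet_features` object with interleaved troughs and
#'   transients.
#' @return A `phase_anchors` object.
#' @export
anchors_from_lfp <- function(f) {
  tt <- f$transient_times_ms; tr <- f$trough_times_ms
  if (length(tt) + length(tr) < 2L)
    stop("need at least two anchor events", call. = FALSE)
  times <- c(tr, tt)
  is_trough <- c(rep(TRUE, length(tr)), rep(FALSE, length(tt)))
  o <- order(times)
  times <- times[o]; is_trough <- is_trough[o]
  if (any(is_trough[-1] == is_trough[-length(is_trough)]))
    stop("troughs and transients must strictly interleave", call. = FALSE)
  # unwrap: first anchor gets 0 if a trough, -180 if a transient
  phase0 <- if (is_trough[1]) 0 else -180
  phases <- phase0 + 180 * (seq_along(times) - 1)
  phase_anchors(times, phases)
}

#' Phase anchors from an EPSC-IPSC alternation
#'
#' EPSC onsets map to 0 (mod 360), IPSC onsets to 180 (mod 360), unwrapped
#' over successive cycles.
#'
#' @param e An `ei_sequence` (see [detect_ei_onsets()]).
#' @return A `phase_anchors` object.
#' @export
anchors_from_ei <- function(e) {
  stopifnot(inherits(e, "ei_sequence"))
  times <- c(e$epsc_onsets_ms, e$ipsc_onsets_ms)
  is_e <- c(rep(TRUE, length(e$epsc_onsets_ms)),
            rep(FALSE, length(e$ipsc_onsets_ms)))
  if (length(times) < 2L)
    stop("need at least two onsets", call. = FALSE)
  o <- order(times)
  times <- times[o]; is_e <- is_e[o]
  if (any(is_e[-1] == is_e[-length(is_e)]))
    stop("EPSC and IPSC onsets must strictly alternate", call. = FALSE)
  phase0 <- if (is_e[1]) 0 else -180
  phase_anchors(times, phase0 + 180 * (seq_along(times) - 1))
}

#' Assign phase angles to spikes
#'
#' Each spike inside the anchor span gets a phase by linear interpolation
#' of the unwrapped anchor phases between its bracketing anchors, then is
#' re-expressed relative to the cycle-reference anchor (phase 0 mod 360)
#' nearest in time, so values slightly beyond +/-180 can occur when the
#' local half-cycles are asymmetric. Spikes outside the anchor span are
#' excluded; their count is returned as an attribute.
#'
#' @param spike_times_ms Spike peak times, same clock as the anchors.
#' @param a A `phase_anchors` object.
#' @return Numeric vector of phases in degrees, with attribute
#'   `n_excluded`.
#' @export
assign_phase <- function(spike_times_ms, a) {
  stopifnot(inherits(a, "phase_anchors"))
  at <- a$anchor_times_ms; ap <- a$anchor_phases_deg
  inside <- spike_times_ms >= at[1] & spike_times_ms <= at[length(at)]
  kept <- spike_times_ms[inside]
  troughs_i <- which(ap %% 360 == 0)
  if (!length(troughs_i))
    stop("anchors contain no cycle-reference (phase 0 mod 360) event",
         call. = FALSE)
  phi <- stats::approx(at, ap, xout = kept, ties = "ordered")$y
  ref <- vapply(kept, function(s)
    ap[troughs_i[which.min(abs(at[troughs_i] - s))]], numeric(1))
  out <- phi - ref
  attr(out, "n_excluded") <- sum(!inside)
  out
}

#' Convert a phase angle to a time interval
#'
#' `(angle / 360) * period`.
#'
#' @param angle_deg Phase angle, degrees.
#' @param period_ms Oscillation period, ms (> 0).
#' @return Time in ms.
#' @export
phase_to_time <- function(angle_deg, period_ms) {
  if (any(period_ms <= 0)) stop("period must be positive", call. = FALSE)
  angle_deg / 360 * period_ms
}

#' Linear-scale phase summary
#'
#' Median and 10th/90th percentiles on the unwrapped linear scale (type-7
#' linear-interpolation percentiles), matching how spike-phase
#' distributions extending slightly past +/-180 are summarized.
#'
#' @param angles_deg Phase angles, degrees (n >= 1).
#' @return List of class `phase_summary`: `median_deg`, `p10_deg`,
#'   `p90_deg`, `n`.
#' @export
phase_summary <- function(angles_deg) {
  if (!length(angles_deg)) stop("no angles supplied", call. = FALSE)
  q <- stats::quantile(angles_deg, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  structure(list(median_deg = q[2], p10_deg = q[1], p90_deg = q[3],
                 n = length(angles_deg)),
            class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf("<phase_summary> median %.0f deg (10-90%%: %.0f to %.0f), n=%d\n",
              x$median_deg, x$p10_deg, x$p90_deg, x$n))
  invisible(x)
}
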