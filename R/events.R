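# EPSC/IPSC onset detection in voltage-clamp sweeps, net charge transfer,
# and the trough-vs-EPSC-onset regression.

#' Construct an EPSC-IPSC sequence
#'
#' @param epsc_onsets_ms,ipsc_onsets_ms Onset times, ms.
#' @param epsc_amplitudes_pa,ipsc_amplitudes_pa Peak amplitudes (signed).
#' @return An object of class `ei_sequence`. The merged onset order must
#'   strictly alternate after the first event.
#' @export
ei_sequence <- function(epsc_onsets_ms, ipsc_onsets_ms,
                        epsc_amplitudes_pa = rep(NA_real_, length(epsc_onsets_ms)),
                        ipsc_amplitudes_pa = rep(NA_real_, length(ipsc_onsets_ms))) {
  times <- c(epsc_onsets_ms, ipsc_onsets_ms)
  is_e <- c(rep(TRUE, length(epsc_onsets_ms)),
            rep(FALSE, length(ipsc_onsets_ms)))
  o <- order(times)
  if (length(times) >= 2 &&
      any(is_e[o][-1] == is_e[o][-length(o)]))
    stop("merged onsets must strictly alternate E, I, E, I, ...",
         call. = FALSE)
  structure(list(epsc_onsets_ms = sort(epsc_onsets_ms),
                 ipsc_onsets_ms = sort(ipsc_onsets_ms),
                 epsc_amplitudes_pa = epsc_amplitudes_pa[order(epsc_onsets_ms)],
                 ipsc_amplitudes_pa = ipsc_amplitudes_pa[order(ipsc_onsets_ms)]),
            class = "ei_sequence")
}

#' Detect alternating EPSC/IPSC onsets in a voltage-clamp trace
#'
#' At an intermediate holding potential (-55 to -50 mV) EPSCs are negative
#' and IPSCs positive deflections. The baseline (mean over the 10 ms before
#' light onset) is subtracted; candidate events are local extrema exceeding
#' `k_mad` times the baseline MAD; the onset of each event is found by
#' backtracking from its extremum along the rising edge until the slope
#' falls below `slope_frac` of the event's peak slope or stops decreasing
#' (the foot of the event, which guards against running into the previous
#' event's recovery phase). Alternation is enforced after the first
#' detected event by dropping the smaller of two consecutive same-sign
#' events, with a warning.
#'
#' @param t A voltage-clamp [trace()].
#' @param protocol The [stimulus_protocol()].
#' @param k_mad Amplitude threshold in baseline-MAD units.
#' @param slope_frac Slope threshold as a fraction of the event peak slope.
#' @param min_amp_pa Absolute floor on event relief (instrument-scale
#'   minimum for a credible synaptic event).
#' @param window_ms Search window, ms from light onset.
#' @return An `ei_sequence` (possibly empty).
#' @export
detect_ei_onsets <- function(t, protocol, k_mad = 5, slope_frac = 0.1,
                             min_amp_pa = 10, window_ms = c(1, 25)) {
  stopifnot(inherits(t, "trace"))
  if (t$kind != "voltage_clamp")
    stop("event detection expects a voltage_clamp trace", call. = FALSE)
  if (t$holding_mv < -55 || t$holding_mv > -50)
    stop("holding potential must lie between -55 and -50 mV", call. = FALSE)
  rate <- t$rate_hz
  t_ms <- trace_times_ms(t)
  on_ms <- protocol$onset_ms
  base_idx <- t_ms >= on_ms - 10 & t_ms < on_ms
  y <- t$samples - mean(t$samples[base_idx])
  y <- .lowpass(y, rate, 2000)
  thr <- max(k_mad * stats::mad(y[base_idx]), min_amp_pa)
  win <- t_ms >= on_ms + window_ms[1] & t_ms <= on_ms + window_ms[2]

  # Candidate events by persistence pruning: alternating local extrema
  # whose relief relative to their surviving neighbors reaches the
  # threshold. Relief (not absolute level) is what identifies a deflection
  # riding the decay of the previous, opposite-sign event.
  ext <- .prune_extrema(y, thr)
  ext <- ext[win[ext$i], , drop = FALSE]
  # sign consistency: an IPSC peak recovers to near or above baseline, an
  # EPSC trough to near or below it; extrema stranded deep on the wrong
  # side are recovery phases of the opposite component, not events
  ext <- ext[(ext$is_max & y[ext$i] > -2 * thr) |
               (!ext$is_max & y[ext$i] < 2 * thr), , drop = FALSE]
  if (!nrow(ext)) return(ei_sequence(numeric(0), numeric(0)))

  slope <- c(0, diff(y)) * rate / 1000 # pA per ms
  onset_of <- function(i_pk, sign, lo_i = 2L) {
    s <- sign * slope # slope in the event's rising direction is positive
    # rising-edge peak slope between the previous event's extremum and
    # this extremum (at most 2 ms back)
    lo <- max(2L, lo_i, i_pk - round(2 * rate / 1000))
    seg <- lo:i_pk
    pk_slope <- max(s[seg])
    i_m <- seg[which.max(s[seg])]
    thr_s <- slope_frac * pk_slope
    i <- i_m
    while (i > lo) {
      if (s[i - 1L] < thr_s) break      # slope threshold reached
      if (s[i - 1L] > s[i] && s[i] < 0.5 * pk_slope) break # foot guard
      i <- i - 1L
    }
    # refine: extrapolate the maximal-slope tangent back to the local
    # background line through the foot (robust when the event rides the
    # previous event's recovery phase)
    foot_ms <- (i - 1L) / rate * 1000
    s_bg <- s[i]
    rise <- sign * (y[i_m] - y[i]) - s_bg * (i_m - i) / rate * 1000
    net_slope <- s[i_m] - s_bg
    if (net_slope > 0 && rise > 0) {
      tangent_ms <- (i_m - 1L) / rate * 1000 - rise / net_slope
      foot_ms <- min(max(tangent_ms, foot_ms), (i_pk - 1L) / rate * 1000)
    }
    foot_ms
  }

  ev <- data.frame(i = ext$i, sign = ifelse(ext$is_max, 1, -1),
                   amp = y[ext$i])
  # relative relief floor: reject wiggles far below the dominant events
  ev <- ev[ext$relief >= 0.12 * max(ext$relief), , drop = FALSE]
  # enforce alternation (after the first event): drop the smaller of two
  # consecutive same-sign events
  repeat {
    same <- which(diff(ev$sign) == 0)
    if (!length(same)) break
    j <- same[1]
    drop_j <- if (abs(ev$amp[j]) < abs(ev$amp[j + 1])) j else j + 1L
    warning(sprintf("dropping same-sign event at %.2f ms to enforce E-I alternation",
                    t_ms[ev$i[drop_j]] - on_ms))
    ev <- ev[-drop_j, , drop = FALSE]
  }
  onsets <- vapply(seq_len(nrow(ev)), function(r)
    onset_of(ev$i[r], ev$sign[r],
             if (r > 1) ev$i[r - 1L] else 2L), numeric(1)) - on_ms
  # onsets must follow the extremum order; clamp rare backtracking overlaps
  if (length(onsets) > 1)
    for (r in 2:length(onsets))
      if (onsets[r] <= onsets[r - 1]) onsets[r] <- onsets[r - 1] + 0.025
  e_sel <- ev$sign < 0
  ei_sequence(onsets[e_sel], onsets[!e_sel],
              epsc_amplitudes_pa = ev$amp[e_sel],
              ipsc_amplitudes_pa = ev$amp[!e_sel])
}

#' Net synaptic charge transfer
#'
#' Trapezoidal integral of the baseline-subtracted current over a window.
#' Negative values indicate net excitation (inward current), positive net
#' inhibition.
#'
#' @param t A voltage-clamp [trace()].
#' @param window_ms `c(start, end)` in ms from sweep start.
#' @param baseline_ms Baseline window; default the 10 ms before the
#'   analysis window.
#' @return Charge in pA*ms.
#' @export
net_charge <- function(t, window_ms, baseline_ms = NULL) {
  stopifnot(inherits(t, "trace"))
  t_ms <- trace_times_ms(t)
  if (window_ms[1] >= window_ms[2] || window_ms[1] < 0 ||
      window_ms[2] > max(t_ms))
    stop("integration window must be nonempty and inside the sweep",
         call. = FALSE)
  if (is.null(baseline_ms)) baseline_ms <- c(window_ms[1] - 10, window_ms[1])
  base <- mean(t$samples[t_ms >= baseline_ms[1] & t_ms < baseline_ms[2]])
  sel <- which(t_ms >= window_ms[1] & t_ms <= window_ms[2])
  y <- t$samples[sel] - base
  dt <- 1000 / t$rate_hz
  sum((y[-1] + y[-length(y)]) / 2) * dt
}

#' Regression of EPSC onsets on ripplet trough times
#'
#' Ordinary least squares of paired EPSC onset times against LFP trough
#' times, with the coefficient of determination.
#'
#' @param trough_times_ms,epsc_onsets_ms Equal-length paired times (n >= 2).
#' @return List with `slope`, `intercept_ms`, `r_squared`, `n`.
#' @export
trough_epsc_regression <- function(trough_times_ms, epsc_onsets_ms) {
  if (length(trough_times_ms) != length(epsc_onsets_ms))
    stop("paired lists must have equal length", call. = FALSE)
  if (length(trough_times_ms) < 2L)
    stop("need at least two pairs", call. = FALSE)
  if (stats::var(trough_times_ms) == 0)
    stop("trough times have zero variance", call. = FALSE)
  fit <- stats::lm(epsc_onsets_ms ~ trough_times_ms)
  list(slope = unname(stats::coef(fit)[2]),
       intercept_ms = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = length(trough_times_ms))
}

# Alternating local extrema of y surviving persistence pruning: adjacent
# extrema pairs whose value difference is below `thr` are cancelled
# iteratively, leaving only deflections with relief >= thr on both sides.
.prune_extrema <- function(y, thr) {
  n <- length(y)
  d <- diff(y)
  sgn <- sign(d)
  sgn[sgn == 0] <- 1
  turns <- which(diff(sgn) != 0) + 1L
  if (!length(turns))
    return(data.frame(i = integer(0), is_max = logical(0),
                      relief = numeric(0)))
  is_max <- y[turns] >= y[pmin(turns + 1L, n)] & y[turns] >= y[pmax(turns - 1L, 1L)]
  v <- y[turns]
  keep <- rep(TRUE, length(turns))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2L) break
    gaps <- abs(diff(v[idx]))
    j <- which.min(gaps)
    if (gaps[j] >= thr) break
    keep[idx[c(j, j + 1L)]] <- FALSE
  }
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(i = integer(0), is_max = logical(0),
                      relief = numeric(0)))
  vv <- v[idx]
  # edge extrema are referenced to the zeroed baseline, so stray filter
  # ripples before the first or after the last event carry no relief
  relief <- vapply(seq_along(idx), function(k) {
    left <- if (k > 1) abs(vv[k] - vv[k - 1]) else abs(vv[k])
    right <- if (k < length(idx)) abs(vv[k] - vv[k + 1]) else abs(vv[k])
    min(left, right)
  }, numeric(1))
  data.frame(i = turns[idx], is_max = is_max[idx], relief = relief)
}
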