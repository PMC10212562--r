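# Shared numerical helpers: sub-sample peak localization, zero-phase
# filtering, kernel evaluation.

# Three-point parabolic interpolation around a sample extremum. `i` is the
# index of the extremum, `y` the sampled signal; returns the fractional
# index offset in (-0.5, 0.5) and the interpolated extremum value. Needed
# because the timing precision of interest (tens of microseconds) is below
# the 50 microsecond sampling period.
.parabolic_peak <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(list(offset = 0, value = y[i]))
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (abs(denom) < .Machine$double.eps) return(list(offset = 0, value = y1))
  d <- 0.5 * (y0 - y2) / denom
  d <- max(-0.5, min(0.5, d))
  list(offset = d, value = y1 - 0.25 * (y0 - y2) * d)
}

# Indices of strict local maxima of y, at least `min_sep` samples apart,
# with y > threshold. When two candidates are closer than min_sep the
# larger one is kept.
.local_maxima <- function(y, threshold = -Inf, min_sep = 1L) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(y[2:(n - 1L)] >= y[1:(n - 2L)] &
                y[2:(n - 1L)] > y[3:n]) + 1L
  cand <- cand[y[cand] > threshold]
  if (length(cand) <= 1L || min_sep <= 1L) return(cand)
  cand <- cand[order(y[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand)
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  sort(keep)
}

# Zero-phase Butterworth low-pass (forward-backward), mirroring the
# acquisition chain's 1.3 kHz hardware filter when applied at that cutoff.
.lowpass <- function(samples, rate_hz, cutoff_hz, order = 4) {
  if (cutoff_hz >= rate_hz / 2) return(samples)
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  as.numeric(signal::filtfilt(bf, samples))
}

# Negative (or positive) Gaussian bump evaluated at times t (ms), centered
# at t0 with SD sigma_ms and signed amplitude amp.
.gauss_bump <- function(t, t0, sigma_ms, amp) {
  amp * exp(-0.5 * ((t - t0) / sigma_ms)^2)
}

# Difference-of-exponentials postsynaptic-current kernel, onset at t0,
# peak-normalized then scaled to `amp` (signed). Zero before onset.
.psc_kernel <- function(t, t0, tau_rise, tau_decay, amp) {
  dt <- t - t0
  y <- ifelse(dt > 0, exp(-dt / tau_decay) - exp(-dt / tau_rise), 0)
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  peak <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  amp * y / peak
}

# Sub-sample time (ms) of the extremum at sample index i.
.interp_time_ms <- function(y, i, rate_hz) {
  pk <- .parabolic_peak(y, i)
  (i - 1L + pk$offset) * 1000 / rate_hz
}
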