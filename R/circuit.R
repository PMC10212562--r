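# Event-driven simulator of the proposed ripplet-generating circuit: a
# synchronous thalamocortical volley launches a feedforward cascade of RS
# spike packets, each packet eliciting an FS spike volley; FS volleys feed
# inhibition back onto RS cells, preempting late crossers and thereby
# enforcing packet synchrony; per-cycle synaptic depression shrinks the
# packets until the cascade dies out. Volley-level (not conductance-level)
# dynamics: the model is a timed cascade, and membrane equations would add
# unconstrained parameters.

#' Circuit-model parameters
#'
#' @param n_rs,n_fs Population sizes.
#' @param tc_time_ms Time of the thalamocortical volley.
#' @param fs_first_latency_ms Monosynaptic TC-to-FS latency (first FS
#'   volley).
#' @param rs_first_offset_ms TC-to-first-RS-packet latency (FS cells fire
#'   ~0.9 ms before RS cells).
#' @param syn_delay_rs_ms,tts_rs_ms RS-to-RS synaptic delay and
#'   post-synaptic time-to-spike; their sum is the 2.4 ms cycle period.
#' @param rs_to_fs_total_ms RS-packet-to-FS-volley delay (1.1 ms synaptic +
#'   0.4 ms FS time-to-spike).
#' @param fs_to_ipsp_delay_ms FS-volley-to-IPSP-onset monosynaptic delay.
#' @param ipsp_rise_ms IPSP onset-to-effect rise: a cell is preempted only
#'   if it has not crossed threshold by IPSP onset + this rise time.
#' @param sigma_rs_ms SD of each RS cell's threshold-crossing time about
#'   the packet center; 0 gives the deterministic schedule.
#' @param p0 Initial participation probability of an eligible RS cell.
#' @param depression Per-cycle multiplicative depression of participation
#'   (0 < depression <= 1).
#' @param n_min Minimum packet size for the cascade to continue.
#' @param refractory_cycles RS refractory period, in cycles.
#' @param inhibition_on If FALSE (local disinhibition), no preemption and
#'   no fast per-cycle depression; instead a slow adaptation factor
#'   `exp(-elapsed / adaptation_tau_ms)` winds the discharge down.
#' @param adaptation_tau_ms Adaptation time constant of the disinhibited
#'   mode.
#' @param fs_jitter_ms Per-FS-cell spike jitter around each volley.
#' @param deterministic If TRUE, run with every noise term off: crossing
#'   times at the packet centers, FS jitter 0, and packet sizes equal to
#'   the rounded expected participation instead of Bernoulli draws.
#' @param seed Integer seed.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(n_rs = 200, n_fs = 20, tc_time_ms = 0,
                           fs_first_latency_ms = 0.8,
                           rs_first_offset_ms = 1.7,
                           syn_delay_rs_ms = 0.9, tts_rs_ms = 1.5,
                           rs_to_fs_total_ms = 1.5,
                           fs_to_ipsp_delay_ms = 0.8, ipsp_rise_ms = 0.2,
                           sigma_rs_ms = 0.3, p0 = 0.9, depression = 0.6,
                           n_min = 10, refractory_cycles = 1,
                           inhibition_on = TRUE, adaptation_tau_ms = 150,
                           fs_jitter_ms = 0.05, deterministic = FALSE,
                           seed = 1) {
  p <- as.list(environment())
  if (p$deterministic) {
    p$sigma_rs_ms <- 0
    p$fs_jitter_ms <- 0
  }
  if (p$n_rs < 1 || p$n_fs < 1) stop("population sizes must be >= 1", call. = FALSE)
  if (p$depression <= 0 || p$depression > 1)
    stop("depression must lie in (0, 1]", call. = FALSE)
  if (any(c(p$fs_first_latency_ms, p$syn_delay_rs_ms, p$tts_rs_ms,
            p$rs_to_fs_total_ms, p$fs_to_ipsp_delay_ms) <= 0))
    stop("all delays must be positive", call. = FALSE)
  if (p$sigma_rs_ms < 0 || p$fs_jitter_ms < 0)
    stop("jitter SDs must be nonnegative", call. = FALSE)
  if (p$p0 <= 0 || p$p0 > 1) stop("p0 must lie in (0, 1]", call. = FALSE)
  p$cycle_period_ms <- p$syn_delay_rs_ms + p$tts_rs_ms
  structure(p, class = "circuit_params")
}

#' Run the event-driven ripplet circuit simulation
#'
#' The first FS volley fires at `tc_time + fs_first_latency`. RS packet k
#' (k >= 1) is centered at `tc_time + rs_first_offset + (k-1) * period`;
#' each eligible (non-refractory) RS cell draws a threshold-crossing time
#' `N(center, sigma_rs)` and participates with probability
#' `p0 * depression^(k-1)`. With inhibition on, cells whose crossing time
#' exceeds the IPSP-arrival cutoff (previous FS volley +
#' `fs_to_ipsp_delay` + `ipsp_rise`) are preempted. A packet occurs iff at
#' least `n_min` cells fire; the cascade stops at the first undersized
#' packet, and every packet that occurs elicits an FS volley
#' `rs_to_fs_total` later (all FS cells, small jitter). With inhibition off
#' there is no preemption and no fast depression; participation decays as
#' `p0 * exp(-(center - tc_time) / adaptation_tau)` until the packet falls
#' below `n_min`, emulating the bounded paroxysmal discharge under local
#' disinhibition.
#'
#' @param p A [circuit_params()].
#' @return An object of class `sim_result`: `rs_raster` / `fs_raster`
#'   (per-cell spike-time lists), `rs_volley_times_ms`,
#'   `fs_volley_times_ms`, `packet_sizes`, `duration_ms` (last spike minus
#'   TC time, 0 if no spikes).
#' @export
simulate_ripplet <- function(p = circuit_params()) {
  stopifnot(inherits(p, "circuit_params"))
  .with_seed(p$seed, {
    rs_raster <- vector("list", p$n_rs)
    fs_raster <- vector("list", p$n_fs)
    fs_volleys <- numeric(0)
    rs_volleys <- numeric(0)
    packet_sizes <- integer(0)
    last_fired_cycle <- rep(-Inf, p$n_rs)

    emit_fs <- function(t) {
      jit <- if (p$fs_jitter_ms > 0)
        stats::rnorm(p$n_fs, 0, p$fs_jitter_ms) else numeric(p$n_fs)
      for (c in seq_len(p$n_fs))
        fs_raster[[c]] <<- c(fs_raster[[c]], t + jit[c])
      fs_volleys <<- c(fs_volleys, t)
    }

    emit_fs(p$tc_time_ms + p$fs_first_latency_ms)

    k <- 1L
    max_cycles <- 5000L
    while (k <= max_cycles) {
      center <- p$tc_time_ms + p$rs_first_offset_ms +
        (k - 1) * p$cycle_period_ms
      p_part <- if (p$inhibition_on)
        p$p0 * p$depression^(k - 1)
      else
        p$p0 * exp(-(center - p$tc_time_ms) / p$adaptation_tau_ms)
      eligible <- which(k - last_fired_cycle > p$refractory_cycles)
      if (!length(eligible)) { packet_sizes <- c(packet_sizes, 0L); break }
      part <- if (p$deterministic)
        eligible[seq_len(min(length(eligible), round(length(eligible) * p_part)))]
      else
        eligible[stats::runif(length(eligible)) < p_part]
      crossing <- center + if (p$sigma_rs_ms > 0)
        stats::rnorm(length(part), 0, p$sigma_rs_ms) else numeric(length(part))
      if (p$inhibition_on) {
        cutoff <- fs_volleys[length(fs_volleys)] + p$fs_to_ipsp_delay_ms +
          p$ipsp_rise_ms
        keep <- crossing <= cutoff
        part <- part[keep]; crossing <- crossing[keep]
      }
      packet_sizes <- c(packet_sizes, length(part))
      if (length(part) < p$n_min) break
      for (j in seq_along(part))
        rs_raster[[part[j]]] <- c(rs_raster[[part[j]]], crossing[j])
      last_fired_cycle[part] <- k
      rs_volleys <- c(rs_volleys, center)
      emit_fs(center + p$rs_to_fs_total_ms)
      k <- k + 1L
    }

    all_spikes <- c(unlist(rs_raster), unlist(fs_raster))
    structure(list(rs_raster = rs_raster, fs_raster = fs_raster,
                   rs_volley_times_ms = rs_volleys,
                   fs_volley_times_ms = fs_volleys,
                   packet_sizes = packet_sizes,
                   duration_ms = if (length(all_spikes))
                     max(all_spikes) - p$tc_time_ms else 0,
                   params = p),
              class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d RS volley(s), %d FS volley(s), duration %.1f ms\n",
              length(x$rs_volley_times_ms), length(x$fs_volley_times_ms),
              x$duration_ms))
  invisible(x)
}

#' Summarize a circuit simulation
#'
#' FS-volley frequency (reciprocal of the mean inter-volley interval), the
#' histogram of spikes per firing RS cell, volley counts and duration.
#'
#' @param r A `sim_result`.
#' @return A list with `fs_frequency_hz` (NA if fewer than two FS
#'   volleys), `rs_spike_histogram` (table over spikes per firing RS
#'   cell), `prop_rs_1_2` (fraction of firing RS cells with 1-2 spikes),
#'   `n_rs_volleys`, `n_fs_volleys`, `duration_ms`.
#' @export
summarize_sim <- function(r) {
  stopifnot(inherits(r, "sim_result"))
  fsv <- r$fs_volley_times_ms
  counts <- lengths(r$rs_raster)
  firing <- counts[counts > 0]
  list(fs_frequency_hz = if (length(fsv) >= 2)
         1000 / mean(diff(fsv)) else NA_real_,
       rs_spike_histogram = table(firing),
       prop_rs_1_2 = if (length(firing)) mean(firing <= 2) else NA_real_,
       n_rs_volleys = length(r$rs_volley_times_ms),
       n_fs_volleys = length(fsv),
       duration_ms = r$duration_ms)
}

#' Render a proxy LFP from a simulation result
#'
#' Negative Gaussian transients are placed one EPSC-to-peak delay after
#' each RS volley (population EPSCs in RS cells are the major contributor
#' to the LFP current sinks), scaled by packet size, plus a small negative
#' presynaptic bump at the thalamocortical volley time. The trace is
#' suitable input for [detect_ripplet_features()].
#'
#' @param r A `sim_result`.
#' @param onset_ms Light-onset position within the sweep.
#' @param tc_delay_ms Latency from light onset to the thalamocortical
#'   volley peak (opsin and axonal conduction delays; 2.3 ms places the
#'   simulated transients at the experimentally observed latencies).
#' @param sweep_ms,rate_hz Sweep geometry.
#' @param transient_delay_ms Delay from an RS packet center to the LFP
#'   negative peak it generates (default 0.25 ms, placing transients
#'   ~1.15 ms after the preceding FS volley, in antiphase with FS spikes).
#' @param sigma_ms Transient kernel SD.
#' @param amp_mv Amplitude of a full-size packet's transient; amplitudes
#'   scale with the square root of relative packet size.
#' @return A [trace()] of kind `lfp`.
#' @export
sim_lfp <- function(r, onset_ms = 10, tc_delay_ms = 2.3, sweep_ms = 50,
                    rate_hz = 20000, transient_delay_ms = 0.25,
                    sigma_ms = 0.35, amp_mv = 1.0) {
  stopifnot(inherits(r, "sim_result"))
  t_ms <- (seq_len(round(sweep_ms * rate_hz / 1000)) - 1) * 1000 / rate_hz
  shift <- onset_ms + tc_delay_ms - r$params$tc_time_ms
  y <- .gauss_bump(t_ms, r$params$tc_time_ms + shift, 0.25, -0.3)
  rsv <- r$rs_volley_times_ms
  sizes <- r$packet_sizes[seq_along(rsv)]
  ref <- max(r$params$n_rs * r$params$p0 * 0.5, 1)
  for (j in seq_along(rsv))
    y <- y + .gauss_bump(t_ms, rsv[j] + shift + transient_delay_ms, sigma_ms,
                         -amp_mv * min(1.5, sqrt(sizes[j] / ref)))
  trace(y, rate_hz = rate_hz, kind = "lfp")
}
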