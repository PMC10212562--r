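# One-shot reproduction runner: recomputes the package's headline
# quantities (worked-example phase conversions, cohort frequency
# recoveries, pairwise synchrony precision, and circuit-simulator timing)
# from scratch. The package functions and this runner are the programmatic
# interface; scripts/acceptance.R is a thin wrapper around it.

#' Recompute the package's headline quantities
#'
#' Runs, from scratch and under one seed: the deterministic phase-to-time
#' conversions relating FS/RS spike phases to latencies; cohort recoveries
#' of the FS burst frequency, ripplet transient frequency and presynaptic
#' volley frequency from per-unit draws of the population timing
#' parameters; the median pairwise JBSI precision of synthetic FS-FS pairs
#' driven by shared volleys; and the circuit simulator's noise-free RS
#' inter-volley interval and its maximum stochastic discharge duration.
#'
#' @param seed Integer master seed for every stochastic component.
#' @param pop A [population_params()] object.
#' @param n_cohort Cohort size for the frequency recoveries.
#' @param n_pairs Number of synthetic FS-FS pairs.
#' @param n_trials_per_pair Trials per pair.
#' @param n_sim_seeds Number of stochastic simulator runs for the duration
#'   bound.
#' @return A data.frame with columns `name`, `value`, `n`.
#' @export
run_reproduction <- function(seed = 1, pop = population_params(),
                             n_cohort = 100, n_pairs = 6,
                             n_trials_per_pair = 30, n_sim_seeds = 100) {
  rows <- list()
  add <- function(name, value, n) rows[[length(rows) + 1L]] <<-
    data.frame(name = name, value = value, n = n)

  # worked-example phase/time conversions (deterministic)
  add("phase_time_100deg_180hz_ms",
      round(phase_to_time(100, 1000 / 180), 1), 1)
  fs_med <- pop$fs_phase_deg[["median"]]
  rs_med <- pop$rs_phase_deg[["median"]]
  add("rs_fs_phase_delay_ms",
      round(phase_to_time(rs_med - fs_med, 1000 / 408), 1), 1)
  ei_med <- pop$ei_fs_phase_deg[["median"]]
  add("epsc_to_fs_latency_ms", round(phase_to_time(ei_med, 2.4), 1), 1)
  add("fs_to_ipsc_interval_ms",
      round(phase_to_time(180 - ei_med, 2.4), 1), 1)

  # cohort frequency recoveries: per-unit means drawn from the population,
  # per-unit 1/mean-ISI frequency, averaged across units
  fs_freqs <- .with_seed(seed + 101, vapply(seq_len(n_cohort), function(i) {
    isis <- .draw_positive(pop$fs_isi_means,
                                 pop$fs_isi_sems * sqrt(pop$fs_n))
    1000 / mean(isis)
  }, numeric(1)))
  add("fs_burst_frequency_hz", mean(fs_freqs), n_cohort)

  slices <- draw_slices(pop, n_cohort, seed = seed + 102)
  add("ripplet_frequency_hz",
      mean(vapply(slices, function(s)
        oscillation_frequency(s$transient_times_ms), numeric(1))),
      n_cohort)
  add("volley_frequency_hz",
      mean(vapply(slices, function(s)
        oscillation_frequency(s$volley_times_ms), numeric(1))),
      n_cohort)

  # pairwise synchrony precision on synthetic FS-FS pairs
  precisions <- vapply(seq_len(n_pairs), function(i) {
    tr <- synth_pair_trains(pop$fs_spike_means, sigma_indep_ms = 0.15,
                            sigma_common_ms = 0.05,
                            n_trials = n_trials_per_pair,
                            seed = seed + 200 + i)
    jbsi_matrix(tr$a, tr$b)$precision_ms
  }, numeric(1))
  add("median_pairwise_precision_ms", stats::median(precisions), n_pairs)

  # circuit simulator: deterministic schedule and stochastic duration bound
  det <- simulate_ripplet(circuit_params(deterministic = TRUE, seed = seed))
  add("rs_intervolley_ms", mean(diff(det$rs_volley_times_ms)),
      length(det$rs_volley_times_ms))
  durations <- vapply(seq_len(n_sim_seeds), function(i)
    simulate_ripplet(circuit_params(seed = seed + 300 + i))$duration_ms,
    numeric(1))
  add("max_sim_duration_ms", max(durations), n_sim_seeds)

  do.call(rbind, rows)
}

# Strictly positive draws (ISIs must be positive; re-draw otherwise).
.draw_positive <- function(means, sds, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(length(means), means, sds)
    if (all(x > 0)) return(x)
  }
  pmax(stats::rnorm(length(means), means, sds), 0.1)
}
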