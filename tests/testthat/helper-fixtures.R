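# Shared fixtures built in code. `mean_slice()` is the population-mean
# slice (no inter-slice scatter); quiet_* wrappers silence expected
# alternation/merge warnings in closure loops.

mean_slice <- function() {
  p <- population_params()
  list(slice_id = 0L,
       volley_times_ms = p$presyn_volley_means,
       transient_times_ms = p$ripplet_peak_means)
}

quiet <- function(expr) suppressWarnings(expr)

# Full LFP condition triple for one slice, averaged.
lfp_triple <- function(slice, seed = 1, n_sweeps = 10,
                       protocol = stimulus_protocol()) {
  list(
    control = average_sweeps(synth_lfp_sweeps(slice, protocol, "control",
                                              n_sweeps, seed)),
    blocked = average_sweeps(synth_lfp_sweeps(slice, protocol, "cnqx_apv",
                                              n_sweeps, seed + 1000)),
    ttx = average_sweeps(synth_lfp_sweeps(slice, protocol, "ttx",
                                          n_sweeps, seed + 2000)),
    protocol = protocol)
}

features_of <- function(slice, seed = 1, ...) {
  tri <- lfp_triple(slice, seed, ...)
  detect_ripplet_features(subtract_artifact(tri$control, tri$ttx),
                          tri$protocol,
                          blocked_avg = subtract_artifact(tri$blocked,
                                                          tri$ttx))
}

# Homogeneous Poisson spike trains over [0, t_max_ms].
poisson_train <- function(rate_hz, t_max_ms, n_trials) {
  lapply(seq_len(n_trials), function(k) {
    n <- stats::rpois(1, rate_hz * t_max_ms / 1000)
    sort(stats::runif(n, 0, t_max_ms))
  })
}
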