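# Hierarchical synthetic-sweep generator. The hierarchy mirrors how the
# experimental cohort statistics are reported: population means with SEMs
# (over n slices or cells) -> per-slice/per-cell means (drawn with SD =
# SEM * sqrt(n)) -> per-trial jitter. All event placement is in continuous
# time; kernels are evaluated at the sample grid, so jitters far below the
# 50 us sampling period remain representable.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Population-level timing parameters of the ripplet cohort
#'
#' Means and standard errors of the event times that define the oscillation
#' at the population (cohort) level: presynaptic thalamocortical volley peak
#' times, postsynaptic ripplet transient peak times, FS spike-burst peak
#' times and ISIs, per-trial FS spike jitters, and the phase statistics of
#' FS and RS spikes. Per-unit (slice or cell) means are drawn from
#' `normal(mean, sem * sqrt(n))`, reconstituting the cohort scatter from the
#' printed standard errors.
#'
#' @param presyn_volley_means,presyn_volley_sems Volley peak times, ms from
#'   light onset, and their SEMs (`presyn_n` slices).
#' @param ripplet_peak_means,ripplet_peak_sems Ripplet transient peak times
#'   (ms) and SEMs (`ripplet_n` slices).
#' @param fs_spike_means,fs_spike_sems FS burst spike peak times (ms) and
#'   SEMs (`fs_n` cells).
#' @param fs_trial_jitters_us Within-cell trial-to-trial SD of each spike
#'   order's peak time, microseconds.
#' @param fs_isi_means,fs_isi_sems First three FS interspike intervals (ms).
#' @param presyn_n,ripplet_n,fs_n Cohort sizes behind each SEM.
#' @param fs_phase_deg,rs_phase_deg,ei_fs_phase_deg Named vectors
#'   (median/p10/p90) of spike phase relative to the LFP cycle (FS, RS) and
#'   of FS spikes in the EPSC-IPSC cycle.
#' @param noise_sd_lfp_mv,noise_sd_cc_mv,noise_sd_vc_pa White-noise SDs per
#'   modality.
#' @return An object of class `population_params`.
#' @export
population_params <- function(
    presyn_volley_means = c(2.3, 6.0, 10.8),
    presyn_volley_sems = c(0.07, 0.22, 0.24),
    presyn_n = 8,
    ripplet_peak_means = c(4.4, 6.5, 8.9, 11.9),
    ripplet_peak_sems = c(0.11, 0.26, 0.30, 0.38),
    ripplet_n = 11,
    fs_spike_means = c(3.1, 5.5, 7.7, 10.3),
    fs_spike_sems = c(0.06, 0.08, 0.12, 0.14),
    fs_n = 25,
    fs_trial_jitters_us = c(23, 63, 110, 183),
    fs_isi_means = c(2.4, 2.2, 2.7),
    fs_isi_sems = c(0.05, 0.08, 0.13),
    fs_phase_deg = c(median = 26, p10 = -14, p90 = 82),
    rs_phase_deg = c(median = 161, p10 = 145, p90 = 187),
    ei_fs_phase_deg = c(median = 59, p10 = 5, p90 = 106),
    noise_sd_lfp_mv = 0.02,
    noise_sd_cc_mv = 0.5,
    noise_sd_vc_pa = 5) {
  p <- list(presyn_volley_means = presyn_volley_means,
            presyn_volley_sems = presyn_volley_sems, presyn_n = presyn_n,
            ripplet_peak_means = ripplet_peak_means,
            ripplet_peak_sems = ripplet_peak_sems, ripplet_n = ripplet_n,
            fs_spike_means = fs_spike_means, fs_spike_sems = fs_spike_sems,
            fs_n = fs_n, fs_trial_jitters_us = fs_trial_jitters_us,
            fs_isi_means = fs_isi_means, fs_isi_sems = fs_isi_sems,
            fs_phase_deg = fs_phase_deg, rs_phase_deg = rs_phase_deg,
            ei_fs_phase_deg = ei_fs_phase_deg,
            noise_sd_lfp_mv = noise_sd_lfp_mv,
            noise_sd_cc_mv = noise_sd_cc_mv, noise_sd_vc_pa = noise_sd_vc_pa)
  stopifnot(length(p$presyn_volley_means) == length(p$presyn_volley_sems),
            length(p$ripplet_peak_means) == length(p$ripplet_peak_sems),
            length(p$fs_spike_means) == length(p$fs_spike_sems),
            length(p$fs_isi_means) == length(p$fs_isi_sems))
  for (nm in c("presyn_volley_means", "ripplet_peak_means", "fs_spike_means"))
    if (is.unsorted(p[[nm]], strictly = TRUE))
      stop(nm, " must be strictly increasing", call. = FALSE)
  structure(p, class = "population_params")
}

# Draw one unit's strictly increasing event times. The cohort scatter is
# decomposed into a shared onset shift, a shared tempo factor stretching
# the intervals, and a small independent per-order deviation: within a
# unit the rhythm stays regular (as in recordings), while the first- and
# last-order marginal SDs match the cohort values and intermediate orders
# come close. Non-monotone draws (rare) are rejected and re-drawn.
.draw_increasing <- function(means, sds, eps_sd = 0.08, max_tries = 100L) {
  n <- length(means)
  sd_on <- sds[1] * 0.95
  span <- means[n] - means[1]
  sd_tempo <- if (n >= 2 && span > 0)
    sqrt(max(sds[n]^2 - sd_on^2, 0)) / span else 0
  for (i in seq_len(max_tries)) {
    a <- stats::rnorm(1, 0, sd_on)
    b <- stats::rnorm(1, 0, sd_tempo)
    x <- means + a + b * (means - means[1]) + stats::rnorm(n, 0, eps_sd)
    if (!is.unsorted(x, strictly = TRUE)) return(x)
  }
  sort(x)
}

#' Draw per-slice event-time specifications from the population
#'
#' Each slice receives its own mean presynaptic volley times and ripplet
#' transient times, drawn independently per order from
#' `normal(population mean, SEM * sqrt(n))` and constrained to be strictly
#' increasing.
#'
#' @param p A [population_params()].
#' @param n_slices Number of slices to draw (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of slice specifications, each with `volley_times_ms`,
#'   `transient_times_ms` and `slice_id`.
#' @export
draw_slices <- function(p = population_params(), n_slices, seed = 1) {
  stopifnot(inherits(p, "population_params"))
  if (!is.numeric(n_slices) || n_slices < 1)
    stop("n_slices must be a positive count", call. = FALSE)
  v_sd <- p$presyn_volley_sems * sqrt(p$presyn_n)
  r_sd <- p$ripplet_peak_sems * sqrt(p$ripplet_n)
  .with_seed(seed, lapply(seq_len(n_slices), function(i) {
    list(slice_id = i,
         volley_times_ms = .draw_increasing(p$presyn_volley_means, v_sd),
         transient_times_ms = .draw_increasing(p$ripplet_peak_means, r_sd))
  }))
}

#' Realize a single recorded cell from the population
#'
#' Draws per-cell mean event times and per-order trial jitters for an FS or
#' RS archetype. FS cells carry the four-spike burst template; RS cells
#' carry EPSP-aligned event times (in-phase with ripplet transients) and a
#' sparse spiking template.
#'
#' @param p A [population_params()].
#' @param cell_class `"FS"` or `"RS"`.
#' @param seed Integer seed.
#' @return An object of class `realized_cell` with fields `cell_class`,
#'   `mean_times_ms`, `trial_jitter_ms`, `reliability`, `ei_balance`,
#'   `v_rest_mv` and `spike_peak_mv`.
#' @export
draw_cell <- function(p = population_params(), cell_class = c("FS", "RS"),
                      seed = 1) {
  cell_class <- match.arg(cell_class)
  .with_seed(seed, {
    if (cell_class == "FS") {
      mt <- .draw_increasing(p$fs_spike_means, p$fs_spike_sems * sqrt(p$fs_n))
      jit <- (p$fs_trial_jitters_us / 1000) * exp(stats::rnorm(4, 0, 0.25))
      rel <- c(1, 1, 1, 1)
      v_rest <- -70 + stats::rnorm(1, 0, 2)
      peak <- 25
      ei <- NA_real_
    } else {
      # RS events ride the ripplet transients; spikes sit slightly before
      # the transient peak (phase ~161 degrees of the 2.4 ms cycle).
      tr <- .draw_increasing(p$ripplet_peak_means,
                             p$ripplet_peak_sems * sqrt(p$ripplet_n))
      mt <- tr - 0.13
      jit <- c(0.10, 0.15, 0.25, 0.40)
      rel <- c(0.95, 0.6, 0.2, 0.05)
      v_rest <- -75 + stats::rnorm(1, 0, 2)
      peak <- 32
      ei <- stats::runif(1)
    }
    structure(list(cell_class = cell_class, mean_times_ms = mt,
                   trial_jitter_ms = jit, reliability = rel,
                   ei_balance = ei, v_rest_mv = v_rest,
                   spike_peak_mv = peak),
              class = "realized_cell")
  })
}

# Geometry shared by the LFP/VC generators: troughs (positive maxima) at
# the midpoints between transients, plus a leading and a trailing trough
# half a mean period outside; FS population volleys slightly (26 deg of a
# cycle) after each trough; IPSC onsets one monosynaptic delay (0.8 ms)
# after each FS volley.
.cycle_geometry <- function(transient_times_ms) {
  tt <- transient_times_ms
  period <- if (length(tt) >= 2) mean(diff(tt)) else 2.4
  troughs <- c(tt[1] - period / 2,
               if (length(tt) >= 2) (tt[-length(tt)] + tt[-1]) / 2,
               tt[length(tt)] + period / 2)
  fs_volleys <- troughs + 26 / 360 * period
  list(period_ms = period, trough_times_ms = troughs,
       fs_volley_times_ms = fs_volleys,
       ipsc_onsets_ms = fs_volleys + 0.8,
       epsc_onsets_ms = troughs)
}

#' Synthesize LFP sweeps for one slice
#'
#' Additive model of the extracellular waveform: a square light-artifact
#' pulse coincident with the stimulus, negative Gaussian presynaptic volley
#' bumps, and (in control) negative Gaussian postsynaptic transients riding
#' on a slow positive half-cosine envelope, plus white noise. Under TTX only
#' the artifact remains; under CNQX+APV the artifact and the presynaptic
#' volleys remain. Pulses shorter than 2 ms recruit a single presynaptic
#' volley and attenuate the last transient; pulses of 5 ms or more recruit
#' all three volleys, with decreasing amplitude and increasing per-sweep
#' jitter ("decreasing coherence").
#'
#' @param slice_spec One element of [draw_slices()].
#' @param protocol A [stimulus_protocol()].
#' @param condition `"control"`, `"cnqx_apv"` or `"ttx"`.
#' @param n_sweeps Number of sweeps.
#' @param seed Integer seed.
#' @param sweep_ms Sweep length, ms.
#' @param rate_hz Sampling rate.
#' @param noise_sd_mv White-noise SD (mV); 0 gives the noiseless additive
#'   model exactly.
#' @return A [sweep_set()] of kind `lfp`.
#' @export
synth_lfp_sweeps <- function(slice_spec, protocol = stimulus_protocol(),
                             condition = c("control", "cnqx_apv", "ttx"),
                             n_sweeps = 20, seed = 1, sweep_ms = 50,
                             rate_hz = 20000, noise_sd_mv = 0.02) {
  condition <- match.arg(condition)
  if (n_sweeps < 1) stop("n_sweeps must be >= 1", call. = FALSE)
  on_ms <- protocol$onset_ms
  t_ms <- (seq_len(round(sweep_ms * rate_hz / 1000)) - 1) * 1000 / rate_hz

  n_volleys <- if (protocol$duration_ms >= 5) length(slice_spec$volley_times_ms) else 1L
  volley_amp <- 0.35 * c(1, 0.5, 0.25)[seq_len(n_volleys)]
  volley_jit <- c(0.02, 0.08, 0.15)[seq_len(n_volleys)]
  tr_amp <- c(0.8, 1.0, 0.7, 0.45) *
    (0.6 + 0.4 * protocol$intensity_frac)
  ntr <- length(slice_spec$transient_times_ms)
  tr_amp <- tr_amp[seq_len(ntr)]
  if (protocol$duration_ms <= 1) tr_amp[ntr] <- tr_amp[ntr] * 0.4
  tr_jit <- c(0.02, 0.04, 0.06, 0.08)[seq_len(ntr)]

  artifact <- ifelse(t_ms >= on_ms & t_ms < on_ms + protocol$duration_ms,
                     -0.08, 0)
  envelope <- {
    t0 <- on_ms + slice_spec$transient_times_ms[1] - 1.5
    dur <- 12
    ifelse(t_ms > t0 & t_ms < t0 + dur,
           0.25 * sin(pi * (t_ms - t0) / dur), 0)
  }

  .with_seed(seed, {
    sweeps <- lapply(seq_len(n_sweeps), function(k) {
      y <- artifact
      if (condition %in% c("control", "cnqx_apv")) {
        vt <- on_ms + slice_spec$volley_times_ms[seq_len(n_volleys)] +
          stats::rnorm(n_volleys, 0, volley_jit)
        for (j in seq_len(n_volleys))
          y <- y + .gauss_bump(t_ms, vt[j], 0.25, -volley_amp[j])
      }
      if (condition == "control") {
        y <- y + envelope
        pt <- on_ms + slice_spec$transient_times_ms +
          stats::rnorm(ntr, 0, tr_jit)
        for (j in seq_len(ntr))
          y <- y + .gauss_bump(t_ms, pt[j], 0.35, -tr_amp[j])
        # positive crests at the cycle troughs (the pre-EPSC maxima the
        # intracellular EPSC onsets are locked to)
        geom <- .cycle_geometry(slice_spec$transient_times_ms)
        for (tk in geom$trough_times_ms)
          y <- y + .gauss_bump(t_ms, on_ms + tk, 0.3, 0.18)
      }
      if (noise_sd_mv > 0) y <- y + stats::rnorm(length(y), 0, noise_sd_mv)
      trace(y, rate_hz = rate_hz, kind = "lfp")
    })
    sweep_set(sweeps, protocol, condition = condition,
              labels = list(slice_id = slice_spec$slice_id))
  })
}

# Effective per-order firing probability at a given light intensity:
# reliability declines for later spike orders as intensity drops. Near
# saturation the probability snaps to 1 so that strong stimuli evoke the
# full burst on every trial, as observed at 90% intensity.
.intensity_reliability <- function(reliability, intensity) {
  k <- seq_along(reliability)
  p <- stats::plogis((intensity + 0.3 - 0.1 * (k - 1)) / 0.15)
  p[p > 0.995] <- 1
  pmin(1, pmax(0, reliability * p))
}

# Per-trial jitter inflation at low light intensity (lower intensity ->
# less precise spikes; roughly x2.5 at 20% vs 90%).
.intensity_jitter_scale <- function(intensity) {
  1 + 1.5 * stats::plogis((0.45 - intensity) / 0.1)
}

# Stylized action-potential waveform: Gaussian depolarization to the class
# peak plus a brief afterhyperpolarization. Only the peak time matters to
# the downstream analyses.
.spike_waveform <- function(t_ms, peak_ms, peak_mv, base_mv, width_sd_ms) {
  .gauss_bump(t_ms, peak_ms, width_sd_ms, peak_mv - base_mv) +
    .gauss_bump(t_ms, peak_ms + 3 * width_sd_ms + 0.4, 0.35,
                -0.18 * (peak_mv - base_mv))
}

#' Synthesize current-clamp sweeps for one cell
#'
#' FS cells fire a stereotyped burst: spike waveforms at the cell's
#' per-order mean times plus per-trial Gaussian jitter, with later orders
#' becoming unreliable (and all orders more jittery) at low light intensity.
#' Pulses of 5 ms or more recruit an additional late, low-reliability spike.
#' RS cells show a depolarizing envelope crested by EPSP bumps aligned with
#' the ripplet transients and fire 1-2 spikes; at low intensity the spike
#' "hops" between the first and second EPSPs.
#'
#' @param cell A [draw_cell()] realization.
#' @param protocol A [stimulus_protocol()].
#' @param n_sweeps Number of sweeps (>= 1).
#' @param seed Integer seed.
#' @param sweep_ms,rate_hz Sweep geometry.
#' @param noise_sd_mv Membrane noise SD (mV).
#' @return A [sweep_set()] of kind `current_clamp`.
#' @export
synth_current_clamp_sweeps <- function(cell, protocol = stimulus_protocol(),
                                       n_sweeps = 20, seed = 1,
                                       sweep_ms = 50, rate_hz = 20000,
                                       noise_sd_mv = 0.5) {
  stopifnot(inherits(cell, "realized_cell"))
  if (n_sweeps < 1) stop("n_sweeps must be >= 1", call. = FALSE)
  on_ms <- protocol$onset_ms
  t_ms <- (seq_len(round(sweep_ms * rate_hz / 1000)) - 1) * 1000 / rate_hz
  base <- cell$v_rest_mv
  fs <- cell$cell_class == "FS"
  width <- if (fs) 0.13 else 0.34

  mt <- cell$mean_times_ms
  jit <- cell$trial_jitter_ms
  rel <- cell$reliability
  if (fs && protocol$duration_ms >= 5) {
    mt <- c(mt, mt[length(mt)] + 2.5)
    jit <- c(jit, 0.35)
    rel <- c(rel, 0.55)
  }
  eff_rel <- .intensity_reliability(rel, protocol$intensity_frac)
  jscale <- .intensity_jitter_scale(protocol$intensity_frac)

  env_amp <- if (fs) 12 else 15
  t0 <- on_ms + mt[1] - 2
  env <- ifelse(t_ms > t0 & t_ms < t0 + 25,
                env_amp * sin(pi * (t_ms - t0) / 25) *
                  (0.5 + 0.5 * protocol$intensity_frac), 0)

  .with_seed(seed, {
    sweeps <- lapply(seq_len(n_sweeps), function(k) {
      y <- base + env
      if (!fs) # EPSP bumps on the crest, in-phase with ripplet transients
        for (j in seq_along(mt))
          y <- y + .gauss_bump(t_ms, on_ms + mt[j] + 0.13, 0.45,
                               4 * eff_rel[j] / max(eff_rel))
      fire <- stats::runif(length(mt)) < eff_rel
      if (!fs && protocol$intensity_frac < 0.5 && fire[1] && fire[2])
        fire[sample(1:2, 1)] <- FALSE # EPSP hopping: one of the two crests
      pk <- on_ms + mt + stats::rnorm(length(mt), 0, jit * jscale)
      for (j in which(fire))
        y <- y + .spike_waveform(t_ms, pk[j], cell$spike_peak_mv, base, width)
      if (noise_sd_mv > 0)
        y <- y + .lowpass(stats::rnorm(length(y), 0, noise_sd_mv * 3),
                          rate_hz, 2000)
      trace(y, rate_hz = rate_hz, kind = "current_clamp")
    })
    sweep_set(sweeps, protocol, condition = "control",
              labels = list(cell_class = cell$cell_class))
  })
}

#' Synthesize voltage-clamp sweeps for one RS cell
#'
#' Sum of negative-going EPSC kernels with onsets at the ripplet troughs and
#' positive-going IPSC kernels with onsets 0.8 ms after each FS population
#' volley (itself slightly after each trough), so the merged onset sequence
#' strictly alternates E, I, E, I, ... The cell's `ei_balance` scales the
#' relative amplitudes so that the net charge ranges from clearly excitatory
#' (balance 0) to clearly inhibitory (balance 1).
#'
#' @param cell A [draw_cell()] RS realization (its `ei_balance` is used).
#' @param slice_spec Slice specification providing the transient times the
#'   cell's synaptic inputs are locked to; defaults to the population means.
#' @param protocol A [stimulus_protocol()].
#' @param holding_mv Holding potential, must lie in [-55, -50].
#' @param n_sweeps,seed,sweep_ms,rate_hz,noise_sd_pa As elsewhere.
#' @return A [sweep_set()] of kind `voltage_clamp`.
#' @export
synth_voltage_clamp_sweeps <- function(cell, slice_spec = NULL,
                                       protocol = stimulus_protocol(),
                                       holding_mv = -52, n_sweeps = 20,
                                       seed = 1, sweep_ms = 50,
                                       rate_hz = 20000, noise_sd_pa = 5) {
  stopifnot(inherits(cell, "realized_cell"))
  if (holding_mv < -55 || holding_mv > -50)
    stop("holding potential must lie between -55 and -50 mV", call. = FALSE)
  if (is.null(slice_spec))
    slice_spec <- list(slice_id = 0,
                       transient_times_ms = population_params()$ripplet_peak_means)
  geom <- .cycle_geometry(slice_spec$transient_times_ms)
  on_ms <- protocol$onset_ms
  t_ms <- (seq_len(round(sweep_ms * rate_hz / 1000)) - 1) * 1000 / rate_hz

  b <- if (is.na(cell$ei_balance)) 0.5 else cell$ei_balance
  amp_e <- 160 * (1 - b)
  # matched per-event charge at balance 0.5: scale by kernel-integral ratio
  amp_i <- 160 * b * ((1.0 - 0.2) / 0.535) / ((2.5 - 0.4) / 0.592)
  ne <- length(geom$epsc_onsets_ms)
  e_amp <- amp_e * c(1, rep(0.85, ne - 1))

  .with_seed(seed, {
    sweeps <- lapply(seq_len(n_sweeps), function(k) {
      y <- numeric(length(t_ms))
      eo <- on_ms + geom$epsc_onsets_ms + stats::rnorm(ne, 0, 0.03)
      io <- on_ms + geom$ipsc_onsets_ms + stats::rnorm(ne, 0, 0.03)
      for (j in seq_len(ne)) {
        if (amp_e > 0) y <- y + .psc_kernel(t_ms, eo[j], 0.2, 1.0, -e_amp[j])
        if (amp_i > 0) y <- y + .psc_kernel(t_ms, io[j], 0.4, 2.5, amp_i)
      }
      if (noise_sd_pa > 0)
        y <- y + .lowpass(stats::rnorm(length(y), 0, noise_sd_pa * 3),
                          rate_hz, 2000)
      trace(y, rate_hz = rate_hz, kind = "voltage_clamp",
            holding_mv = holding_mv)
    })
    sweep_set(sweeps, protocol, condition = "control",
              labels = list(ei_balance = b))
  })
}

#' Synthesize a pair of spike trains driven by shared volleys
#'
#' Emulates two simultaneously recorded FS cells driven by common excitatory
#' volleys: in every trial both cells inherit a common offset
#' `N(0, sigma_common)` added to the shared volley times, and each cell adds
#' independent `N(0, sigma_indep)` jitter per spike.
#'
#' @param shared_times_ms Volley times shared by the pair (nonempty).
#' @param sigma_indep_ms Per-cell, per-spike independent jitter SD (ms).
#' @param sigma_common_ms Per-trial common jitter SD (ms).
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @return A list with `a` and `b`: lists (one per trial) of sorted spike
#'   times in ms.
#' @export
synth_pair_trains <- function(shared_times_ms, sigma_indep_ms = 0.15,
                              sigma_common_ms = 0.05, n_trials = 30,
                              seed = 1) {
  if (!length(shared_times_ms))
    stop("shared_times_ms must be nonempty", call. = FALSE)
  if (sigma_indep_ms < 0 || sigma_common_ms < 0)
    stop("jitter SDs must be nonnegative", call. = FALSE)
  n <- length(shared_times_ms)
  .with_seed(seed, {
    a <- vector("list", n_trials); b <- vector("list", n_trials)
    for (k in seq_len(n_trials)) {
      common <- shared_times_ms + stats::rnorm(1, 0, sigma_common_ms)
      a[[k]] <- sort(common + stats::rnorm(n, 0, sigma_indep_ms))
      b[[k]] <- sort(common + stats::rnorm(n, 0, sigma_indep_ms))
    }
    list(a = a, b = b)
  })
}

#' Synthesize a standardized current-step family for one cell
#'
#' Emulates the routine characterization protocol: 600-ms current steps in
#' both directions around rest. Subthreshold sweeps charge exponentially to
#' `I * R_in`; suprathreshold sweeps ride a depolarized plateau and fire
#' stylized spikes whose rate, adaptation and width follow the class
#' archetype (FS: fast sustained firing, narrow spikes, no adaptation; RS:
#' an initial doublet then slow steady firing, wide spikes). Beyond
#' `i_crit_pa` the first-spike height declines with increasing current,
#' defining the maximal tolerated step.
#'
#' @param cell_class `"FS"` or `"RS"`.
#' @param currents_pa Per-sweep step currents; defaults cover 4-6
#'   subthreshold steps of both signs plus a suprathreshold series.
#' @param r_in_mohm Input resistance, megaohms.
#' @param v_rest_mv Resting potential.
#' @param rheobase_pa Minimal spiking current.
#' @param i_crit_pa Largest current with full-height spikes.
#' @param tau_m_ms Membrane time constant.
#' @param seed,rate_hz,noise_sd_mv As elsewhere.
#' @return A current-clamp [sweep_set()] with `labels$currents_pa` set;
#'   steps span 100-700 ms of an 800 ms sweep.
#' @export
synth_step_family <- function(cell_class = c("FS", "RS"),
                              currents_pa = NULL, r_in_mohm = NULL,
                              v_rest_mv = NULL, rheobase_pa = 200,
                              i_crit_pa = 500, tau_m_ms = 10, seed = 1,
                              rate_hz = 20000, noise_sd_mv = 0.1) {
  cell_class <- match.arg(cell_class)
  fs <- cell_class == "FS"
  if (is.null(r_in_mohm)) r_in_mohm <- if (fs) 100 else 150
  if (is.null(v_rest_mv)) v_rest_mv <- if (fs) -70 else -75
  if (is.null(currents_pa))
    currents_pa <- c(-100, -50, -25, 25, 50, 100, rheobase_pa,
                     300, 400, 500, 600)
  step_on <- 100; step_off <- 700; sweep_ms <- 800
  t_ms <- (seq_len(round(sweep_ms * rate_hz / 1000)) - 1) * 1000 / rate_hz
  width <- if (fs) 0.127 else 0.34
  peak_mv <- 20

  .with_seed(seed, {
    sweeps <- lapply(currents_pa, function(I) {
      instep <- t_ms >= step_on & t_ms < step_off
      # strong suprathreshold drive depolarizes much faster than the
      # passive membrane time constant
      tau <- if (I >= rheobase_pa) 2.5 else tau_m_ms
      charge <- ifelse(instep, 1 - exp(-(t_ms - step_on) / tau), 0)
      relax <- ifelse(t_ms >= step_off,
                      exp(-(t_ms - step_off) / tau), 0)
      if (I < rheobase_pa) {
        dv <- I / 1000 * r_in_mohm # pA * MOhm = mV per nA
        y <- v_rest_mv + dv * (charge + relax * (1 - exp(-(step_off - step_on) / tau_m_ms)))
      } else {
        plateau <- 20
        y <- v_rest_mv + plateau * (charge + relax)
        if (fs) {
          rate_fire <- min(300, 150 + 0.25 * (I - rheobase_pa))
          st <- seq(step_on + 8, step_off - 5, by = 1000 / rate_fire)
        } else {
          st <- c(step_on + 8, step_on + 12,
                  seq(step_on + 40, step_off - 5, by = 30))
        }
        hscale <- if (I > i_crit_pa) 1 - 0.15 * (I - i_crit_pa) / 100 else 1
        base_loc <- v_rest_mv + plateau
        amp <- (peak_mv - base_loc) * hscale
        for (s0 in st) {
          y <- y + .gauss_bump(t_ms, s0, width, amp) +
            .gauss_bump(t_ms, s0 + 3 * width + 0.4, 0.4, -8)
        }
      }
      if (noise_sd_mv > 0)
        y <- y + stats::rnorm(length(y), 0, noise_sd_mv)
      trace(y, rate_hz = rate_hz, kind = "current_clamp")
    })
    sweep_set(sweeps, stimulus_protocol(onset_ms = step_on,
                                        duration_ms = step_off - step_on,
                                        intensity_frac = 1),
              condition = "control",
              labels = list(cell_class = cell_class,
                            currents_pa = currents_pa))
  })
}
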