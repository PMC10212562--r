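test_that("generators are deterministic given a seed and vary across seeds", {
  p <- population_params()
  expect_identical(draw_slices(p, 5, seed = 42), draw_slices(p, 5, seed = 42))
  expect_false(identical(draw_slices(p, 5, seed = 42),
                         draw_slices(p, 5, seed = 43)))
  tr1 <- synth_pair_trains(c(3, 6, 9), n_trials = 5, seed = 7)
  expect_identical(tr1, synth_pair_trains(c(3, 6, 9), n_trials = 5, seed = 7))
  expect_false(identical(tr1,
                         synth_pair_trains(c(3, 6, 9), n_trials = 5, seed = 8)))
  # the seeded generators restore the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(draw_slices(p, 2, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("slice draws recover the population means (law of large numbers)", {
  p <- population_params()
  slices <- draw_slices(p, 4000, seed = 3)
  first_peak <- vapply(slices, function(s) s$transient_times_ms[1],
                       numeric(1))
  sd1 <- p$ripplet_peak_sems[1] * sqrt(p$ripplet_n)
  expect_lt(abs(mean(first_peak) - p$ripplet_peak_means[1]),
            3 * sd1 / sqrt(4000) + 0.02)
  # times strictly increasing in every slice
  expect_true(all(vapply(slices, function(s)
    !is.unsorted(s$transient_times_ms, strictly = TRUE) &&
      !is.unsorted(s$volley_times_ms, strictly = TRUE), logical(1))))
})

test_that("LFP conditions are additive around the artifact", {
  slice <- mean_slice()
  prot <- stimulus_protocol()
  ctrl <- average_sweeps(synth_lfp_sweeps(slice, prot, "control", 1, seed = 1,
                                          noise_sd_mv = 0))
  blk <- average_sweeps(synth_lfp_sweeps(slice, prot, "cnqx_apv", 1, seed = 1,
                                         noise_sd_mv = 0))
  ttx <- average_sweeps(synth_lfp_sweeps(slice, prot, "ttx", 1, seed = 1,
                                         noise_sd_mv = 0))
  # control - blocked = postsynaptic only; the same sweep seed shares the
  # volley jitter, so the residual volley component cancels exactly
  post <- isolate_postsynaptic(ctrl, blk)
  t_ms <- trace_times_ms(post) - prot$onset_ms
  pre_window <- t_ms > 1 & t_ms < 2.5 # before the leading cycle crest
  expect_lt(max(abs(post$samples[pre_window])), 0.02)
  # ttx carries only the square artifact
  in_pulse <- t_ms >= 0.2 & t_ms <= prot$duration_ms - 0.2
  expect_equal(unique(round(ttx$samples[in_pulse], 6)), -0.08)
  expect_equal(max(abs(ttx$samples[t_ms > prot$duration_ms + 1])), 0)
})

test_that("largest postsynaptic transient reaches the analyzable amplitude", {
  slice <- mean_slice()
  avg <- average_sweeps(synth_lfp_sweeps(slice, n_sweeps = 10, seed = 2))
  f <- detect_ripplet_features(avg, stimulus_protocol())
  expect_identical(f$flag, "ok")
  expect_gte(max(f$transient_amplitudes_mv), 0.5)
})

test_that("FS sweeps fire the full burst at high intensity and respect reliability", {
  cell <- draw_cell(cell_class = "FS", seed = 5)
  prot <- stimulus_protocol(duration_ms = 2, intensity_frac = 0.9)
  cc <- synth_current_clamp_sweeps(cell, prot, n_sweeps = 20, seed = 6)
  counts <- vapply(cc$sweeps, function(tr) length(detect_spikes(tr)),
                   integer(1))
  expect_true(all(counts == 4L))

  cell0 <- cell
  cell0$reliability[3] <- 0
  cc0 <- synth_current_clamp_sweeps(cell0, prot, n_sweeps = 15, seed = 7)
  counts0 <- vapply(cc0$sweeps, function(tr) length(detect_spikes(tr)),
                    integer(1))
  expect_true(all(counts0 == 3L))
})

test_that("measured per-order jitter recovers the configured jitter", {
  cell <- draw_cell(cell_class = "FS", seed = 8)
  prot <- stimulus_protocol(duration_ms = 2, intensity_frac = 0.9)
  cc <- synth_current_clamp_sweeps(cell, prot, n_sweeps = 200, seed = 9)
  sts <- assign_spike_orders(detect_spike_trains(cc))
  bs <- burst_stats(sts)
  for (k in 2:4) # order 1 jitter (23 us) sits at the sampling floor
    expect_lt(abs(bs$per_order$jitter_us[k] - cell$trial_jitter_ms[k] * 1000),
              0.25 * cell$trial_jitter_ms[k] * 1000)
})

test_that("voltage-clamp synthesis alternates onsets and obeys the balance sign", {
  cell <- draw_cell(cell_class = "RS", seed = 10)
  cell$ei_balance <- 0
  vc <- synth_voltage_clamp_sweeps(cell, n_sweeps = 5, seed = 11)
  q <- net_charge(average_sweeps(vc), c(12, 40))
  expect_lt(q, 0) # fully excitatory -> net inward (negative) charge

  geom <- rippletlab:::.cycle_geometry(mean_slice()$transient_times_ms)
  merged <- sort(c(geom$epsc_onsets_ms, geom$ipsc_onsets_ms))
  is_e <- merged %in% geom$epsc_onsets_ms
  expect_true(all(is_e[c(TRUE, FALSE)]))
  expect_true(all(diff(merged) > 0))

  expect_error(synth_voltage_clamp_sweeps(cell, holding_mv = -45),
               "holding")
})

test_that("paired trains share common volleys with independent jitter", {
  st <- c(3.1, 5.5, 7.7, 10.3)
  tr0 <- synth_pair_trains(st, sigma_indep_ms = 0, sigma_common_ms = 0.1,
                           n_trials = 20, seed = 12)
  for (k in seq_len(20)) expect_equal(tr0$a[[k]], tr0$b[[k]])

  tr <- synth_pair_trains(st, sigma_indep_ms = 0.15, sigma_common_ms = 0,
                          n_trials = 1000, seed = 13)
  diffs <- unlist(Map(`-`, tr$a, tr$b))
  expect_equal(sd(diffs), sqrt(2) * 0.15, tolerance = 0.05)
  expect_error(synth_pair_trains(numeric(0)), "nonempty")
})
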