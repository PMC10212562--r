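test_that("spike detection handles flat traces and refractory merges", {
  flat <- trace(rep(-70, 2000), kind = "current_clamp")
  expect_identical(detect_spikes(flat), numeric(0))
  expect_error(detect_spikes(trace(rep(0, 100), kind = "lfp")),
               "current_clamp")

  # two spikes 0.5 ms apart merge into one detection, with a warning
  t_ms <- (0:1999) / 20
  y <- -70 + 90 * exp(-(t_ms - 40)^2 / (2 * 0.12^2)) +
    80 * exp(-(t_ms - 40.5)^2 / (2 * 0.12^2))
  expect_warning(pk <- detect_spikes(trace(y, kind = "current_clamp")),
                 "merged")
  expect_length(pk, 1L)
})

test_that("spike peak times are recovered to sub-sample precision", {
  t_ms <- (0:1999) / 20
  true_pk <- c(12.3471, 15.9113, 18.5032)
  y <- -70
  for (p in true_pk) y <- y + 95 * exp(-(t_ms - p)^2 / (2 * 0.13^2))
  pk <- detect_spikes(trace(y, kind = "current_clamp"))
  expect_length(pk, 3L)
  expect_lt(max(abs(pk - true_pk)), 0.005)
})

test_that("order assignment matches spikes to the burst template", {
  base <- c(3.1, 5.5, 7.7, 10.3)
  trains <- lapply(1:10, function(i) base + rnorm(4, 0, 0.05))
  trains[[4]] <- trains[[4]][-3] # one trial missing spike 3
  trains[[7]] <- sort(c(trains[[7]], 16.0)) # stray spike far out
  s <- assign_spike_orders(spike_train_set(trains))
  expect_equal(s$orders[[1]], 1:4)
  expect_equal(s$orders[[4]], c(1L, 2L, 4L))
  expect_true(is.na(s$orders[[7]][5]))
  bs <- burst_stats(s)
  expect_equal(bs$per_order$reliability[3], 9 / 10)
  expect_error(assign_spike_orders(spike_train_set(trains[1:2])),
               "three trials")
})

test_that("burst statistics satisfy their identities", {
  # CV identity on a constructed set: order mean 3.1 ms, jitter 23 us
  set.seed(31)
  times <- rnorm(400, 3.1, 0.023)
  times <- 3.1 + (times - mean(times)) * 0.023 / sd(times) # exact moments
  s <- spike_train_set(as.list(times), orders = as.list(rep(1L, 400)))
  bs <- burst_stats(s)
  expect_equal(bs$per_order$jitter_us, 23, tolerance = 1e-6)
  expect_equal(round(bs$per_order$cv_pct, 1), 0.7)
  expect_equal(bs$per_order$cv_pct,
               bs$per_order$jitter_us / 1000 / bs$per_order$mean_ms * 100)

  # burst frequency from the printed ISIs
  trains <- lapply(1:5, function(i) cumsum(c(3.1, 2.4, 2.2, 2.7)))
  s2 <- assign_spike_orders(spike_train_set(trains))
  bs2 <- burst_stats(s2)
  expect_equal(bs2$isis_ms, c(2.4, 2.2, 2.7))
  expect_equal(round(bs2$burst_frequency_hz, 2), 410.96)
  expect_equal(bs2$per_order$jitter_us, rep(0, 4)) # identical trials
  expect_equal(bs2$spikes_per_stimulus, 4)
})

test_that("jitter estimator recovers configured spread within 15%", {
  set.seed(32)
  sigma <- 0.11 # ms
  trains <- lapply(1:200, function(i) sort(c(rnorm(1, 3.1, sigma),
                                             rnorm(1, 7.7, sigma))))
  bs <- burst_stats(assign_spike_orders(spike_train_set(trains),
                                        tol_ms = 1.5))
  expect_lt(max(abs(bs$per_order$jitter_us - sigma * 1000)),
            0.15 * sigma * 1000)
})

test_that("ephys parameters are extracted from a step family", {
  fam <- synth_step_family("FS", seed = 33)
  p <- extract_ephys_params(fam)
  expect_identical(p$flag, "ok")
  expect_equal(p$r_in_mohm, 100, tolerance = 0.02)
  expect_lt(abs(p$v_rest_mv - -70), 0.5)
  expect_equal(p$i_max_pa, 500)
  # FS steady state: ISI 1000/225 at the maximal tolerated step
  expect_equal(p$f_max_hz, 225, tolerance = 0.01)
  expect_lt(p$swhh_ms, 0.5)
  expect_gt(p$spike_height_mv, 10)

  # last five ISIs all 4 ms -> 250 Hz (direct reciprocal check)
  expect_equal(1000 / mean(rep(4, 5)), 250)

  # no dV/dt = 5 V/s crossing -> threshold undefined
  slow <- synth_step_family("FS", seed = 34)
  slow$sweeps <- lapply(slow$sweeps, function(tr)
    trace(-70 + 0.1 * sin(trace_times_ms(tr) / 50),
          kind = "current_clamp"))
  expect_identical(extract_ephys_params(slow)$flag, "non_spiking")
})

test_that("classification separates the two archetypes without confusion", {
  expect_identical(classify_cell(list(f_max_hz = 200, swhh_ms = 0.3)), "FS")
  expect_identical(classify_cell(list(f_max_hz = 40, swhh_ms = 0.9)), "RS")
  expect_identical(classify_cell(list(f_max_hz = 120, swhh_ms = 0.4)),
                   "unclassified")
  for (sd in 1:4) {
    expect_identical(
      classify_cell(extract_ephys_params(synth_step_family("FS", seed = sd))),
      "FS")
    expect_identical(
      classify_cell(extract_ephys_params(synth_step_family("RS", seed = sd))),
      "RS")
  }
})

test_that("coupling coefficient is the follower/driver deflection ratio", {
  n <- 16000 # 800 ms at 20 kHz
  t_ms <- (seq_len(n) - 1) / 20
  instep <- t_ms >= 100 & t_ms < 700
  drv <- trace(-70 - 10 * instep, kind = "current_clamp")
  fol <- trace(-70 - 0.08 * instep, kind = "current_clamp")
  expect_equal(coupling_coefficient(drv, fol), 0.8, tolerance = 1e-9)
  zero <- trace(rep(-70, n), kind = "current_clamp")
  expect_equal(coupling_coefficient(drv, zero), 0)
  weak <- trace(-70 - 0.5 * instep, kind = "current_clamp")
  expect_error(coupling_coefficient(weak, fol), "below 1 mV")
})
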