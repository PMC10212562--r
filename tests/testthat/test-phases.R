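test_that("anchors are built from interleaved troughs and transients", {
  f <- structure(list(transient_times_ms = 4.4,
                      trough_times_ms = c(2.9, 5.3)),
                 class = "ripplet_features")
  a <- anchors_from_lfp(f)
  expect_equal(a$anchor_times_ms, c(2.9, 4.4, 5.3))
  expect_equal(a$anchor_phases_deg, c(0, 180, 360))

  bad <- structure(list(transient_times_ms = c(4.4, 5.0),
                        trough_times_ms = c(2.9, 5.3)),
                   class = "ripplet_features")
  expect_error(anchors_from_lfp(bad), "interleave")

  slice <- mean_slice()
  ff <- features_of(slice, seed = 61)
  aa <- anchors_from_lfp(ff)
  expect_equal(length(aa$anchor_times_ms), 2L * ff$n_transients + 1L)
})

test_that("E-I anchors map EPSC onsets to 0 and IPSC onsets to 180", {
  e <- ei_sequence(c(3.0, 5.4), c(4.0, 6.4))
  a <- anchors_from_ei(e)
  expect_equal(a$anchor_phases_deg, c(0, 180, 360, 540))
  expect_equal(a$anchor_times_ms, c(3.0, 4.0, 5.4, 6.4))
  expect_error(ei_sequence(c(3.0, 3.5), c(6.0)), "alternate")
  # mirror of the LFP-anchor geometry on detected generator output
  cell <- draw_cell(cell_class = "RS", seed = 62)
  cell$ei_balance <- 0.5
  vc <- synth_voltage_clamp_sweeps(cell, n_sweeps = 20, seed = 63)
  ei <- quiet(detect_ei_onsets(average_sweeps(vc), vc$protocol))
  aa <- anchors_from_ei(ei)
  expect_equal(diff(aa$anchor_phases_deg),
               rep(180, length(aa$anchor_times_ms) - 1))
})

test_that("phase assignment interpolates linearly between anchors", {
  a <- phase_anchors(c(2.9, 4.4, 5.3), c(0, 180, 360))
  expect_equal(assign_phase(2.9, a), 0, ignore_attr = TRUE)
  expect_equal(assign_phase(2.9 + 0.75, a), 90, ignore_attr = TRUE)
  # trough at t0, peak at t0 + 1.2, spike at t0 + 0.173 -> ~26 degrees
  a2 <- phase_anchors(c(2.0, 3.2, 4.4), c(0, 180, 360))
  expect_equal(as.numeric(assign_phase(2.173, a2)), 180 * 0.173 / 1.2,
               tolerance = 1e-9)
  # monotone in spike time between anchors
  ph <- assign_phase(seq(2.95, 5.25, by = 0.05), a)
  expect_true(all(diff(ph) > 0 | diff(ph) < -300)) # one wrap at mid trough
  # spikes outside the span are excluded and counted
  out <- assign_phase(c(1.0, 3.0, 9.0), a)
  expect_length(out, 1L)
  expect_equal(attr(out, "n_excluded"), 2L)
})

test_that("phases re-express relative to the time-nearest trough", {
  # asymmetric half-cycles: values slightly beyond +180 are possible
  a <- phase_anchors(c(0, 1.2, 3.6), c(0, 180, 360))
  # spike just past the peak: nearest trough in time is still the first
  ph <- assign_phase(1.3, a)
  expect_gt(ph[1], 180)
  expect_equal(round(ph[1], 1), 187.5, ignore_attr = TRUE)
})

test_that("phase-to-time conversion matches the worked examples", {
  expect_equal(round(phase_to_time(100, 1000 / 180), 1), 1.5)
  expect_equal(phase_to_time(360, 7.3), 7.3)
  expect_equal(round(phase_to_time(59, 2.4), 1), 0.4)
  expect_equal(round(phase_to_time(135, 1000 / 408), 1), 0.9)
  expect_error(phase_to_time(90, 0), "positive")
})

test_that("phase summaries use linear-scale percentiles", {
  s <- phase_summary(0)
  expect_equal(c(s$median_deg, s$p10_deg, s$p90_deg), c(0, 0, 0))
  expect_equal(phase_summary(c(-10, 0, 10))$median_deg, 0)
  x <- c(-14, 5, 20, 26, 30, 50, 82)
  s2 <- phase_summary(x)
  expect_equal(s2$median_deg, 26)
  expect_equal(s2$p10_deg, unname(quantile(x, 0.1)))
})

test_that("generated FS and RS phase cohorts are recovered non-overlapping", {
  p <- population_params()
  # asymmetric cycle (trough->peak 1.2 ms, peak->trough 1.7 ms): spikes
  # slightly past a peak stay referred to the preceding trough, so phases
  # beyond +180 survive without wrapping, as in the plotted data
  times <- 3 + cumsum(c(0, rep(c(1.2, 1.7), 5)))
  a <- phase_anchors(times, seq(0, by = 180, length.out = length(times)))
  set.seed(64)
  fs_sd <- (p$fs_phase_deg[["p90"]] - p$fs_phase_deg[["p10"]]) / 2.5631
  rs_sd <- (p$rs_phase_deg[["p90"]] - p$rs_phase_deg[["p10"]]) / 2.5631
  fs_deg <- rnorm(28, p$fs_phase_deg[["median"]], fs_sd)
  rs_deg <- rnorm(13, p$rs_phase_deg[["median"]], rs_sd)
  trough2 <- times[5] # a mid-train trough (phase 720)
  to_time <- function(deg) trough2 +
    ifelse(deg >= 0, pmin(deg, 180) / 180 * 1.2, deg / 180 * 1.7) +
    pmax(deg - 180, 0) / 180 * 1.7
  fs_rec <- assign_phase(to_time(fs_deg), a)
  rs_rec <- assign_phase(to_time(rs_deg), a)
  expect_equal(as.numeric(fs_rec), fs_deg, tolerance = 1e-9)
  expect_equal(as.numeric(rs_rec), rs_deg, tolerance = 1e-9)
  expect_lt(abs(phase_summary(rs_rec)$median_deg -
                  p$rs_phase_deg[["median"]]), 10)
  expect_lt(max(fs_rec), min(rs_rec))
})
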