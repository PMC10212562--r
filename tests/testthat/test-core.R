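test_that("domain containers validate their invariants", {
  expect_error(stimulus_protocol(duration_ms = 0), "positive")
  expect_error(stimulus_protocol(intensity_frac = 1.2), "intensity")
  expect_error(trace(1:10, kind = "voltage_clamp"), "holding")
  expect_error(trace(1:10, kind = "lfp", holding_mv = -52), "holding")
  tr <- trace(rep(0, 100), kind = "lfp")
  expect_error(sweep_set(list(), stimulus_protocol()), "at least one")
  expect_error(sweep_set(list(tr, trace(rep(0, 50), kind = "lfp")),
                         stimulus_protocol(onset_ms = 0.5, duration_ms = 1)),
               "share")
  expect_error(sweep_set(list(tr), stimulus_protocol(), condition = "nacl"),
               "unknown condition")
  # stimulus must fit inside the sweep (100 samples @ 20 kHz = 5 ms)
  expect_error(sweep_set(list(tr), stimulus_protocol(onset_ms = 4,
                                                     duration_ms = 2)),
               "before the sweep")
})

test_that("average_sweeps is the pointwise mean and is linear", {
  prot <- stimulus_protocol(onset_ms = 1, duration_ms = 1)
  tpl <- sin(seq(0, 4 * pi, length.out = 200))
  mk <- function(v) trace(v, kind = "lfp")
  s_same <- sweep_set(list(mk(tpl), mk(tpl), mk(tpl)), prot)
  expect_equal(average_sweeps(s_same)$samples, tpl)

  s_sym <- sweep_set(list(mk(tpl + 1), mk(tpl - 1)), prot)
  expect_equal(average_sweeps(s_sym)$samples, tpl)

  # linearity: average(a * sweeps) = a * average(sweeps)
  a <- 2.5
  s_scaled <- sweep_set(lapply(s_sym$sweeps, function(tr)
    trace(a * tr$samples, kind = "lfp")), prot)
  expect_equal(average_sweeps(s_scaled)$samples,
               a * average_sweeps(s_sym)$samples)
})

test_that("averaging N noisy copies shrinks the RMS error like 1/sqrt(N)", {
  prot <- stimulus_protocol(onset_ms = 1, duration_ms = 1)
  tpl <- sin(seq(0, 4 * pi, length.out = 400))
  set.seed(11)
  rms <- vapply(c(4, 64), function(n) {
    sweeps <- lapply(seq_len(n), function(i)
      trace(tpl + rnorm(400, 0, 0.5), kind = "lfp"))
    avg <- average_sweeps(sweep_set(sweeps, prot))
    sqrt(mean((avg$samples - tpl)^2))
  }, numeric(1))
  # ratio should be ~ sqrt(64/4) = 4
  expect_gt(rms[1] / rms[2], 2.5)
  expect_lt(rms[1] / rms[2], 6.5)
})

test_that("sweep files round-trip through write and read", {
  slice <- mean_slice()
  s <- synth_lfp_sweeps(slice, n_sweeps = 3, seed = 4)
  s$labels$animal <- "synthetic_A1"
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweepset(s, path)
  s2 <- read_sweepset(path)
  expect_equal(length(s2$sweeps), 3L)
  expect_equal(s2$sweeps[[1]]$kind, "lfp")
  expect_equal(s2$condition, s$condition)
  expect_equal(s2$protocol, s$protocol)
  expect_equal(s2$labels$animal, "synthetic_A1")
  for (k in seq_along(s$sweeps))
    expect_lt(max(abs(s2$sweeps[[k]]$samples - s$sweeps[[k]]$samples)),
              1e-6)
  # canonical re-serialization is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_sweepset(s2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed sweep files are rejected with a useful message", {
  slice <- mean_slice()
  s <- synth_lfp_sweeps(slice, n_sweeps = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweepset(s, path)
  lines <- readLines(path)

  p1 <- withr::local_tempfile()
  writeLines(lines[!grepl("^# sample_rate_hz", lines)], p1)
  expect_error(read_sweepset(p1), "sample_rate_hz")

  p2 <- withr::local_tempfile()
  bad <- lines
  bad[20] <- sub(",[^,]*$", "", bad[20]) # drop one field
  writeLines(bad, p2)
  expect_error(read_sweepset(p2), "line 20")

  p3 <- withr::local_tempfile()
  bad <- lines
  bad[3] <- "# condition=saline"
  writeLines(bad, p3)
  expect_error(read_sweepset(p3), "unknown condition")

  expect_error(read_sweepset(file.path(tempdir(), "does_not_exist.csv")),
               "not found")
})

test_that("voltage-clamp metadata (holding potential) survives the round-trip", {
  cell <- draw_cell(cell_class = "RS", seed = 2)
  vc <- synth_voltage_clamp_sweeps(cell, n_sweeps = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweepset(vc, path)
  vc2 <- read_sweepset(path)
  expect_equal(vc2$sweeps[[1]]$kind, "voltage_clamp")
  expect_equal(vc2$sweeps[[1]]$holding_mv, -52)
})

test_that("analysis results serialize to JSON documents", {
  f <- features_of(mean_slice(), seed = 77)
  path <- withr::local_tempfile(fileext = ".json")
  write_result_json(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$transient_times_ms, f$transient_times_ms)
  expect_equal(back$flag, "ok")
})
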