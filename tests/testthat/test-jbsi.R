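test_that("identical isolated trains give JBSI exactly 1", {
  # spikes isolated: pairwise gaps > 2 * (J + SW) for every grid SW
  tr <- list(c(5, 20, 35), c(10, 50))
  for (sw in c(0.2, 0.5, 1.0)) {
    expect_equal(jbsi(tr, tr, jbsi_params(sw)), 1.0, tolerance = 1e-12)
  }
})

test_that("the analytic chance term follows the interval-overlap geometry", {
  # A = {10.0}, B = {10.4}, SW = 0.3, J = 0.6: S = 0,
  # p = |[10.1, 10.7] n [9.4, 10.6]| / 1.2 = 0.5 / 1.2
  v <- jbsi(list(10.0), list(10.4), jbsi_params(0.3))
  expect_equal(v, 2 * (0 - 0.5 / 1.2), tolerance = 1e-12)
  expect_equal(round(v, 4), -0.8333)
})

test_that("fully offset trains give JBSI 0", {
  a <- list(c(5, 10, 15))
  b <- list(c(5, 10, 15) + 3) # offset > J + SW for SW = 0.5
  expect_equal(jbsi(a, b, jbsi_params(0.5)), 0, tolerance = 1e-12)
})

test_that("empty trains are flagged undefined", {
  expect_warning(v <- jbsi(list(numeric(0)), list(c(1, 2)),
                           jbsi_params(0.3)), "empty")
  expect_true(is.na(v))
  expect_error(jbsi(list(1), list(1, 2), jbsi_params(0.3)), "trial counts")
})

test_that("analytic chance equals the Monte-Carlo oracle on random fixtures", {
  set.seed(41)
  worst <- 0
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    a <- list(sort(runif(n, 0, 30)))
    b <- list(sort(runif(sample(3:8, 1), 0, 30)))
    sw <- runif(1, 0.2, 0.8)
    params <- jbsi_params(sw)
    # analytic <S_J> extracted from the index: jbsi = beta * (S - <S_J>)
    pick <- rippletlab:::.jbsi_pick(a, b)
    acc <- rippletlab:::.jbsi_trial(pick$a[[1]], pick$b[[1]],
                                    params$sw_ms, params$j_ms, 0)
    analytic <- acc[2] / acc[3]
    mc <- chance_synchrony_mc(a, b, params, n_reps = 4000, seed = rep)
    se <- sqrt(analytic * (1 - analytic) / (acc[3] * 4000)) + 1e-4
    worst <- max(worst, abs(mc - analytic) / se)
  }
  expect_lt(worst, 3.5)
})

test_that("isolated coincident spikes have chance synchrony 1/2", {
  a <- list(c(10, 30)); params <- jbsi_params(0.4)
  mc <- chance_synchrony_mc(a, a, params, n_reps = 5000, seed = 2)
  expect_equal(mc, 0.5, tolerance = 0.02)
  # J -> SW limit: jitter can never move a coincident spike out of window
  tight <- jbsi_params(0.4, j_ms = 0.4000001)
  expect_equal(chance_synchrony_mc(a, a, tight, n_reps = 500, seed = 3), 1)
})

test_that("JBSI never exceeds 1 with the standard J = 2 SW, beta = 2", {
  set.seed(42)
  for (rep in 1:30) {
    a <- lapply(1:3, function(k) sort(runif(sample(2:6, 1), 0, 25)))
    b <- lapply(1:3, function(k) sort(runif(sample(2:6, 1), 0, 25)))
    v <- jbsi(a, b, jbsi_params(runif(1, 0.1, 1)))
    expect_lte(v, 1 + 1e-9)
  }
})

test_that("independent Poisson trains have near-zero expected JBSI", {
  set.seed(43)
  vals <- vapply(1:200, function(i) {
    a <- poisson_train(80, 50, 4)
    b <- poisson_train(80, 50, 4)
    jbsi(a, b, jbsi_params(0.3))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("appending a distant synchronous block preserves perfect synchrony", {
  a <- list(c(5, 8, 11))
  expect_equal(jbsi(a, a, jbsi_params(0.3)), 1)
  a2 <- list(c(5, 8, 11, 100, 103, 106))
  expect_equal(jbsi(a2, a2, jbsi_params(0.3)), 1)
})

test_that("the matrix localizes an injected lag and defines precision", {
  st <- c(3.1, 5.5, 7.7, 10.3)
  tr <- synth_pair_trains(st, sigma_indep_ms = 0.05, sigma_common_ms = 0.02,
                          n_trials = 30, seed = 44)
  # shift train b later by 0.3 ms
  tr$b <- lapply(tr$b, function(x) x + 0.3)
  m <- jbsi_matrix(tr$a, tr$b)
  expect_equal(abs(m$lag_at_precision_ms), 0.3, tolerance = 0.1001)

  # identical trains: precision = smallest grid SW, lag 0
  tr0 <- list(c(5, 10, 15))
  m0 <- jbsi_matrix(tr0, tr0)
  expect_equal(m0$precision_ms, 0.1)
  expect_equal(m0$lag_at_precision_ms, 0)
})

test_that("precision is the smallest window whose best-lag JBSI exceeds 0.5", {
  m <- structure(list(sw_grid_ms = c(0.1, 0.2, 0.3, 0.4),
                      lag_grid_ms = 0,
                      values = matrix(c(0.2, 0.4, 0.7, 0.8), ncol = 1)),
                 class = "jbsi_matrix")
  pl <- precision_and_lag(m)
  expect_equal(pl$precision_ms, 0.3)
  m$values <- matrix(c(0.1, 0.2, 0.3, 0.4), ncol = 1)
  expect_true(is.na(precision_and_lag(m)$precision_ms))
})

test_that("the jittered-pair protocol shows rise-then-collapse with precision 0.3", {
  st <- c(3.1, 5.5, 7.7, 10.3)
  precisions <- vapply(1:6, function(i) {
    tr <- synth_pair_trains(st, sigma_indep_ms = 0.15, sigma_common_ms = 0.05,
                            n_trials = 30, seed = 50 + i)
    m <- jbsi_matrix(tr$a, tr$b)
    best_02 <- max(m$values["sw_0.2", ])
    best_03 <- max(m$values["sw_0.3", ])
    expect_gt(best_03, 0.5) # rises above the precision level by SW 0.3
    m$precision_ms
  }, numeric(1))
  expect_equal(median(precisions), 0.3, tolerance = 0.1001)
})
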