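# Jitter-Based Synchrony Index. Observed synchrony S is the fraction of
# spikes in the less active train falling within +/-SW of a spike in the
# other train; chance synchrony <S_J> is computed analytically as, for each
# jittered spike, the measure of the union of the target +/-SW windows
# intersected with the spike's +/-J jitter range, divided by 2J (uniform
# jitter on [-J, +J]). JBSI = beta * (S - <S_J>). With J = 2*SW and
# beta = 2 the index is bounded by 1. Trials are independent: counts and
# probability masses are pooled across trials, never matched across trial
# boundaries.

#' JBSI parameters
#'
#' @param sw_ms Synchrony window, ms (> 0).
#' @param j_ms Jitter half-range, ms; default `2 * sw_ms`.
#' @param beta Normalization factor (default 2).
#' @param lag_ms Virtual lag applied to the jittered train, ms (signed;
#'   positive shifts it later).
#' @return A list of class `jbsi_params`.
#' @export
jbsi_params <- function(sw_ms, j_ms = 2 * sw_ms, beta = 2, lag_ms = 0) {
  if (sw_ms <= 0) stop("synchrony window must be positive", call. = FALSE)
  if (j_ms <= 0) stop("jitter range must be positive", call. = FALSE)
  structure(list(sw_ms = sw_ms, j_ms = j_ms, beta = beta, lag_ms = lag_ms),
            class = "jbsi_params")
}

# Total length of (union of [b - sw, b + sw]) intersected with [lo, hi],
# with overlapping target windows merged (measured as a set).
.union_overlap <- function(b, sw, lo, hi) {
  if (!length(b)) return(0)
  b <- sort(b)
  starts <- b - sw; ends <- b + sw
  # merge overlapping/adjacent windows
  m_start <- starts[1]; m_end <- ends[1]; total <- 0
  for (i in seq_along(b)[-1]) {
    if (starts[i] <= m_end) {
      m_end <- max(m_end, ends[i])
    } else {
      total <- total + max(0, min(m_end, hi) - max(m_start, lo))
      m_start <- starts[i]; m_end <- ends[i]
    }
  }
  total + max(0, min(m_end, hi) - max(m_start, lo))
}

# Choose which train is jittered: the one with fewer total spikes; on a
# tie, the first argument.
.jbsi_pick <- function(train_a, train_b) {
  na <- sum(lengths(train_a)); nb <- sum(lengths(train_b))
  if (nb < na) list(a = train_b, b = train_a) else list(a = train_a, b = train_b)
}

# Per-trial observed synchrony count and summed analytic chance mass for
# jittered train a against reference train b.
.jbsi_trial <- function(a, b, sw, j, lag) {
  a <- a + lag
  if (!length(a)) return(c(0, 0, 0))
  if (!length(b)) return(c(0, 0, length(a)))
  sync <- vapply(a, function(ai) min(abs(ai - b)) <= sw, logical(1))
  p <- vapply(a, function(ai) .union_overlap(b, sw, ai - j, ai + j) / (2 * j),
              numeric(1))
  c(sum(sync), sum(p), length(a))
}

#' Jitter-Based Synchrony Index of two trial-aligned spike trains
#'
#' @param train_a,train_b Lists of per-trial spike-time vectors (ms), equal
#'   trial counts. The train with fewer total spikes is the jittered one
#'   (ties: `train_a`).
#' @param params A [jbsi_params()].
#' @return The JBSI (a single number in [-beta/2, 1] for the default
#'   parameters), or `NA` with a warning if either train is empty.
#' @export
jbsi <- function(train_a, train_b, params) {
  stopifnot(inherits(params, "jbsi_params"))
  if (length(train_a) != length(train_b))
    stop("trains must have matching trial counts", call. = FALSE)
  if (!sum(lengths(train_a)) || !sum(lengths(train_b))) {
    warning("empty spike train; JBSI undefined")
    return(NA_real_)
  }
  pick <- .jbsi_pick(train_a, train_b)
  acc <- Reduce(`+`, Map(.jbsi_trial, pick$a, pick$b,
                         MoreArgs = list(sw = params$sw_ms, j = params$j_ms,
                                         lag = params$lag_ms)))
  s_obs <- acc[1] / acc[3]
  s_chance <- acc[2] / acc[3]
  params$beta * (s_obs - s_chance)
}

#' Monte-Carlo estimate of chance synchrony
#'
#' Validation oracle for the analytic chance term: mean observed synchrony
#' over `n_reps` realizations of independent uniform jitter on [-J, +J]
#' applied to each spike of the jittered train.
#'
#' @inheritParams jbsi
#' @param n_reps Number of jitter realizations (>= 100).
#' @param seed Integer seed.
#' @return Mean synchrony fraction under jitter.
#' @export
chance_synchrony_mc <- function(train_a, train_b, params, n_reps = 1000,
                                seed = 1) {
  stopifnot(inherits(params, "jbsi_params"))
  if (n_reps < 100) stop("n_reps must be >= 100", call. = FALSE)
  if (!sum(lengths(train_a)) || !sum(lengths(train_b))) {
    warning("empty spike train; chance synchrony undefined")
    return(NA_real_)
  }
  pick <- .jbsi_pick(train_a, train_b)
  sw <- params$sw_ms; j <- params$j_ms; lag <- params$lag_ms
  .with_seed(seed, {
    fracs <- vapply(seq_len(n_reps), function(r) {
      acc <- c(0, 0)
      for (k in seq_along(pick$a)) {
        a <- pick$a[[k]] + lag
        b <- pick$b[[k]]
        if (!length(a)) next
        if (length(b)) {
          aj <- a + stats::runif(length(a), -j, j)
          acc[1] <- acc[1] + sum(vapply(aj, function(ai)
            min(abs(ai - b)) <= sw, logical(1)))
        }
        acc[2] <- acc[2] + length(a)
      }
      acc[1] / acc[2]
    }, numeric(1))
    mean(fracs)
  })
}

#' JBSI over a synchrony-window x virtual-lag grid
#'
#' @param train_a,train_b As in [jbsi()].
#' @param sw_grid_ms,lag_grid_ms Grids (default 0.1-1.0 ms and -1...+1 ms in
#'   0.1 ms steps).
#' @param beta Normalization factor.
#' @return An object of class `jbsi_matrix`: `values` (SW x lag), the
#'   grids, and `precision_ms` / `lag_at_precision_ms` from
#'   [precision_and_lag()].
#' @export
jbsi_matrix <- function(train_a, train_b,
                        sw_grid_ms = seq(0.1, 1.0, by = 0.1),
                        lag_grid_ms = seq(-1.0, 1.0, by = 0.1),
                        beta = 2) {
  if (!length(sw_grid_ms) || !length(lag_grid_ms))
    stop("grids must be nonempty", call. = FALSE)
  vals <- matrix(NA_real_, length(sw_grid_ms), length(lag_grid_ms),
                 dimnames = list(sprintf("sw_%.1f", sw_grid_ms),
                                 sprintf("lag_%+.1f", lag_grid_ms)))
  for (i in seq_along(sw_grid_ms))
    for (k in seq_along(lag_grid_ms))
      vals[i, k] <- tryCatch(
        jbsi(train_a, train_b,
             jbsi_params(sw_grid_ms[i], lag_ms = lag_grid_ms[k],
                         beta = beta)),
        warning = function(w) NA_real_)
  m <- structure(list(sw_grid_ms = sw_grid_ms, lag_grid_ms = lag_grid_ms,
                      values = vals, precision_ms = NA_real_,
                      lag_at_precision_ms = NA_real_),
                 class = "jbsi_matrix")
  pl <- precision_and_lag(m)
  m$precision_ms <- pl$precision_ms
  m$lag_at_precision_ms <- pl$lag_ms
  m
}

#' Pairwise precision and lag from a JBSI matrix
#'
#' Pairwise precision is the smallest synchrony window whose row maximum
#' (over virtual lags) exceeds 0.5; pairwise lag is the virtual lag
#' maximizing the JBSI along that row. Undefined (NA) when no row
#' qualifies.
#'
#' @param m A `jbsi_matrix`.
#' @param threshold JBSI level defining precision (default 0.5).
#' @return List with `precision_ms` and `lag_ms` (NA when undefined).
#' @export
precision_and_lag <- function(m, threshold = 0.5) {
  stopifnot(inherits(m, "jbsi_matrix"))
  row_max <- suppressWarnings(apply(m$values, 1L, max, na.rm = TRUE))
  qual <- which(is.finite(row_max) & row_max > threshold)
  if (!length(qual))
    return(list(precision_ms = NA_real_, lag_ms = NA_real_))
  i <- qual[1]
  row <- m$values[i, ]
  ks <- which(row >= max(row, na.rm = TRUE) - 1e-12)
  k <- ks[which.min(abs(m$lag_grid_ms[ks]))] # ties resolve to smallest lag
  list(precision_ms = m$sw_grid_ms[i], lag_ms = m$lag_grid_ms[k])
}

#' @export
print.jbsi_matrix <- function(x, ...) {
  cat(sprintf("<jbsi_matrix> %d SW x %d lag values; precision %s ms, lag %s ms\n",
              length(x$sw_grid_ms), length(x$lag_grid_ms),
              format(x$precision_ms), format(x$lag_at_precision_ms)))
  invisible(x)
}
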