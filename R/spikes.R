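# Spike detection, order assignment across trials, burst statistics,
# step-family electrophysiological characterization and FS/RS
# classification.

#' Detect spike peak times in a current-clamp trace
#'
#' Local maxima exceeding the detection level, separated by a refractory
#' distance (closer candidates are merged into the larger peak, with a
#' warning). Peak times are localized to sub-sample precision by parabolic
#' interpolation and reported in ms from sweep start.
#'
#' @param t A current-clamp [trace()].
#' @param detect_mv Detection level, mV (default 0: spike peaks overshoot).
#' @param min_sep_ms Minimum peak separation, ms.
#' @return Numeric vector of spike peak times (ms), possibly empty.
#' @export
detect_spikes <- function(t, detect_mv = 0, min_sep_ms = 0.8) {
  stopifnot(inherits(t, "trace"))
  if (t$kind != "current_clamp")
    stop("spike detection expects a current_clamp trace", call. = FALSE)
  sep <- max(1L, round(min_sep_ms * t$rate_hz / 1000))
  raw <- .local_maxima(t$samples, threshold = detect_mv, min_sep = 1L)
  idx <- .local_maxima(t$samples, threshold = detect_mv, min_sep = sep)
  if (length(raw) > length(idx))
    warning(sprintf("%d candidate peak(s) within the %g ms refractory distance were merged",
                    length(raw) - length(idx), min_sep_ms))
  vapply(idx, function(i) .interp_time_ms(t$samples, i, t$rate_hz), numeric(1))
}

#' Detect spikes across all sweeps of a current-clamp set
#'
#' Convenience wrapper returning a spike-train set with times measured from
#' light onset.
#'
#' @param s A current-clamp [sweep_set()].
#' @param ... Passed to [detect_spikes()].
#' @return A `spike_train_set`: list with `trains` (per-trial sorted times,
#'   ms from light onset), `orders` (NA until assigned), `n_trials`.
#' @export
detect_spike_trains <- function(s, ...) {
  stopifnot(inherits(s, "sweep_set"))
  trains <- lapply(s$sweeps, function(tr)
    detect_spikes(tr, ...) - s$protocol$onset_ms)
  spike_train_set(trains)
}

#' Construct a spike-train set
#'
#' @param trains List of per-trial spike time vectors (ms), each strictly
#'   increasing.
#' @param orders Optional list of per-trial integer orders (NA =
#'   unassigned).
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, orders = NULL) {
  stopifnot(is.list(trains))
  for (tr in trains)
    if (length(tr) > 1 && is.unsorted(tr, strictly = TRUE))
      stop("spike times must be strictly increasing within a trial",
           call. = FALSE)
  if (is.null(orders))
    orders <- lapply(trains, function(tr) rep(NA_integer_, length(tr)))
  structure(list(trains = trains, orders = orders,
                 n_trials = length(trains)),
            class = "spike_train_set")
}

#' Assign spike orders across trials
#'
#' Builds a burst template from the trials with the modal spike count
#' (per-order median times), assigns every spike to the nearest template
#' order within `tol_ms` (ties broken by proximity; at most one spike per
#' order per trial, keeping the closer one), re-estimates the template once
#' from the assignments, and re-assigns.
#'
#' @param s A `spike_train_set`.
#' @param tol_ms Assignment tolerance, ms.
#' @return The spike-train set with `orders` filled (NA = unassigned) and a
#'   `template` attribute of per-order median times.
#' @export
assign_spike_orders <- function(s, tol_ms = 0.8) {
  stopifnot(inherits(s, "spike_train_set"))
  if (s$n_trials < 3L)
    stop("order assignment needs at least three trials", call. = FALSE)
  counts <- lengths(s$trains)
  pos_counts <- counts[counts > 0]
  if (!length(pos_counts))
    stop("no spikes in any trial", call. = FALSE)
  tab <- table(pos_counts)
  modal <- as.integer(names(tab)[which.max(tab)])
  modal_trials <- which(counts == modal)
  if (length(modal_trials) < 2L)
    stop("no group of >= 2 trials shares the modal spike count",
         call. = FALSE)
  template <- apply(do.call(rbind, s$trains[modal_trials]), 2L, stats::median)

  assign_once <- function(template) {
    lapply(s$trains, function(tr) {
      ord <- rep(NA_integer_, length(tr))
      if (!length(tr)) return(ord)
      for (j in seq_along(template)) {
        d <- abs(tr - template[j])
        d[!is.na(ord)] <- Inf
        i <- which.min(d)
        if (length(i) && d[i] <= tol_ms) ord[i] <- j
      }
      ord
    })
  }
  orders <- assign_once(template)
  # one re-estimation pass from all assigned spikes
  template2 <- vapply(seq_along(template), function(j) {
    v <- unlist(Map(function(tr, o) tr[which(o == j)], s$trains, orders))
    if (length(v)) stats::median(v) else template[j]
  }, numeric(1))
  orders <- assign_once(template2)
  out <- spike_train_set(s$trains, orders)
  attr(out, "template") <- template2
  out
}

#' Per-order burst statistics
#'
#' For each spike order: mean latency (ms from light onset), trial-to-trial
#' jitter (SD of peak times, microseconds; n-1 denominator, computed only
#' over trials where the order fired), coefficient of variation
#' (jitter/mean, percent), and reliability (fraction of trials firing that
#' order). ISIs are differences of consecutive order means; burst frequency
#' is the reciprocal of the mean ISI; spikes/stimulus is the mean number of
#' assigned spikes per trial.
#'
#' @param s A `spike_train_set` with orders assigned.
#' @return An object of class `burst_stats`: data.frame `per_order`
#'   (columns order, mean_ms, jitter_us, cv_pct, reliability, n), plus
#'   `isis_ms`, `burst_frequency_hz`, `spikes_per_stimulus`.
#' @export
burst_stats <- function(s) {
  stopifnot(inherits(s, "spike_train_set"))
  if (all(vapply(s$orders, function(o) all(is.na(o)), logical(1))))
    stop("orders are not assigned; run assign_spike_orders first",
         call. = FALSE)
  ords <- sort(unique(stats::na.omit(unlist(s$orders))))
  per <- lapply(ords, function(j) {
    v <- unlist(Map(function(tr, o) tr[which(o == j)], s$trains, s$orders))
    jit <- if (length(v) >= 2) stats::sd(v) * 1000 else NA_real_
    m <- mean(v)
    data.frame(order = j, mean_ms = m, jitter_us = jit,
               cv_pct = if (is.na(jit)) NA_real_ else jit / 1000 / m * 100,
               reliability = length(v) / s$n_trials, n = length(v))
  })
  per <- do.call(rbind, per)
  isis <- diff(per$mean_ms)
  structure(
    list(per_order = per, isis_ms = isis,
         burst_frequency_hz = if (length(isis)) 1000 / mean(isis) else NA_real_,
         spikes_per_stimulus = mean(vapply(s$orders, function(o)
           sum(!is.na(o)), numeric(1)))),
    class = "burst_stats")
}

#' @export
print.burst_stats <- function(x, ...) {
  cat(sprintf("<burst_stats> %.2f spikes/stimulus, burst frequency %.1f Hz\n",
              x$spikes_per_stimulus, x$burst_frequency_hz))
  print(x$per_order, row.names = FALSE)
  invisible(x)
}

#' Extract the eight-parameter electrophysiological profile of a cell
#'
#' Works from a standardized family of 600-ms current steps. Definitions:
#' resting potential = pre-step baseline mean; spike threshold = voltage at
#' the first point on the rheobase spike where dV/dt reaches 5 V/s; spike
#' height = peak - threshold; width at half-height between threshold and
#' peak; AHP = threshold - post-spike trough; input resistance =
#' least-squares slope of steady-state dV vs injected current over
#' subthreshold steps with |dV| <= 15 mV; Imax = largest step before the
#' first-spike height drops more than 10% below its rheobase value; Fmax =
#' reciprocal of the mean of the last five ISIs at Imax.
#'
#' @param s A current-clamp [sweep_set()] whose `labels$currents_pa` gives
#'   the per-sweep step current (pA), or `currents_pa` passed explicitly.
#' @param currents_pa Per-sweep current amplitudes (pA).
#' @param step_window_ms `c(start, end)` of the step within the sweep, ms.
#' @return An object of class `ephys_params` (fields v_rest_mv,
#'   v_threshold_mv, spike_height_mv, swhh_ms, ahp_mv, r_in_mohm, i_max_pa,
#'   f_max_hz, flag).
#' @export
extract_ephys_params <- function(s, currents_pa = NULL,
                                 step_window_ms = c(100, 700)) {
  stopifnot(inherits(s, "sweep_set"))
  if (is.null(currents_pa)) currents_pa <- s$labels$currents_pa
  if (is.null(currents_pa) || length(currents_pa) != length(s$sweeps))
    stop("need one current amplitude per sweep", call. = FALSE)
  rate <- s$sweeps[[1]]$rate_hz
  t_ms <- trace_times_ms(s$sweeps[[1]])
  pre <- t_ms < step_window_ms[1] - 5
  late <- t_ms >= mean(step_window_ms) & t_ms < step_window_ms[2] # last 50%
  spikes <- lapply(s$sweeps, detect_spikes)
  n_spk <- lengths(spikes)

  if (!any(n_spk > 0))
    return(structure(list(flag = "non_spiking"), class = "ephys_params"))

  v_rest <- mean(vapply(s$sweeps[currents_pa == 0 | abs(currents_pa) ==
                                   min(abs(currents_pa))],
                        function(tr) mean(tr$samples[pre]), numeric(1)))

  # input resistance from subthreshold steps
  sub <- which(n_spk == 0 & currents_pa != 0)
  dv <- vapply(s$sweeps[sub], function(tr)
    mean(tr$samples[late]) - mean(tr$samples[pre]), numeric(1))
  keep <- abs(dv) <= 15
  r_in <- if (sum(keep) >= 2) {
    unname(stats::coef(stats::lm(dv[keep] ~ currents_pa[sub][keep]))[2]) * 1000
  } else NA_real_

  # rheobase sweep: smallest positive current evoking >= 1 spike
  supra <- which(n_spk > 0 & currents_pa > 0)
  rheo <- supra[which.min(currents_pa[supra])]
  spike_feats <- function(sweep_i) {
    tr <- s$sweeps[[sweep_i]]
    pk_ms <- spikes[[sweep_i]][1]
    i_pk <- round(pk_ms * rate / 1000) + 1L
    dvdt <- c(0, diff(tr$samples)) * rate / 1000 # mV/ms = V/s
    seg <- max(1L, i_pk - round(3 * rate / 1000)):i_pk
    cross <- seg[which(dvdt[seg] >= 5)]
    if (!length(cross)) return(NULL)
    i_th <- cross[1]
    v_th <- tr$samples[i_th]
    v_pk <- max(tr$samples[seg])
    half <- v_th + (v_pk - v_th) / 2
    above <- which(tr$samples >= half)
    above <- above[above >= i_th & above <= i_pk + round(3 * rate / 1000)]
    swhh <- if (length(above)) (max(above) - min(above) + 1) / rate * 1000 else NA_real_
    post <- i_pk:min(length(tr$samples), i_pk + round(5 * rate / 1000))
    ahp <- v_th - min(tr$samples[post])
    list(v_th = v_th, height = v_pk - v_th, swhh = swhh, ahp = ahp)
  }
  rf <- spike_feats(rheo)
  if (is.null(rf))
    stop("dV/dt never reaches 5 V/s on the rheobase spike; threshold undefined",
         call. = FALSE)

  # Imax: largest step before first-spike height drops >10% below rheobase
  supra_sorted <- supra[order(currents_pa[supra])]
  i_max <- currents_pa[rheo]
  i_max_sweep <- rheo
  for (k in supra_sorted) {
    f <- spike_feats(k)
    if (is.null(f) || f$height < 0.9 * rf$height) break
    i_max <- currents_pa[k]; i_max_sweep <- k
  }
  st <- spikes[[i_max_sweep]]
  f_max <- if (length(st) >= 6) {
    isis <- diff(st)
    1000 / mean(utils::tail(isis, 5))
  } else NA_real_

  structure(list(v_rest_mv = v_rest, v_threshold_mv = rf$v_th,
                 spike_height_mv = rf$height, swhh_ms = rf$swhh,
                 ahp_mv = rf$ahp, r_in_mohm = r_in, i_max_pa = i_max,
                 f_max_hz = f_max, flag = "ok"),
            class = "ephys_params")
}

#' Classify a cell as fast-spiking or regular-spiking
#'
#' FS: maximal steady-state rate >= 150 Hz and narrow spikes
#' (half-height width <= 0.5 ms). RS: steady-state rate < 100 Hz and wide
#' spikes (> 0.5 ms). Cells in the gap are left unclassified.
#'
#' @param p An `ephys_params` object (or list with `f_max_hz`, `swhh_ms`).
#' @return `"FS"`, `"RS"` or `"unclassified"`.
#' @export
classify_cell <- function(p) {
  f <- p$f_max_hz; w <- p$swhh_ms
  if (is.null(f) || is.null(w) || is.na(f) || is.na(w)) return("unclassified")
  if (f >= 150 && w <= 0.5) return("FS")
  if (f < 100 && w > 0.5) return("RS")
  "unclassified"
}

#' Electrical coupling coefficient between a driver and a follower cell
#'
#' 100 x (steady-state voltage deflection in the follower) / (deflection in
#' the driver) during a hyperpolarizing step injected into the driver.
#' Steady state is the mean over the last half of the step window minus the
#' pre-step baseline.
#'
#' @param pre_step Driver-cell current-clamp [trace()].
#' @param post_response Follower-cell current-clamp [trace()].
#' @param step_window_ms `c(start, end)` of the step, ms.
#' @return Coupling coefficient, percent.
#' @export
coupling_coefficient <- function(pre_step, post_response,
                                 step_window_ms = c(100, 700)) {
  .check_same_shape(pre_step, post_response)
  if (pre_step$kind != "current_clamp" || post_response$kind != "current_clamp")
    stop("coupling test expects current_clamp traces", call. = FALSE)
  t_ms <- trace_times_ms(pre_step)
  pre <- t_ms < step_window_ms[1] - 5
  late <- t_ms >= mean(step_window_ms) & t_ms < step_window_ms[2]
  dv_pre <- mean(pre_step$samples[late]) - mean(pre_step$samples[pre])
  dv_post <- mean(post_response$samples[late]) - mean(post_response$samples[pre])
  if (abs(dv_pre) < 1)
    stop("driver deflection below 1 mV; coupling coefficient undefined",
         call. = FALSE)
  100 * dv_post / dv_pre
}
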