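# Distribution-free tests used throughout the analyses: a two-tailed
# Monte-Carlo permutation test and the exact two-sided sign test.

#' Two-tailed Monte-Carlo permutation test
#'
#' Permutes group labels `n_perm` times and reports the fraction of
#' permutations whose |statistic| is at least the observed |statistic|
#' (two tails pooled via the absolute value; the observed arrangement is
#' not counted among the permutations). When no permutation is as extreme,
#' the p-value is reported as a bound (`p < 1/n_perm`, e.g. p < 0.0001 at
#' 10,000 permutations) with `is_bound = TRUE`.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param statistic Function of two samples; default difference of means.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list of class `test_result`: `p_value`, `is_bound`,
#'   `statistic`, `n_permutations`.
#' @export
permutation_test <- function(x, y, statistic = function(a, b) mean(a) - mean(b),
                             n_perm = 10000, seed = 1) {
  if (!length(x) || !length(y))
    stop("both groups must be nonempty", call. = FALSE)
  obs <- statistic(x, y)
  pooled <- c(x, y)
  nx <- length(x)
  .with_seed(seed, {
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), nx)
      if (abs(statistic(pooled[idx], pooled[-idx])) >= abs(obs))
        exceed <- exceed + 1L
    }
    if (exceed == 0L)
      structure(list(p_value = 1 / n_perm, is_bound = TRUE, statistic = obs,
                     n_permutations = n_perm), class = "test_result")
    else
      structure(list(p_value = exceed / n_perm, is_bound = FALSE,
                     statistic = obs, n_permutations = n_perm),
                class = "test_result")
  })
}

#' Exact two-sided sign test
#'
#' `p = 2 * P(X <= min(n_pos, n_neg))` under Binomial(n, 1/2), capped at 1.
#' Ties are excluded upstream.
#'
#' @param n_positive,n_negative Counts of positive and negative
#'   differences (sum >= 1).
#' @return A `test_result` with `p_value` and `statistic` (= n_positive).
#' @export
sign_test <- function(n_positive, n_negative) {
  n <- n_positive + n_negative
  if (n < 1) stop("need at least one non-tied observation", call. = FALSE)
  p <- min(1, 2 * stats::pbinom(min(n_positive, n_negative), n, 0.5))
  structure(list(p_value = p, is_bound = FALSE, statistic = n_positive,
                 n_permutations = NA_integer_), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> statistic %.4g, p %s%.4g\n", x$statistic,
              if (x$is_bound) "< " else "= ", x$p_value))
  invisible(x)
}
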