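#' Pointwise paired t statistics for two time-series conditions
#'
#' Computes the paired t statistic `mean(d) / (sd(d)/sqrt(n))` at every time
#' point, where `d` is the participant-wise difference between conditions.
#' A time point with zero variance of the differences yields `+/-Inf` (sign
#' of the mean difference) rather than `NaN`; an all-zero difference yields
#' 0.
#'
#' @param a,b numeric matrices, participants x time, paired by row.
#' @return Numeric vector of t statistics, one per time point.
#' @export
pointwise_paired_t <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("conditions must share participants and time base")
  n <- nrow(a)
  if (n < 2) stop("need at least 2 participants")
  d <- a - b
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  t <- ifelse(se == 0, ifelse(m == 0, 0, sign(m) * Inf), m / se)
  t
}

# t statistics for all sign-flip assignments in `signs` (iterations x n)
# applied to difference matrix d (n x T); exploits the fact that flipping
# signs leaves sum(d^2) unchanged.
flip_t_matrix <- function(d, signs) {
  n <- nrow(d)
  ss <- colSums(d^2)
  m <- (signs %*% d) / n
  v <- sweep(-n * m^2, 2, ss, "+") / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  t <- m / se
  t[se == 0] <- ifelse(m[se == 0] == 0, 0, sign(m[se == 0]) * Inf)
  t
}

#' Sign-flip permutation null for a paired time-series contrast
#'
#' Builds the permutation null by randomly flipping each participant's
#' condition labels (equivalently, the sign of the paired difference) and
#' recomputing the pointwise paired t statistics; the default 2000
#' iterations match the procedure this package emulates. P-values are
#' two-sided with add-one smoothing:
#' `p = (# null |t| >= |t_obs| + 1) / (n_iter + 1)`. With `exhaustive =
#' TRUE` all `2^n` sign patterns are enumerated instead (p is then the exact
#' proportion of the full enumeration).
#'
#' @param a,b participants x time matrices, paired by row.
#' @param n_iter Monte-Carlo iterations.
#' @param seed integer seed.
#' @param exhaustive enumerate all sign flips (n <= 20 enforced).
#' @param keep_null retain the null t matrix in the result.
#' @return An object of class `permutation_result`: `t_observed`,
#'   `p_values`, `n_iterations`, optionally `null_distribution`.
#' @export
permutation_null <- function(a, b, n_iter = 2000, seed = 1L,
                             exhaustive = FALSE, keep_null = FALSE) {
  if (!exhaustive && n_iter < 1) stop("n_iter must be >= 1")
  n <- nrow(a)
  d <- a - b
  t_obs <- pointwise_paired_t(a, b)
  # comparison threshold backed off by one part in 10^10 so the identity
  # sign pattern always counts as >= despite summation-order rounding
  t_ref <- abs(t_obs) * (1 - 1e-10)
  if (exhaustive) {
    if (n > 20) stop("exhaustive enumeration limited to n <= 20 participants")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_null <- flip_t_matrix(d, signs)
    p <- colMeans(sweep(abs(t_null), 2, t_ref, ">="))
    n_it <- nrow(signs)
  } else {
    signs <- with_seed(seed,
      matrix(sample(c(-1, 1), n_iter * n, replace = TRUE), n_iter, n))
    t_null <- flip_t_matrix(d, signs)
    exceed <- colSums(sweep(abs(t_null), 2, t_ref, ">="))
    p <- (exceed + 1) / (n_iter + 1)
    n_it <- n_iter
  }
  structure(list(t_observed = t_obs, p_values = p, n_iterations = n_it,
                 null_distribution = if (keep_null) t_null else NULL,
                 exhaustive = exhaustive),
            class = "permutation_result")
}

#' Significant runs under the run-length criterion
#'
#' Finds maximal runs of consecutive time points with `p < alpha` and keeps
#' those at least `min_run` samples long (the emulated criterion: p below
#' 0.05 for a minimum of 15 consecutive samples).
#'
#' @param p_values numeric p-value series.
#' @param alpha pointwise threshold.
#' @param min_run minimum run length in samples.
#' @param rate sampling rate, Hz; with `time_origin` it converts run
#'   boundaries to seconds.
#' @param time_origin time of the first sample, s.
#' @return Data frame with `start`, `end` (sample indices), `length`, and,
#'   when `rate` is given, `start_s`, `end_s`.
#' @export
significant_runs <- function(p_values, alpha = 0.05, min_run = 15,
                             rate = NULL, time_origin = 0) {
  runs <- mask_runs(p_values < alpha)
  if (nrow(runs)) {
    runs$length <- runs$end - runs$start + 1
    runs <- runs[runs$length >= min_run, , drop = FALSE]
  } else runs$length <- integer(0)
  rownames(runs) <- NULL
  if (!is.null(rate) && nrow(runs)) {
    runs$start_s <- time_origin + (runs$start - 1) / rate
    runs$end_s <- time_origin + (runs$end - 1) / rate
  }
  runs
}

#' Windowed percentile permutation test
#'
#' Restricts a paired contrast to a time window (half-open, `[start, end)`
#' in seconds) and flags a time point as significant when the observed |t|
#' exceeds the 95th percentile (more generally the `1 - alpha` quantile) of
#' its own sign-flip null distribution of |t|.
#'
#' @param a,b participants x time matrices.
#' @param time time vector (s) for the columns.
#' @param window length-2 numeric, window in seconds, `[start, end)`.
#' @param n_iter Monte-Carlo iterations.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return An object of class `permutation_result` with `significant`
#'   (logical per in-window time point), `window_index` (column indices
#'   analyzed), `t_observed`, `threshold` (per-point null quantile).
#' @export
windowed_percentile_test <- function(a, b, time, window, n_iter = 2000,
                                     alpha = 0.05, seed = 1L) {
  idx <- which(time >= window[1] & time < window[2])
  if (length(idx) == 0) stop("empty analysis window")
  aw <- a[, idx, drop = FALSE]
  bw <- b[, idx, drop = FALSE]
  n <- nrow(aw)
  d <- aw - bw
  t_obs <- pointwise_paired_t(aw, bw)
  signs <- with_seed(seed,
    matrix(sample(c(-1, 1), n_iter * n, replace = TRUE), n_iter, n))
  t_null <- abs(flip_t_matrix(d, signs))
  thresh <- apply(t_null, 2, stats::quantile, probs = 1 - alpha, names = FALSE,
                  type = 7)
  structure(list(t_observed = t_obs, threshold = thresh,
                 significant = abs(t_obs) > thresh,
                 window_index = idx, time = time[idx],
                 n_iterations = n_iter, alpha = alpha),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %d time points, %d iterations%s\n",
              length(x$t_observed), x$n_iterations,
              if (isTRUE(x$exhaustive)) " (exhaustive)" else ""))
  if (!is.null(x$p_values))
    cat(sprintf("  p < 0.05 at %d points\n", sum(x$p_values < 0.05)))
  if (!is.null(x$significant))
    cat(sprintf("  significant at %d of %d window points\n",
                sum(x$significant), length(x$significant)))
  invisible(x)
}
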