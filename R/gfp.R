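# Global field power and paired permutation statistics.

#' Global field power of an evoked response
#'
#' GFP(t) is the spatial standard deviation across sensors at each time
#' point: `sqrt(mean((x_i(t) - xbar(t))^2))` over the K channels. It is
#' reference-free and nonnegative, and used here as the overall response
#' strength across MEG-like sensors.
#'
#' @param ev an `erp_evoked` (or any channels x samples matrix via `$data`).
#' @return A `gfp_series`: list with `gfp` (numeric vector), `times` (ms),
#'   `srate`, `condition`.
#' @export
global_field_power <- function(ev) {
  x <- if (is.matrix(ev)) ev else ev$data
  check_that(nrow(x) >= 2, "GFP requires at least two channels")
  mu <- colMeans(x)
  gfp <- sqrt(colMeans(x^2) - mu^2)
  gfp[gfp < 0 | is.nan(gfp)] <- 0  # guard tiny negative rounding
  structure(list(gfp = gfp,
                 times = if (is.matrix(ev)) NULL else ev$times,
                 srate = if (is.matrix(ev)) NULL else ev$srate,
                 condition = if (is.matrix(ev)) NULL else ev$condition),
            class = "gfp_series")
}

#' Paired sign-flip permutation T test (internal engine)
#'
#' Given a subjects x points matrix of paired condition differences, computes
#' the paired T statistic per point and a permutation null by randomly
#' sign-flipping each subject's whole difference vector (`n_perm` fresh
#' draws). The sum of squared differences is flip-invariant, so the null T
#' values are computed from flipped means alone. Zero-variance points with
#' zero mean yield T = 0, p = 1.
#'
#' @return list(t_obs, p) with one entry per column of `d`.
#' @noRd
signflip_t_test <- function(d, n_perm = 1000, seed = NULL) {
  n <- nrow(d)
  ss <- colSums(d^2)
  t_from_mean <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    v[v < 0] <- 0
    se <- sqrt(v / n)
    tt <- ifelse(se > 0, m / se, ifelse(abs(m) > 0, Inf * sign(m), 0))
    tt
  }
  m_obs <- colMeans(d)
  t_obs <- t_from_mean(m_obs)
  flips <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                  n_perm, n))
  m_perm <- (flips %*% d) / n                   # n_perm x points
  v_perm <- sweep(-n * m_perm^2, 2, ss, `+`) / (n - 1)
  v_perm[v_perm < 0] <- 0
  t_perm <- ifelse(sqrt(v_perm / n) > 0, m_perm / sqrt(v_perm / n),
                   ifelse(abs(m_perm) > 0, Inf, 0))
  exceed <- colSums(abs(t_perm) >= matrix(abs(t_obs), n_perm, ncol(d), byrow = TRUE))
  list(t_obs = t_obs, p = exceed / n_perm)
}

#' Pointwise permutation test for a significant GFP interval
#'
#' For each time point, a paired T statistic compares the two conditions
#' across subjects; the null distribution is built by randomly swapping the
#' condition labels within subjects (sign flips of the paired differences).
#' Significant intervals are maximal runs of pointwise `p < alpha` lasting at
#' least `min_run` ms, suppressing isolated false positives.
#'
#' @param gfp_cong,gfp_incong subjects x timepoints matrices of paired GFP
#'   series (row i of both matrices belongs to subject i).
#' @param times ms time axis (one entry per column).
#' @param n_perm number of permutation draws (default 1000; < 100 warns).
#' @param alpha pointwise significance level (default 0.05).
#' @param min_run minimal interval duration in ms (default 30).
#' @param seed integer seed for the permutation draws.
#' @return An `interval_test_result`: pointwise `p` and `t_obs`, a
#'   data.frame `intervals` (`start_ms`, `end_ms`), and the test settings.
#' @export
permutation_interval_test <- function(gfp_cong, gfp_incong, times,
                                      n_perm = 1000, alpha = 0.05,
                                      min_run = 30, seed = 1L) {
  check_that(identical(dim(gfp_cong), dim(gfp_incong)),
             "unpaired input: condition matrices differ in shape")
  check_that(nrow(gfp_cong) >= 5, "at least 5 subjects required")
  check_that(length(times) == ncol(gfp_cong), "times must match the column count")
  if (n_perm < 100) warning("n_perm < 100 gives unstable p-values")
  d <- gfp_incong - gfp_cong
  res <- signflip_t_test(d, n_perm, seed)
  sig <- res$p < alpha
  runs <- logical_runs(sig)
  if (nrow(runs) > 0) {
    dur <- times[runs$end] - times[runs$start]
    runs <- runs[dur >= min_run, , drop = FALSE]
  }
  intervals <- data.frame(start_ms = times[runs$start], end_ms = times[runs$end])
  structure(list(p = res$p, t_obs = res$t_obs, times = times,
                 intervals = intervals, n_perm = n_perm, alpha = alpha,
                 min_run = min_run, seed = seed),
            class = "interval_test_result")
}

#' @export
print.interval_test_result <- function(x, ...) {
  cat(sprintf("<interval_test_result> %d permutations, alpha = %g, min run %g ms\n",
              x$n_perm, x$alpha, x$min_run))
  if (nrow(x$intervals) == 0) cat("  no significant intervals\n")
  else for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  significant: %g..%g ms\n", x$intervals$start_ms[i], x$intervals$end_ms[i]))
  invisible(x)
}

#' Paired t test on per-subject window means
#'
#' Classical paired t test comparing per-subject scalar summaries (window-mean
#' GFP or ERP amplitude) between conditions, with the per-condition
#' mean +- SEM summary used for group-level reporting.
#'
#' @param cong,incong numeric vectors of per-subject window means (paired by
#'   position).
#' @return List with `t`, `df`, `p` (two-sided), per-condition `means` and
#'   `sem`, the paired `diffs`, and `degenerate = TRUE` in place of an
#'   infinite statistic when the differences have zero variance.
#' @export
window_mean_test <- function(cong, incong) {
  check_that(length(cong) == length(incong), "unpaired input")
  check_that(length(cong) >= 3, "at least 3 subjects required")
  diffs <- incong - cong
  sem <- function(x) sd(x) / sqrt(length(x))
  out <- list(means = c(congruent = mean(cong), incongruent = mean(incong)),
              sem = c(congruent = sem(cong), incongruent = sem(incong)),
              diffs = diffs, n = length(cong), degenerate = FALSE)
  if (sd(diffs) == 0) {
    out$degenerate <- TRUE
    out$t <- if (mean(diffs) == 0) 0 else NA_real_
    out$df <- length(diffs) - 1L
    out$p <- if (mean(diffs) == 0) 1 else NA_real_
    return(out)
  }
  tt <- t.test(incong, cong, paired = TRUE)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p <- tt$p.value
  out
}
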