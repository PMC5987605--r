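# Morlet wavelet time-frequency decomposition and permutation statistics.

#' Time-frequency analysis configuration
#'
#' @param freqs frequency grid in Hz (default 1..45 in 1 Hz steps; a 6-cycle
#'   wavelet below 1 Hz would need more support than a 1.1 s epoch offers, so
#'   the grid starts at 1 Hz even when the broadband filter passes 0.5 Hz).
#' @param n_cycles wavelet cycles (default 6); the wavelet's temporal sigma is
#'   `n_cycles / (2 pi f)`.
#' @param analysis_window ms window of the epochs (default -200..900).
#' @param baseline ms baseline interval (default -100..0).
#' @param power_floor minimum power before taking log10, in squared signal
#'   units (guards against -Inf on silent epochs).
#' @return A list of class `tfr_config`.
#' @export
tfr_config <- function(freqs = 1:45, n_cycles = 6,
                       analysis_window = c(-200, 900), baseline = c(-100, 0),
                       power_floor = 1e-20) {
  cfg <- list(freqs = freqs, n_cycles = n_cycles,
              analysis_window = analysis_window, baseline = baseline,
              power_floor = power_floor)
  check_that(all(freqs > 0), "frequencies must be positive")
  check_that(n_cycles >= 3, "n_cycles must be >= 3")
  check_that(baseline[1] >= analysis_window[1] && baseline[2] <= analysis_window[2],
             "baseline must lie within the analysis window")
  check_that(power_floor > 0, "power_floor must be > 0")
  class(cfg) <- "tfr_config"
  cfg
}

# unit-energy complex Morlet wavelet sampled at srate
morlet_wavelet <- function(f, n_cycles, srate) {
  sigma_t <- n_cycles / (2 * pi * f)
  t <- seq(-4 * sigma_t, 4 * sigma_t, by = 1 / srate)
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w / sqrt(sum(Mod(w)^2) / srate)  # unit energy
}

#' Morlet wavelet time-frequency decomposition of epochs
#'
#' Convolves every trial and channel with unit-energy complex Morlet wavelets
#' (`n_cycles` cycles), takes power as the squared magnitude of the
#' coefficients, floors it, and returns log10 power. When
#' `average_channels = TRUE` (the sensor-level map convention) the log power
#' is averaged across channels after per-channel decomposition.
#'
#' Samples within one wavelet temporal sigma of the epoch boundary are
#' edge-affected; they are flagged in `edge_mask` (freqs x times, `TRUE` =
#' contaminated), not dropped.
#'
#' @param ep an `erp_epochs` object.
#' @param cfg a [tfr_config].
#' @param average_channels average log power over channels (default TRUE).
#' @return A `tfr_array`: `data` is trials x freqs x times (channels retained
#'   as a 4th dimension when `average_channels = FALSE`), with `freqs`,
#'   `times`, per-trial `labels`, `edge_mask`, and `baseline_corrected =
#'   FALSE`. Units: log10 of squared signal units.
#' @export
morlet_tfr <- function(ep, cfg = tfr_config(), average_channels = TRUE) {
  srate <- ep$srate
  check_that(max(cfg$freqs) < srate / 2, "frequency grid exceeds Nyquist (%g Hz)",
             srate / 2)
  dims <- dim(ep$data)
  n_trials <- dims[1]; n_chan <- dims[2]; n_samp <- dims[3]
  # trials*channels as columns for batched FFT convolution
  xmat <- matrix(aperm(ep$data, c(3, 2, 1)), nrow = n_samp)
  out <- array(0, dim = c(n_trials, length(cfg$freqs), n_samp,
                          if (average_channels) NULL else n_chan))
  edge <- matrix(FALSE, length(cfg$freqs), n_samp)
  fft_cache <- new.env()  # forward FFTs keyed by padded length
  for (fi in seq_along(cfg$freqs)) {
    f <- cfg$freqs[fi]
    wav <- morlet_wavelet(f, cfg$n_cycles, srate)
    nw <- length(wav)
    nfft <- 2^ceiling(log2(n_samp + nw - 1))
    key <- as.character(nfft)
    if (is.null(fft_cache[[key]])) {
      fft_cache[[key]] <- mvfft(rbind(xmat, matrix(0, nfft - n_samp, ncol(xmat))))
    }
    X <- fft_cache[[key]]
    W <- fft(c(wav, rep(0, nfft - nw)))
    Y <- mvfft(X * W, inverse = TRUE) / nfft / srate
    half <- (nw - 1) %/% 2
    coef <- Y[(half + 1):(half + n_samp), , drop = FALSE]
    logp <- log10(pmax(Re(coef)^2 + Im(coef)^2, cfg$power_floor))
    lp <- array(logp, dim = c(n_samp, n_chan, n_trials))
    if (average_channels) {
      acc <- lp[, 1, ]
      if (n_chan > 1) for (ch in 2:n_chan) acc <- acc + lp[, ch, ]
      out[, fi, ] <- t(acc / n_chan)  # trials x samples
    } else {
      out[, fi, , ] <- aperm(lp, c(3, 1, 2))
    }
    sigma_t_ms <- cfg$n_cycles / (2 * pi * f) * 1000
    edge[fi, ] <- ep$times < ep$times[1] + sigma_t_ms |
                  ep$times > ep$times[n_samp] - sigma_t_ms
  }
  structure(list(data = out, freqs = cfg$freqs, times = ep$times,
                 labels = ep$labels, srate = srate, edge_mask = edge,
                 baseline_corrected = FALSE, cfg = cfg),
            class = "tfr_array")
}

#' @export
print.tfr_array <- function(x, ...) {
  cat(sprintf("<tfr_array> %d trials x %d freqs (%g..%g Hz) x %d times, baseline %s\n",
              dim(x$data)[1], length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times),
              if (x$baseline_corrected) "corrected" else "raw"))
  invisible(x)
}

#' Subtract baseline log power
#'
#' Per trial and frequency, the mean log power over the baseline interval is
#' subtracted from every time point, so post-stimulus values express change
#' from the pre-stimulus spectrum.
#'
#' @param tfr a `tfr_array` (not yet baseline-corrected).
#' @param baseline ms interval (defaults to the array's configured baseline).
#' @return The corrected `tfr_array` with `baseline_corrected = TRUE`.
#' @export
baseline_subtract_tfr <- function(tfr, baseline = NULL) {
  check_that(!tfr$baseline_corrected, "TFR is already baseline-corrected")
  if (is.null(baseline)) baseline <- tfr$cfg$baseline
  bidx <- time_index(tfr$times, baseline)
  check_that(length(bidx) > 0, "baseline interval contains no samples")
  nd <- length(dim(tfr$data))
  bdat <- if (nd == 4) tfr$data[, , bidx, , drop = FALSE] else tfr$data[, , bidx, drop = FALSE]
  bl <- apply(bdat, seq_len(nd)[-3], mean)
  tfr$data <- sweep(tfr$data, seq_len(nd)[-3], bl, `-`)
  tfr$baseline_corrected <- TRUE
  tfr
}

#' Average a TFR over trials of one condition
#'
#' @param tfr a `tfr_array` with per-trial labels.
#' @param condition label to average.
#' @return freqs x times matrix of mean log power.
#' @export
tfr_condition_average <- function(tfr, condition) {
  idx <- which(tfr$labels == condition)
  check_that(length(idx) >= 1, "no trials of condition '%s'", condition)
  apply(tfr$data[idx, , , drop = FALSE], c(2, 3), mean)
}

#' Permutation T map comparing two conditions across subjects
#'
#' At every (frequency, time) point a paired T statistic across subjects
#' compares the trial-averaged log power of the two conditions; the null is
#' built by within-subject condition swaps (sign flips of paired
#' differences). The significance mask covers the post-stimulus range
#' `post_window` (default 0..800 ms).
#'
#' @param tfr_cong,tfr_incong lists (one element per subject) of freqs x
#'   times matrices, or subjects x freqs x times arrays, on identical grids.
#' @param times,freqs grid axes (ms, Hz).
#' @param n_perm permutation draws (default 1000).
#' @param alpha significance level (default 0.05).
#' @param post_window ms range over which the mask applies (default 0..800).
#' @param seed integer seed.
#' @return List with `t_map`, `p_map`, logical `mask` (freqs x times),
#'   `times`, `freqs`, and the test settings.
#' @export
tfr_permutation_test <- function(tfr_cong, tfr_incong, times, freqs,
                                 n_perm = 1000, alpha = 0.05,
                                 post_window = c(0, 800), seed = 1L) {
  as_array <- function(x) {
    if (is.list(x)) x <- simplify2array(x)  # freqs x times x subjects
    x
  }
  a <- as_array(tfr_cong); b <- as_array(tfr_incong)
  check_that(identical(dim(a), dim(b)), "condition TFR grids do not match")
  check_that(dim(a)[1] == length(freqs) && dim(a)[2] == length(times),
             "TFR dimensions do not match the stated grid")
  n_subj <- dim(a)[3]
  check_that(n_subj >= 5, "at least 5 subjects required")
  # subjects x (freq*time) differences
  d <- t(matrix(b - a, ncol = n_subj))
  res <- signflip_t_test(d, n_perm, seed)
  t_map <- matrix(res$t_obs, length(freqs), length(times))
  p_map <- matrix(res$p, length(freqs), length(times))
  mask <- p_map < alpha
  mask[, !(times >= post_window[1] & times <= post_window[2])] <- FALSE
  list(t_map = t_map, p_map = p_map, mask = mask, times = times, freqs = freqs,
       n_perm = n_perm, alpha = alpha, post_window = post_window, seed = seed)
}

#' Average a TFR over a frequency band
#'
#' @param tfr a `tfr_array`, or a freqs x times matrix with `freqs` supplied.
#' @param band Hz interval `(low, high)`, inclusive.
#' @param freqs frequency axis when `tfr` is a plain matrix.
#' @return Per-trial time series (trials x times matrix) for a `tfr_array`;
#'   a numeric time series for a matrix input.
#' @export
band_average <- function(tfr, band, freqs = NULL) {
  if (inherits(tfr, "tfr_array")) {
    fidx <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
    check_that(length(fidx) > 0, "band (%g..%g Hz) does not intersect the grid",
               band[1], band[2])
    out <- apply(tfr$data[, fidx, , drop = FALSE], c(1, 3), mean)
    return(out)
  }
  check_that(!is.null(freqs), "freqs required for matrix input")
  fidx <- which(freqs >= band[1] & freqs <= band[2])
  check_that(length(fidx) > 0, "band (%g..%g Hz) does not intersect the grid",
             band[1], band[2])
  colMeans(tfr[fidx, , drop = FALSE])
}
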