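# Filtering, resampling, epoching, baseline correction, averaging.

#' Zero-phase IIR filtering with reflection padding
#'
#' Forward-backward application of an ARMA filter. The input is extended at
#' both ends by reflected copies (up to 3 s) so low-frequency cut-offs do not
#' produce edge transients, then trimmed back to the original length.
#' @noRd
filter_zerophase <- function(x, filt, srate) {
  n <- length(x)
  npad <- min(n - 1L, round(3 * srate))
  if (npad > 0) {
    xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  } else {
    xp <- x
  }
  y <- .iir_core(filt$b, filt$a, xp)
  y <- rev(.iir_core(filt$b, filt$a, rev(y)))
  y[(npad + 1):(npad + n)]
}

butter_cascade <- function(kind, cutoffs, srate) {
  ny <- srate / 2
  check_that(all(cutoffs > 0) && all(cutoffs < ny),
             "filter cutoffs must lie in (0, Nyquist = %g Hz)", ny)
  switch(kind,
    lowpass = list(signal::butter(4, cutoffs[1] / ny, type = "low")),
    highpass = list(signal::butter(4, cutoffs[1] / ny, type = "high")),
    # band-pass as a high-pass/low-pass cascade: numerically robust when the
    # low edge sits far below Nyquist (e.g. 0.5 Hz at 300 Hz)
    bandpass = {
      check_that(length(cutoffs) == 2 && cutoffs[1] < cutoffs[2],
                 "bandpass needs increasing (low, high) cutoffs")
      list(signal::butter(4, cutoffs[1] / ny, type = "high"),
           signal::butter(4, cutoffs[2] / ny, type = "low"))
    },
    stop("unknown filter kind: ", kind))
}

# second-order notch resonator at f0 with the given -3 dB bandwidth
notch_filter <- function(f0, srate, bw = 2) {
  w0 <- 2 * pi * f0 / srate
  r <- 1 - pi * bw / srate
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  # unit gain at DC
  b <- b * sum(a) / sum(b)
  signal::Arma(b = b, a = a)
}

#' Filter a continuous recording (zero phase)
#'
#' All filters run forward-backward so evoked component latencies are not
#' shifted. `"notch"` applies a second-order resonator at the line frequency
#' and every harmonic below Nyquist; `"lowpass"` and `"bandpass"` are 4th-order
#' Butterworth designs (band-pass as a high-pass + low-pass cascade).
#'
#' @param rec a [continuous_recording].
#' @param kind one of `"notch"`, `"lowpass"`, `"bandpass"`.
#' @param params cutoff frequencies in Hz: the line frequency for `"notch"`
#'   (default 60), a single cutoff for `"lowpass"`, `(low, high)` for
#'   `"bandpass"`.
#' @param channels optional labels to filter; others pass through untouched.
#' @return The filtered [continuous_recording]; rate and channel kinds
#'   unchanged.
#' @export
apply_filter <- function(rec, kind = c("notch", "lowpass", "bandpass"),
                         params = NULL, channels = NULL) {
  kind <- match.arg(kind)
  check_that(inherits(rec, "continuous_recording"), "rec must be a continuous_recording")
  check_that(ncol(rec$data) > 0, "empty recording")
  ny <- rec$srate / 2
  filts <- if (kind == "notch") {
    f0 <- if (is.null(params)) 60 else params[1]
    harmonics <- f0 * seq_len(floor((ny - 1e-9) / f0))
    lapply(harmonics, notch_filter, srate = rec$srate)
  } else {
    check_that(!is.null(params), "cutoff frequencies required for %s", kind)
    butter_cascade(kind, params, rec$srate)
  }
  idx <- if (is.null(channels)) seq_len(nrow(rec$data)) else match(channels, rec$channels$label)
  out <- rec
  for (ch in idx) {
    x <- rec$data[ch, ]
    for (f in filts) x <- filter_zerophase(x, f, rec$srate)
    out$data[ch, ] <- x
  }
  out
}

#' Downsample a recording by an integer factor
#'
#' Applies an 8th-order Butterworth anti-alias low-pass at 80% of the target
#' Nyquist (zero phase), then keeps every q-th sample. Event onsets expressed
#' in seconds remain valid because sample 1 stays at t = 0.
#'
#' @param rec a [continuous_recording].
#' @param target_rate new rate in Hz; must divide the current rate.
#' @return The resampled [continuous_recording] with `ceiling(n/q)` samples.
#' @export
resample_recording <- function(rec, target_rate) {
  check_that(target_rate <= rec$srate, "upsampling is not supported")
  if (target_rate == rec$srate) return(rec)
  q <- rec$srate / target_rate
  check_that(abs(q - round(q)) < 1e-9,
             "target_rate must divide the current rate (%g / %g)", rec$srate, target_rate)
  q <- round(q)
  aa <- signal::butter(8, 0.8 / q)
  n <- ncol(rec$data)
  keep <- seq(1, n, by = q)
  data <- matrix(0, nrow(rec$data), length(keep))
  for (ch in seq_len(nrow(rec$data))) {
    data[ch, ] <- filter_zerophase(rec$data[ch, ], aa, rec$srate)[keep]
  }
  continuous_recording(data, rec$channels$label, rec$channels$kind,
                       target_rate, rec$ground_truth)
}

#' Segment a recording into stimulus-locked epochs
#'
#' Cuts a window around each selected event. Epochs whose window would extend
#' beyond the recording are dropped with a message and counted in
#' `attr(, "n_dropped")`.
#'
#' @param rec a [continuous_recording].
#' @param events an `event_table`.
#' @param window ms interval relative to event onset (default -200..900).
#' @param kind event kinds to keep (default `"word_target"`).
#' @param condition optionally restrict to one condition.
#' @param channels optional channel labels to keep.
#' @return An `erp_epochs` object: `data` is trials x channels x samples,
#'   with per-trial `labels`, the ms time axis `times`, `srate` and channel
#'   metadata.
#' @export
epoch_recording <- function(rec, events, window = c(-200, 900),
                            kind = "word_target", condition = NULL,
                            channels = NULL) {
  check_that(window[1] < window[2], "empty or reversed epoch window")
  sel <- events$kind %in% kind
  if (!is.null(condition)) sel <- sel & events$condition %in% condition
  ev <- events[sel, , drop = FALSE]
  check_that(nrow(ev) > 0, "no events match the requested kind/condition")
  if (!is.null(channels)) rec <- select_channels(rec, channels)
  offs <- window_offsets(window, rec$srate)
  n <- ncol(rec$data)
  onset_idx <- round(ev$onset * rec$srate) + 1L
  ok <- onset_idx + offs[1] >= 1L & onset_idx + offs[length(offs)] <= n
  if (any(!ok)) message(sum(!ok), " epoch(s) dropped: window exceeds recording bounds")
  ev <- ev[ok, , drop = FALSE]
  onset_idx <- onset_idx[ok]
  check_that(length(onset_idx) > 0, "all selected epochs fall outside the recording")
  dat <- array(0, dim = c(length(onset_idx), nrow(rec$data), length(offs)))
  for (i in seq_along(onset_idx)) {
    dat[i, , ] <- rec$data[, onset_idx[i] + offs, drop = FALSE]
  }
  out <- structure(list(
    data = dat, labels = ev$condition, window = window,
    times = offs * 1000 / rec$srate, srate = rec$srate,
    channels = rec$channels, baseline_corrected = FALSE
  ), class = "erp_epochs")
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat(sprintf("<erp_epochs> %d trials x %d channels x %d samples @ %g Hz, window %g..%g ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$srate,
              x$window[1], x$window[2]))
  print(table(x$labels))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts the per-trial, per-channel mean over the baseline interval.
#' Idempotent: the corrected data has zero baseline mean, so reapplying
#' changes nothing.
#'
#' @param ep an `erp_epochs` object.
#' @param baseline ms interval inside the epoch window (default -100..0).
#' @return The corrected `erp_epochs` with `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(ep, baseline = c(-100, 0)) {
  check_that(baseline[1] >= ep$window[1] && baseline[2] <= ep$window[2],
             "baseline (%g..%g ms) outside the epoch window (%g..%g ms)",
             baseline[1], baseline[2], ep$window[1], ep$window[2])
  bidx <- time_index(ep$times, baseline)
  check_that(length(bidx) > 0, "baseline interval contains no samples")
  means <- apply(ep$data[, , bidx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(rep(means, dim(ep$data)[3]), dim = dim(ep$data))
  ep$baseline_corrected <- TRUE
  ep
}

#' Average epochs of one condition
#'
#' @param ep an `erp_epochs` object.
#' @param condition label to average (`"congruent"` or `"incongruent"`).
#' @return An `erp_evoked`: channels x samples trial average with `n_trials`,
#'   time axis and channel metadata.
#' @export
conditional_average <- function(ep, condition) {
  idx <- which(ep$labels == condition)
  check_that(length(idx) >= 1, "no trials of condition '%s'", condition)
  avg <- apply(ep$data[idx, , , drop = FALSE], c(2, 3), mean)
  rownames(avg) <- ep$channels$label
  structure(list(data = avg, condition = condition, n_trials = length(idx),
                 times = ep$times, srate = ep$srate, channels = ep$channels,
                 window = ep$window),
            class = "erp_evoked")
}

#' @export
print.erp_evoked <- function(x, ...) {
  cat(sprintf("<erp_evoked> '%s': %d channels x %d samples, average of %d trials\n",
              x$condition, nrow(x$data), ncol(x$data), x$n_trials))
  invisible(x)
}

#' Grand average across subjects
#'
#' Unweighted mean of per-subject evoked responses on a common grid.
#'
#' @param evokeds list of `erp_evoked` objects with identical channels/times.
#' @return An `erp_evoked` whose `n_trials` counts subjects.
#' @export
grand_average <- function(evokeds) {
  check_that(length(evokeds) >= 1, "need at least one evoked response")
  out <- evokeds[[1]]
  acc <- Reduce(`+`, lapply(evokeds, function(e) e$data))
  out$data <- acc / length(evokeds)
  out$n_trials <- length(evokeds)
  out
}

#' Difference of two evoked responses
#'
#' @param a,b `erp_evoked` objects on the same grid; returns `a - b`.
#' @return An `erp_evoked` with condition label `"difference"`.
#' @export
evoked_difference <- function(a, b) {
  check_that(identical(dim(a$data), dim(b$data)), "evoked responses differ in shape")
  out <- a
  out$data <- a$data - b$data
  out$condition <- "difference"
  out
}

#' Peak latency of an evoked waveform within a search window
#'
#' Locates the extremum of one channel inside a window at the sampling grid's
#' resolution.
#'
#' @param ev an `erp_evoked`.
#' @param channel channel label.
#' @param window ms search interval (default 300..500).
#' @param mode `"min"` for a negative deflection (default, N-type), `"max"`
#'   for positive, `"abs"` for the largest magnitude.
#' @return Latency in ms.
#' @export
peak_latency <- function(ev, channel, window = c(300, 500), mode = c("min", "max", "abs")) {
  mode <- match.arg(mode)
  ch <- match(channel, ev$channels$label)
  check_that(!is.na(ch), "unknown channel '%s'", channel)
  idx <- time_index(ev$times, window)
  check_that(length(idx) > 0, "search window contains no samples")
  x <- ev$data[ch, idx]
  i <- switch(mode, min = which.min(x), max = which.max(x), abs = which.max(abs(x)))
  ev$times[idx[i]]
}

#' Peak characterization of an evoked difference wave
#'
#' Classical ERP peak measurement: the global extremum of the waveform over
#' all channels and time points inside the search window defines, at once,
#' the scalp maximum (the channel hosting the extremum), the peak latency
#' (its time) and the peak amplitude (its value).
#'
#' @param ev an `erp_evoked` (typically an incongruent-minus-congruent
#'   difference).
#' @param window ms search interval (default 300..500).
#' @param mode `"min"` for a negative component (default), `"max"`, or
#'   `"abs"`.
#' @return List with `channel`, `latency_ms`, `amplitude`.
#' @export
peak_characterization <- function(ev, window = c(300, 500),
                                  mode = c("min", "max", "abs")) {
  mode <- match.arg(mode)
  idx <- time_index(ev$times, window)
  check_that(length(idx) > 0, "search window contains no samples")
  sub <- ev$data[, idx, drop = FALSE]
  pos <- arrayInd(switch(mode, min = which.min(sub), max = which.max(sub),
                         abs = which.max(abs(sub))), dim(sub))
  list(channel = ev$channels$label[pos[1]],
       latency_ms = ev$times[idx[pos[2]]],
       amplitude = sub[pos[1], pos[2]])
}

#' Mean amplitude of an evoked waveform over a window
#'
#' @inheritParams peak_latency
#' @return Mean value over the window (channel units).
#' @export
window_mean <- function(ev, channel, window = c(300, 500)) {
  ch <- match(channel, ev$channels$label)
  check_that(!is.na(ch), "unknown channel '%s'", channel)
  mean(ev$data[ch, time_index(ev$times, window)])
}
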