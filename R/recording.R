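#' Continuous multichannel recording
#'
#' Container for a continuous electrophysiological recording: a channels x
#' samples numeric matrix with per-channel metadata (label, kind, unit) and a
#' sampling rate. EEG/EOG channels are in microvolts, MEG-like channels in
#' femtotesla. Sample `i` sits at time `(i - 1) / srate` seconds.
#'
#' @param data numeric matrix, channels x samples.
#' @param labels character vector of channel labels (rownames of `data`).
#' @param kinds character vector, one of `"eeg"`, `"eog"`, `"meg"` per channel.
#' @param srate sampling rate in Hz.
#' @param ground_truth optional [ground_truth] object stored alongside the
#'   synthesized recording.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, labels, kinds, srate, ground_truth = NULL) {
  check_that(is.matrix(data) && is.numeric(data), "data must be a numeric matrix")
  check_that(length(labels) == nrow(data), "one label per channel required")
  check_that(length(kinds) == nrow(data), "one kind per channel required")
  check_that(all(kinds %in% c("eeg", "eog", "meg")),
             "channel kinds must be eeg, eog or meg")
  check_that(is_scalar_num(srate) && srate > 0, "srate must be a positive number")
  rownames(data) <- labels
  units <- c(eeg = "uV", eog = "uV", meg = "fT")[kinds]
  structure(list(
    data = data,
    channels = data.frame(label = labels, kind = kinds, unit = unname(units),
                          stringsAsFactors = FALSE),
    srate = srate,
    ground_truth = ground_truth
  ), class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  tab <- table(x$channels$kind)
  cat("  channels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$ground_truth)) cat("  ground truth attached (seed",
                                    x$ground_truth$seed, ")\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [continuous_recording].
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$srate

#' Select channels of a recording
#'
#' @param rec a [continuous_recording].
#' @param labels channel labels to keep (in this order), or `NULL`.
#' @param kind optionally restrict to a channel kind.
#' @return A [continuous_recording] with the selected channels.
#' @export
select_channels <- function(rec, labels = NULL, kind = NULL) {
  keep <- rec$channels$label
  if (!is.null(kind)) keep <- keep[rec$channels$kind[match(keep, rec$channels$label)] %in% kind]
  if (!is.null(labels)) {
    check_that(all(labels %in% keep), "unknown channel label requested")
    keep <- labels
  }
  idx <- match(keep, rec$channels$label)
  continuous_recording(rec$data[idx, , drop = FALSE], rec$channels$label[idx],
                       rec$channels$kind[idx], rec$srate, rec$ground_truth)
}
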