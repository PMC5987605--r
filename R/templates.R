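#' Evoked-response template specification
#'
#' A smooth unimodal (Gaussian-windowed) deflection used as a ground-truth
#' evoked component. `half_width` is the full width at half maximum of the
#' deflection; the waveform is truncated to zero beyond three half-widths from
#' the peak. Negative amplitudes give negative-going (N-type) deflections.
#'
#' The default parameterizes the incongruent-minus-congruent N400 differential:
#' a negativity peaking at 420 ms, maximal parietally (Pz), attenuating toward
#' frontal sites. Amplitudes are generator design values in microvolts, not
#' literature measurements.
#'
#' @param peak_latency peak latency in ms post-stimulus.
#' @param half_width FWHM of the deflection in ms.
#' @param amplitude_per_channel named numeric vector, channel label -> peak
#'   amplitude in microvolts.
#' @return A list of class `template_spec`.
#' @export
template_spec <- function(peak_latency = 420, half_width = 120,
                          amplitude_per_channel = c(Pz = -4.0, Cz = -3.2, Fz = -2.0)) {
  check_that(is_scalar_num(peak_latency), "peak_latency must be a number (ms)")
  check_that(is_scalar_num(half_width) && half_width > 0, "half_width must be > 0")
  check_that(is.numeric(amplitude_per_channel) && !is.null(names(amplitude_per_channel)),
             "amplitude_per_channel must be a named numeric vector")
  structure(list(peak_latency = peak_latency, half_width = half_width,
                 amplitude_per_channel = amplitude_per_channel),
            class = "template_spec")
}

#' Render a template as per-channel waveforms on an epoch time grid
#'
#' @param spec a [template_spec].
#' @param srate sampling rate in Hz.
#' @param epoch_window ms interval `(start, end)` relative to stimulus onset.
#' @return channels x samples matrix; `attr(, "times_ms")` carries the time
#'   axis. The extremum of each channel's trace sits at `peak_latency` (on the
#'   sample grid) with value `amplitude_per_channel`.
#' @export
make_erp_template <- function(spec, srate, epoch_window = c(-200, 900)) {
  check_that(inherits(spec, "template_spec"), "spec must be a template_spec")
  check_that(spec$peak_latency > epoch_window[1] && spec$peak_latency < epoch_window[2],
             "peak_latency %g ms lies outside the epoch window (%g, %g) ms",
             spec$peak_latency, epoch_window[1], epoch_window[2])
  times <- window_offsets(epoch_window, srate) * 1000 / srate
  sigma <- spec$half_width / (2 * sqrt(2 * log(2)))  # FWHM -> Gaussian sigma
  g <- exp(-(times - spec$peak_latency)^2 / (2 * sigma^2))
  g[abs(times - spec$peak_latency) > 3 * spec$half_width] <- 0
  out <- outer(spec$amplitude_per_channel, g)
  rownames(out) <- names(spec$amplitude_per_channel)
  attr(out, "times_ms") <- times
  out
}

#' Default per-condition evoked templates
#'
#' Each condition maps to a list of [template_spec] components that are summed
#' at synthesis time. Both conditions share a common auditory word response
#' (N1-P2 complex); the incongruent condition additionally carries the N400
#' differential `differential` (default: 420 ms peak, Pz-maximal negativity),
#' so the incongruent-minus-congruent difference equals the differential
#' template exactly.
#'
#' @param differential the incongruent-minus-congruent [template_spec].
#' @param common list of [template_spec] components shared by both conditions.
#' @return Named list with `congruent` and `incongruent` template lists.
#' @export
default_condition_templates <- function(differential = template_spec(),
                                        common = list(
                                          template_spec(100, 70, c(Fz = -1.2, Cz = -1.5, Pz = -0.8)),
                                          template_spec(210, 90, c(Fz = 1.3, Cz = 1.8, Pz = 1.1))
                                        )) {
  list(congruent = common, incongruent = c(common, list(differential)))
}

#' N100-like tone response used for sequence fidelity
#'
#' Tones carry a small generic fronto-central negativity; they are generated
#' so the recording has realistic inter-stimulus structure but are not
#' analyzed by the word-pair pipeline.
#' @return A [template_spec].
#' @export
tone_template <- function() {
  template_spec(100, 60, c(Fz = -1.0, Cz = -1.2, Pz = -0.6))
}
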