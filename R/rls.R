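#' Recursive-least-squares adaptive filter configuration
#'
#' Settings for EOG interference cancellation: each reference channel feeds a
#' short FIR filter of `taps_m` coefficients (current plus past samples) whose
#' weights adapt by exponentially weighted recursive least squares with
#' forgetting factor `forgetting_lambda`. `init_delta` scales the initial
#' inverse-correlation matrix `P0 = init_delta^-1 I`.
#'
#' @param taps_m FIR taps per reference channel (default 3).
#' @param forgetting_lambda forgetting factor in (0, 1] (default 0.9999).
#' @param init_delta initialization scale (> 0, default 0.01).
#' @return A list of class `rls_config`.
#' @export
rls_config <- function(taps_m = 3L, forgetting_lambda = 0.9999, init_delta = 0.01) {
  cfg <- list(taps_m = as.integer(taps_m), forgetting_lambda = forgetting_lambda,
              init_delta = init_delta)
  check_that(cfg$taps_m >= 1L, "taps_m must be >= 1")
  check_that(cfg$forgetting_lambda > 0 && cfg$forgetting_lambda <= 1,
             "forgetting_lambda must be in (0, 1]")
  check_that(cfg$init_delta > 0, "init_delta must be > 0")
  class(cfg) <- "rls_config"
  cfg
}

#' Remove reference-correlated interference from one channel
#'
#' Runs the RLS recursion sample by sample: the cleaned output is the
#' prediction error `e_n = eeg_n - h' r_n`, where `r_n` stacks the last
#' `taps_m` samples of every reference channel (zero-padded history at the
#' start). Signal uncorrelated with the references passes through; the
#' component predictable from the references is adaptively subtracted.
#'
#' @param eeg numeric vector, the contaminated channel.
#' @param eog_refs numeric vector or samples x references matrix of reference
#'   channels (same length as `eeg`).
#' @param cfg an [rls_config].
#' @return List with `cleaned` (same length as input) and `state`
#'   (`h` weight vector, `P` inverse-correlation matrix, `n_samples`).
#' @export
rls_denoise <- function(eeg, eog_refs, cfg = rls_config()) {
  if (is.vector(eog_refs)) eog_refs <- matrix(eog_refs, ncol = 1)
  check_that(nrow(eog_refs) == length(eeg),
             "eeg and reference series must have the same length")
  res <- .rls_core(as.numeric(eeg), eog_refs, cfg$taps_m,
                   cfg$forgetting_lambda, cfg$init_delta)
  list(cleaned = res$cleaned,
       state = list(h = res$h, P = res$P, n_samples = res$n_samples))
}

#' Clean all EEG channels of a recording using its EOG channels
#'
#' Applies [rls_denoise()] to every EEG channel with all EOG channels as a
#' joint (stacked) reference, over the continuous recording before epoching.
#' Weights adapt once per channel across the whole recording and are never
#' reset. EOG and MEG channels pass through untouched.
#'
#' @param rec a [continuous_recording] containing both EEG and EOG channels.
#' @param cfg an [rls_config].
#' @return The cleaned recording; per-channel final weights are stored in
#'   `attr(, "rls_weights")` for audit.
#' @export
rls_clean_recording <- function(rec, cfg = rls_config()) {
  eeg_idx <- which(rec$channels$kind == "eeg")
  eog_idx <- which(rec$channels$kind == "eog")
  check_that(length(eeg_idx) > 0, "recording has no EEG channels")
  check_that(length(eog_idx) > 0, "recording has no EOG reference channels")
  refs <- t(rec$data[eog_idx, , drop = FALSE])
  weights <- list()
  out <- rec
  for (ch in eeg_idx) {
    res <- rls_denoise(rec$data[ch, ], refs, cfg)
    out$data[ch, ] <- res$cleaned
    weights[[rec$channels$label[ch]]] <- res$state$h
  }
  attr(out, "rls_weights") <- weights
  out
}
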