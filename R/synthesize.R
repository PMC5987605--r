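#' Subject-level synthesis parameters
#'
#' Parameters of the ground-truth signal model for one synthetic subject:
#' 1/f background noise, Poisson blink artifacts on the vertical EOG leaking
#' into frontal EEG, an ongoing beta-band oscillation whose amplitude drops by
#' `beta_desync_depth` inside `beta_desync_window` of incongruent word targets
#' (an induced, non-phase-locked effect), and MEG-like sensors driven by the
#' same cortical sources through a random nonnegative mixing matrix.
#'
#' @param noise_sigma standard deviation of the 1/f background, microvolts.
#' @param blink_rate blink events per minute on the vertical EOG.
#' @param blink_amplitude blink peak amplitude, microvolts.
#' @param eog_mixing named vector: EEG channel -> vertical-EOG coupling
#'   coefficient (horizontal EOG couples at 0.4 x these values).
#' @param beta_freq center frequency of the ongoing beta oscillation, Hz.
#' @param beta_amplitude equivalent sinusoid amplitude of the beta
#'   oscillation, microvolts.
#' @param beta_desync_depth fractional amplitude reduction of the beta
#'   oscillation in incongruent trials (0 = none, 1 = full suppression).
#' @param beta_desync_window ms interval post-stimulus in which the reduction
#'   applies.
#' @param sample_rate native sampling rate, Hz.
#' @param meg_channels number of synthetic MEG-like sensors.
#' @param meg_noise_sigma MEG sensor noise standard deviation, femtotesla.
#' @param meg_gain source-to-sensor scale, femtotesla per microvolt.
#' @return A list of class `subject_params`.
#' @export
subject_params <- function(noise_sigma = 10, blink_rate = 8, blink_amplitude = 150,
                           eog_mixing = c(Fz = 0.25, Cz = 0.12, Pz = 0.05),
                           beta_freq = 20, beta_amplitude = 2,
                           beta_desync_depth = 0.5,
                           beta_desync_window = c(335, 440),
                           sample_rate = 1200, meg_channels = 32L,
                           meg_noise_sigma = 30, meg_gain = 20) {
  p <- list(noise_sigma = noise_sigma, blink_rate = blink_rate,
            blink_amplitude = blink_amplitude, eog_mixing = eog_mixing,
            beta_freq = beta_freq, beta_amplitude = beta_amplitude,
            beta_desync_depth = beta_desync_depth,
            beta_desync_window = beta_desync_window,
            sample_rate = sample_rate, meg_channels = as.integer(meg_channels),
            meg_noise_sigma = meg_noise_sigma, meg_gain = meg_gain)
  check_that(p$noise_sigma >= 0 && p$meg_noise_sigma >= 0, "noise sigmas must be >= 0")
  check_that(p$blink_rate >= 0 && p$blink_amplitude >= 0, "blink parameters must be >= 0")
  check_that(p$beta_desync_depth >= 0 && p$beta_desync_depth <= 1,
             "beta_desync_depth must be in [0, 1]")
  check_that(p$sample_rate >= 2 * max(p$beta_freq, 45),
             "sample_rate must be at least twice the highest synthesized frequency")
  check_that(p$meg_channels >= 0L, "meg_channels must be >= 0")
  check_that(all(names(p$eog_mixing) %in% c("Fz", "Cz", "Pz")),
             "eog_mixing names must be EEG channels (Fz, Cz, Pz)")
  class(p) <- "subject_params"
  p
}

# relative per-channel gain of the beta source on the scalp
BETA_SCALP_GAINS <- c(Fz = 0.8, Cz = 1.0, Pz = 0.9)
EEG_CHANNELS <- c("Fz", "Cz", "Pz")
EOG_CHANNELS <- c("heog", "veog")

#' 1/f (pink) background noise
#'
#' Spectrally shaped white noise with power proportional to 1/f, flattened
#' below 0.5 Hz, rescaled to standard deviation `sigma`.
#' @noRd
one_over_f_noise <- function(n, srate, sigma) {
  if (sigma == 0) return(numeric(n))
  w <- rnorm(n)
  # frequency of FFT bin k: min(k, n-k) * srate / n
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * srate / n
  shape <- 1 / sqrt(pmax(f, 0.5))
  x <- Re(fft(fft(w) * shape, inverse = TRUE)) / n
  x * sigma / sd(x)
}

# narrowband noise oscillation centered on f0 (width +- 2.5 Hz), RMS = rms
narrowband_oscillation <- function(n, srate, f0, rms) {
  if (rms == 0) return(numeric(n))
  w <- rnorm(n)
  lo <- max(f0 - 2.5, 0.5)
  hi <- min(f0 + 2.5, srate / 2 * 0.95)
  x <- filter_zerophase(w, signal::butter(4, c(lo, hi) / (srate / 2), type = "pass"), srate)
  x * rms / sd(x)
}

# biphasic blink transient sampled at srate, centered on t = 0.15 s
blink_kernel <- function(srate, amplitude) {
  t <- seq(0, 0.6, by = 1 / srate)
  amplitude * (exp(-(t - 0.15)^2 / (2 * 0.045^2)) -
               0.35 * exp(-(t - 0.30)^2 / (2 * 0.09^2)))
}

add_at <- function(x, start_idx, kernel) {
  idx <- start_idx + seq_along(kernel) - 1L
  keep <- idx >= 1L & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + kernel[keep]
  x
}

#' Synthesize a single-subject continuous recording
#'
#' Builds the EEG (Fz, Cz, Pz), EOG (heog, veog) and MEG-like channels implied
#' by an event table: evoked templates added at every word target according to
#' its condition (plus a small generic tone response), an ongoing beta
#' oscillation whose amplitude is multiplied by `1 - beta_desync_depth` inside
#' the desynchronization window of incongruent targets only, Poisson-timed
#' biphasic blinks on the vertical EOG leaked into EEG via `eog_mixing`, and
#' independent 1/f noise per channel. MEG-like sensors mix the same evoked and
#' beta sources through a seeded random nonnegative matrix scaled by
#' `meg_gain`. Each component consumes its own sub-seed, so disabling one via
#' `include` leaves every other component bit-identical (exact superposition).
#'
#' @param params a [subject_params].
#' @param events an `event_table` from [generate_event_sequence()].
#' @param templates per-condition template lists as returned by
#'   [default_condition_templates()].
#' @param seed integer seed; the recording is fully deterministic given it.
#' @param include character subset of
#'   `c("evoked", "beta", "noise", "blinks")`; omitted components are zeroed
#'   without disturbing the others' random streams.
#' @param duration recording length in seconds; defaults to the last event
#'   onset plus one second, rounded up to a whole second.
#' @return A [continuous_recording] with a `ground_truth` record (component
#'   seeds, rendered templates, mixing matrices, desync windows) sufficient to
#'   reconstruct the noiseless signal.
#' @export
synthesize_subject <- function(params = subject_params(), events,
                               templates = default_condition_templates(),
                               seed = 1L,
                               include = c("evoked", "beta", "noise", "blinks"),
                               duration = NULL) {
  check_that(inherits(params, "subject_params"), "params must be a subject_params")
  check_that(all(c("congruent", "incongruent") %in% names(templates)),
             "templates must map both conditions")
  srate <- params$sample_rate
  if (is.null(duration)) duration <- ceiling(max(events$onset) + 1)
  check_that(duration >= max(events$onset) + 0.9,
             "recording (%.1f s) shorter than last event + epoch end (%.1f s)",
             duration, max(events$onset) + 0.9)
  n <- round(duration * srate)
  seeds <- derive_seeds(seed, 5L)
  names(seeds) <- c("beta", "noise", "blinks", "meg_mix", "saccades")

  epoch_window <- c(-200, 900)
  render <- function(spec_list) {
    out <- matrix(0, 3, length(window_offsets(epoch_window, srate)),
                  dimnames = list(EEG_CHANNELS, NULL))
    for (sp in spec_list) {
      tm <- make_erp_template(sp, srate, epoch_window)
      out[rownames(tm), ] <- out[rownames(tm), , drop = FALSE] + tm
    }
    out
  }
  cond_templates <- list(congruent = render(templates$congruent),
                         incongruent = render(templates$incongruent))
  tone_tm <- render(list(tone_template()))
  pre_samples <- -window_offsets(epoch_window, srate)[1]

  # --- evoked sources (deterministic) ---
  evoked <- matrix(0, 3, n, dimnames = list(EEG_CHANNELS, NULL))
  if ("evoked" %in% include) {
    prime_tm <- cond_templates$congruent * 0.6  # generic word response
    tm_len <- ncol(tone_tm)
    for (i in seq_len(nrow(events))) {
      onset_idx <- round(events$onset[i] * srate) + 1L
      tm <- switch(events$kind[i],
                   word_target = cond_templates[[events$condition[i]]],
                   tone_std = tone_tm, tone_dev = tone_tm,
                   word_prime = prime_tm,
                   NULL)
      if (!is.null(tm)) {
        idx <- onset_idx - pre_samples + seq_len(tm_len) - 1L
        keep <- idx >= 1L & idx <= n
        ii <- idx[keep]
        evoked[, ii] <- evoked[, ii] + tm[, keep, drop = FALSE]
      }
    }
  }

  # --- beta oscillation with event-related desynchronization ---
  beta_src <- numeric(n)
  desync_windows <- data.frame(start = numeric(0), end = numeric(0))
  if (params$beta_amplitude > 0) {
    osc <- with_seed(seeds[["beta"]],
                     narrowband_oscillation(n, srate, params$beta_freq,
                                            params$beta_amplitude / sqrt(2)))
    envelope <- rep(1, n)
    incong <- events[events$kind == "word_target" & events$condition == "incongruent", ]
    if (nrow(incong) > 0 && params$beta_desync_depth > 0) {
      w <- params$beta_desync_window / 1000
      desync_windows <- data.frame(start = incong$onset + w[1], end = incong$onset + w[2])
      for (j in seq_len(nrow(desync_windows))) {
        i0 <- round(desync_windows$start[j] * srate) + 1L
        i1 <- round(desync_windows$end[j] * srate) + 1L
        envelope[i0:i1] <- 1 - params$beta_desync_depth
      }
    }
    beta_src <- osc * envelope
  }
  beta_eeg <- outer(BETA_SCALP_GAINS[EEG_CHANNELS], beta_src)
  if (!("beta" %in% include)) beta_eeg[] <- 0

  sources <- evoked + beta_eeg  # cortical signal seen by both modalities

  # --- ocular artifacts ---
  veog_art <- numeric(n); heog_art <- numeric(n)
  with_seed(seeds[["blinks"]], {
    n_blinks <- rpois(1, params$blink_rate * duration / 60)
    blink_times <- sort(runif(n_blinks, 0, duration - 0.6))
  })
  with_seed(seeds[["saccades"]], {
    # saccade-like hEOG transients at half the blink rate
    n_sac <- rpois(1, params$blink_rate / 2 * duration / 60)
    sac_times <- sort(runif(n_sac, 0, duration - 0.5))
    sac_signs <- sample(c(-1, 1), n_sac, replace = TRUE)
  })
  if ("blinks" %in% include) {
    bk <- blink_kernel(srate, params$blink_amplitude)
    for (bt in blink_times) veog_art <- add_at(veog_art, round(bt * srate) + 1L, bk)
    sk_t <- seq(0, 0.4, by = 1 / srate)
    sk <- 30 * exp(-(sk_t - 0.2)^2 / (2 * 0.06^2))
    for (j in seq_along(sac_times)) {
      heog_art <- add_at(heog_art, round(sac_times[j] * srate) + 1L, sac_signs[j] * sk)
    }
  }
  mix <- params$eog_mixing[EEG_CHANNELS]
  mix[is.na(mix)] <- 0
  eog_leak <- outer(mix, veog_art) + outer(0.4 * mix, heog_art)

  # --- background noise, independent per channel ---
  n_meg <- params$meg_channels
  noise_mat <- matrix(0, 5 + n_meg, n)
  with_seed(seeds[["noise"]], {
    for (ch in 1:5) noise_mat[ch, ] <- one_over_f_noise(n, srate, params$noise_sigma)
    if (n_meg > 0) {
      for (ch in 1:n_meg) noise_mat[5 + ch, ] <- one_over_f_noise(n, srate, params$meg_noise_sigma)
    }
  })
  if (!("noise" %in% include)) noise_mat[] <- 0

  # --- MEG-like sensors: nonnegative random mixing of the same sources ---
  meg_mixing <- matrix(0, n_meg, 3, dimnames = list(NULL, EEG_CHANNELS))
  if (n_meg > 0) {
    meg_mixing <- with_seed(seeds[["meg_mix"]],
                            matrix(runif(n_meg * 3), n_meg, 3,
                                   dimnames = list(NULL, EEG_CHANNELS)))
    meg_data <- params$meg_gain * (meg_mixing %*% sources) + noise_mat[5 + 1:n_meg, , drop = FALSE]
  } else {
    meg_data <- matrix(0, 0, n)
  }

  eeg_data <- sources + eog_leak + noise_mat[1:3, , drop = FALSE]
  eog_data <- rbind(heog_art, veog_art) + noise_mat[4:5, , drop = FALSE]

  labels <- c(EEG_CHANNELS, EOG_CHANNELS,
              if (n_meg > 0) sprintf("MEG%02d", 1:n_meg))
  kinds <- c(rep("eeg", 3), rep("eog", 2), rep("meg", n_meg))
  gt <- structure(list(
    seed = seed, component_seeds = seeds, params = params,
    condition_templates = cond_templates, tone_template = tone_tm,
    epoch_window = epoch_window, meg_mixing = meg_mixing,
    eog_mixing = mix, beta_scalp_gains = BETA_SCALP_GAINS,
    desync_windows = desync_windows, include = include,
    blink_times = blink_times
  ), class = "ground_truth")
  continuous_recording(rbind(eeg_data, eog_data, meg_data), labels, kinds, srate, gt)
}

#' Cohort-level parameter distributions
#'
#' Describes how single-subject generator parameters vary across a synthetic
#' cohort: every subject's evoked template amplitudes are scaled by a common
#' factor drawn uniformly from `1 +- amp_jitter`, and every template peak
#' latency is shifted by a subject-level offset drawn uniformly from
#' `+- latency_jitter_ms`.
#'
#' @param params baseline [subject_params].
#' @param templates baseline condition templates
#'   ([default_condition_templates()]).
#' @param sequence a [sequence_config] shared by all subjects (event
#'   realizations remain subject-specific).
#' @param amp_jitter fractional amplitude jitter (>= 0).
#' @param latency_jitter_ms latency jitter half-range in ms (>= 0).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(params = subject_params(),
                        templates = default_condition_templates(),
                        sequence = sequence_config(),
                        amp_jitter = 0.2, latency_jitter_ms = 20) {
  check_that(amp_jitter >= 0 && latency_jitter_ms >= 0,
             "cohort jitters must be >= 0 (degenerate distribution)")
  check_that(amp_jitter < 1, "amp_jitter must be < 1")
  structure(list(params = params, templates = templates, sequence = sequence,
                 amp_jitter = amp_jitter, latency_jitter_ms = latency_jitter_ms),
            class = "cohort_spec")
}

jitter_templates <- function(templates, amp_factor, lat_shift) {
  adjust <- function(sp) template_spec(sp$peak_latency + lat_shift, sp$half_width,
                                       sp$amplitude_per_channel * amp_factor)
  lapply(templates, function(cond) lapply(cond, adjust))
}

#' Draw per-subject generator settings for a cohort
#'
#' Deterministic given `(spec, n_subjects, seed)`; shared by
#' [generate_cohort()] and the pipeline runner so both produce identical
#' subjects.
#'
#' @inheritParams generate_cohort
#' @return List of per-subject lists: `params`, `templates`, `event_seed`,
#'   `synth_seed`, `amp_factor`, `lat_shift`.
#' @export
draw_cohort_subjects <- function(n_subjects, spec = cohort_spec(), seed = 7L) {
  check_that(n_subjects >= 2, "n_subjects must be >= 2")
  seeds <- matrix(derive_seeds(seed, 2L * n_subjects), ncol = 2)
  draws <- with_seed(seed + 1L, {
    # +1 offsets the stream used for sub-seed derivation
    list(amp = runif(n_subjects, 1 - spec$amp_jitter, 1 + spec$amp_jitter),
         lat = runif(n_subjects, -spec$latency_jitter_ms, spec$latency_jitter_ms))
  })
  lapply(seq_len(n_subjects), function(i) {
    list(params = spec$params,
         templates = jitter_templates(spec$templates, draws$amp[i], draws$lat[i]),
         event_seed = seeds[i, 1], synth_seed = seeds[i, 2],
         amp_factor = draws$amp[i], lat_shift = draws$lat[i])
  })
}

#' Generate a synthetic cohort
#'
#' @param n_subjects number of subjects (>= 2).
#' @param spec a [cohort_spec] describing the parameter distributions.
#' @param seed master seed; per-subject seeds are derived from it, so the
#'   whole cohort is reproducible.
#' @return List of subjects, each `list(recording, events, ground_truth)`.
#' @export
generate_cohort <- function(n_subjects, spec = cohort_spec(), seed = 7L) {
  subj <- draw_cohort_subjects(n_subjects, spec, seed)
  lapply(subj, function(s) {
    events <- generate_event_sequence(spec$sequence, s$event_seed)
    rec <- synthesize_subject(s$params, events, s$templates, s$synth_seed)
    list(recording = rec, events = events, ground_truth = rec$ground_truth)
  })
}
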