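# Small fixture builders shared across test files.

# single-channel recording holding an arbitrary waveform
wave_recording <- function(x, srate = 300, label = "Cz", kind = "eeg") {
  continuous_recording(matrix(x, 1), label, kind, srate)
}

epoch_times <- function(window = c(-200, 900), srate = 300) {
  offs <- seq(round(window[1] * srate / 1000), round(window[2] * srate / 1000))
  offs * 1000 / srate
}

# build an erp_epochs object directly from a trials x channels x samples array
make_epochs <- function(dat, labels, srate = 300, window = c(-200, 900),
                        chan = NULL) {
  if (is.null(chan)) chan <- paste0("ch", seq_len(dim(dat)[2]))
  structure(list(
    data = dat, labels = labels, window = window,
    times = epoch_times(window, srate), srate = srate,
    channels = data.frame(label = chan, kind = "eeg", unit = "uV",
                          stringsAsFactors = FALSE),
    baseline_corrected = FALSE
  ), class = "erp_epochs")
}

# build an erp_evoked with given channel waveforms (channels x samples)
make_evoked <- function(dat, condition, srate = 300, window = c(-200, 900),
                        chan = rownames(dat)) {
  structure(list(
    data = dat, condition = condition, n_trials = 1L,
    times = epoch_times(window, srate), srate = srate,
    channels = data.frame(label = chan, kind = "eeg", unit = "uV",
                          stringsAsFactors = FALSE),
    window = window
  ), class = "erp_evoked")
}

# fast single-subject settings: EEG/EOG only, no MEG sensors
eeg_only_params <- function(...) subject_params(meg_channels = 0L, ...)
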