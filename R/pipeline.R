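# End-to-end pipeline: simulate -> preprocess -> clean -> statistics -> classify.

#' Pipeline configuration
#'
#' Bundles every stage's settings with a master seed. Each stochastic stage
#' consumes a sub-seed derived deterministically from `seed`, so rerunning
#' the same configuration reproduces every number in the report.
#'
#' @param n_subjects cohort size (default 15).
#' @param cohort a [cohort_spec].
#' @param seed master seed (default 7).
#' @param analysis_seed seed driving the analysis-side randomness (fold
#'   assignments, permutation draws); defaults to `seed` so a single value
#'   reproduces everything, but can be varied independently of the cohort.
#' @param target_rate analysis sampling rate in Hz after downsampling.
#' @param line_freq power-line frequency for the notch filter, Hz.
#' @param lowpass_cutoff broadband low-pass cutoff, Hz.
#' @param eeg_band ERP-branch band-pass, Hz.
#' @param broadband_band GFP/TFR-branch band-pass, Hz.
#' @param epoch_window,baseline ms intervals for segmentation and baseline.
#' @param analysis_window ms window of interest for amplitude/latency
#'   statistics (default 300..500).
#' @param rls an [rls_config].
#' @param tfr a [tfr_config].
#' @param beta_band Hz interval used for beta-band summaries.
#' @param meg_baseline baseline-correct MEG voltage epochs before GFP
#'   (default TRUE).
#' @param n_perm_interval,n_perm_tfr,n_perm_class permutation counts for the
#'   GFP interval test, the TFR map and the classification null.
#' @param cv_folds,cv_repeats cross-validation settings.
#' @param perm_cv_repeats CV repeats inside each classification permutation
#'   (default 1; the null accuracy is invariant in expectation to the repeat
#'   count, and single-repeat nulls keep the 1000-permutation test tractable).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 15, cohort = cohort_spec(), seed = 7L,
                            analysis_seed = seed,
                            target_rate = 300, line_freq = 60,
                            lowpass_cutoff = 100, eeg_band = c(1, 10),
                            broadband_band = c(0.5, 45),
                            epoch_window = c(-200, 900), baseline = c(-100, 0),
                            analysis_window = c(300, 500),
                            rls = rls_config(), tfr = tfr_config(),
                            beta_band = c(13, 30), meg_baseline = TRUE,
                            n_perm_interval = 1000, n_perm_tfr = 1000,
                            n_perm_class = 1000, cv_folds = 10, cv_repeats = 10,
                            perm_cv_repeats = 1) {
  cfg <- as.list(environment())
  check_that(cfg$n_subjects >= 2, "n_subjects must be >= 2")
  check_that(cfg$target_rate <= cfg$cohort$params$sample_rate,
             "target_rate exceeds the native sampling rate")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Preprocess one subject's raw recording
#'
#' Downsample (anti-aliased) to the analysis rate, notch out the line
#' frequency and harmonics, low-pass, then remove ocular contamination from
#' the EEG channels by RLS adaptive filtering against the EOG channels.
#'
#' @param rec raw [continuous_recording].
#' @param cfg a [pipeline_config].
#' @return The cleaned, resampled recording.
#' @export
preprocess_subject <- function(rec, cfg = pipeline_config()) {
  rec <- resample_recording(rec, cfg$target_rate)
  rec <- apply_filter(rec, "notch", cfg$line_freq)
  if (cfg$lowpass_cutoff < cfg$target_rate / 2) {
    rec <- apply_filter(rec, "lowpass", cfg$lowpass_cutoff)
  }
  rls_clean_recording(rec, cfg$rls)
}

#' Per-subject analysis branches
#'
#' `eeg_branch_subject()` runs the ERP branch on a cleaned recording:
#' band-pass to the ERP band (default 1-10 Hz), epoch around word targets,
#' baseline-correct, and average per condition. `meg_branch_subject()` runs
#' the broadband branch on the MEG-like channels: band-pass (default
#' 0.5-45 Hz), epoch, evoked averages and GFP per condition, and the
#' baseline-referenced Morlet TFR averaged per condition.
#'
#' @param rec a preprocessed [continuous_recording]
#'   (see [preprocess_subject()]).
#' @param events the subject's `event_table`.
#' @param cfg a [pipeline_config].
#' @return `eeg_branch_subject`: list of `erp_evoked` per condition.
#'   `meg_branch_subject`: list with `evoked`, `gfp`, `tfr_avg` per condition
#'   and the epoch time axis.
#' @export
eeg_branch_subject <- function(rec, events, cfg = pipeline_config()) {
  eeg <- apply_filter(select_channels(rec, kind = "eeg"), "bandpass", cfg$eeg_band)
  ep <- epoch_recording(eeg, events, cfg$epoch_window)
  ep <- baseline_correct(ep, cfg$baseline)
  list(congruent = conditional_average(ep, "congruent"),
       incongruent = conditional_average(ep, "incongruent"))
}

#' @rdname eeg_branch_subject
#' @export
meg_branch_subject <- function(rec, events, cfg = pipeline_config()) {
  meg <- apply_filter(select_channels(rec, kind = "meg"), "bandpass", cfg$broadband_band)
  ep <- epoch_recording(meg, events, cfg$epoch_window)
  ep_bl <- if (cfg$meg_baseline) baseline_correct(ep, cfg$baseline) else ep
  evoked <- list(congruent = conditional_average(ep_bl, "congruent"),
                 incongruent = conditional_average(ep_bl, "incongruent"))
  tfr <- morlet_tfr(ep, cfg$tfr)
  tfr <- baseline_subtract_tfr(tfr, cfg$tfr$baseline)
  list(evoked = evoked,
       gfp = lapply(evoked, function(e) global_field_power(e)$gfp),
       tfr_avg = list(congruent = tfr_condition_average(tfr, "congruent"),
                      incongruent = tfr_condition_average(tfr, "incongruent")),
       times = ep$times)
}

#' Run the full rapid-N400 analysis pipeline
#'
#' Simulates (or accepts) a cohort, preprocesses each subject (downsample,
#' notch, low-pass, RLS ocular cleaning), then runs two branches from the
#' same cleaned recordings: the EEG/ERP branch (1-10 Hz, epoch, conditional
#' averages, window-mean paired t at Cz, grand-average difference peak
#' latency at the maximal electrode, SVM classification with a
#' label-permutation null) and the MEG-like branch (0.5-45 Hz, GFP with a
#' sign-flip permutation interval test, Morlet TFR with a permutation T map
#' and beta-band summary).
#'
#' @param cfg a [pipeline_config].
#' @param subjects optionally, a pre-generated cohort as returned by
#'   [generate_cohort()]; by default the cohort is synthesized from `cfg`.
#' @param keep_intermediates keep per-subject evoked/GFP/TFR summaries in the
#'   report (default TRUE; set FALSE for a compact report).
#' @param progress print stage progress to stderr.
#' @return A `pipeline_report` list: `erp` (window test, latency, grand
#'   averages), `classification`, `gfp` (interval test + window test), `tfr`
#'   (T map, mask, beta summary), and a `provenance` block (config, seeds,
#'   package version).
#' @export
run_pipeline <- function(cfg = pipeline_config(), subjects = NULL,
                         keep_intermediates = TRUE, progress = TRUE) {
  say <- function(...) if (progress) message("[rn400] ", ...)
  stage_seeds <- derive_seeds(cfg$analysis_seed, 4L)
  names(stage_seeds) <- c("interval", "tfr", "cv", "perm")

  if (is.null(subjects)) {
    say("simulating cohort of ", cfg$n_subjects, " subjects (seed ", cfg$seed, ")")
    spec <- draw_cohort_subjects(cfg$n_subjects, cfg$cohort, cfg$seed)
  } else {
    check_that(length(subjects) >= 2, "need at least 2 subjects")
    spec <- NULL
  }
  n_subj <- if (is.null(spec)) length(subjects) else cfg$n_subjects

  eeg_evokeds <- vector("list", n_subj)
  meg_gfp_c <- NULL; meg_gfp_i <- NULL
  tfr_c <- vector("list", n_subj); tfr_i <- vector("list", n_subj)
  meg_times <- NULL
  have_meg <- TRUE

  for (i in seq_len(n_subj)) {
    if (is.null(spec)) {
      rec <- subjects[[i]]$recording
      events <- subjects[[i]]$events
    } else {
      s <- spec[[i]]
      events <- generate_event_sequence(cfg$cohort$sequence, s$event_seed)
      rec <- synthesize_subject(s$params, events, s$templates, s$synth_seed)
    }
    say("subject ", i, "/", n_subj, ": preprocessing")
    rec <- preprocess_subject(rec, cfg)
    eeg_evokeds[[i]] <- eeg_branch_subject(rec, events, cfg)
    if (any(rec$channels$kind == "meg")) {
      mb <- meg_branch_subject(rec, events, cfg)
      if (is.null(meg_gfp_c)) {
        meg_gfp_c <- matrix(0, n_subj, length(mb$gfp$congruent))
        meg_gfp_i <- meg_gfp_c
        meg_times <- mb$times
      }
      meg_gfp_c[i, ] <- mb$gfp$congruent
      meg_gfp_i[i, ] <- mb$gfp$incongruent
      tfr_c[[i]] <- mb$tfr_avg$congruent
      tfr_i[[i]] <- mb$tfr_avg$incongruent
    } else {
      have_meg <- FALSE
    }
    rm(rec)
  }

  # --- EEG/ERP statistics ---
  say("ERP statistics")
  times <- eeg_evokeds[[1]]$congruent$times
  cz_means <- vapply(eeg_evokeds, function(e)
    c(window_mean(e$congruent, "Cz", cfg$analysis_window),
      window_mean(e$incongruent, "Cz", cfg$analysis_window)), numeric(2))
  erp_test <- window_mean_test(cz_means[1, ], cz_means[2, ])
  ga_c <- grand_average(lapply(eeg_evokeds, `[[`, "congruent"))
  ga_i <- grand_average(lapply(eeg_evokeds, `[[`, "incongruent"))
  ga_diff <- evoked_difference(ga_i, ga_c)
  site_effects <- vapply(c("Fz", "Cz", "Pz"), function(ch)
    window_mean(ga_diff, ch, cfg$analysis_window), numeric(1))
  peak <- peak_characterization(ga_diff, cfg$analysis_window, mode = "min")
  max_site <- peak$channel
  latency <- peak$latency_ms

  # --- classification ---
  say("classification (", cfg$cv_repeats, "x ", cfg$cv_folds, "-fold CV)")
  fm <- build_feature_matrix(eeg_evokeds)
  cls <- svm_crossval(fm, cfg$cv_folds, cfg$cv_repeats, seed = stage_seeds[["cv"]])
  say("classification permutation null (", cfg$n_perm_class, " permutations)")
  perm <- permutation_significance(fm, cls$accuracy, cfg$n_perm_class,
                                   cfg$cv_folds, cfg$perm_cv_repeats,
                                   seed = stage_seeds[["perm"]])
  cls$p_perm <- perm$p
  cls$n_perm <- perm$n_perm
  cls$null_mean <- perm$null_mean
  cls$null_sd <- perm$null_sd

  # --- MEG-like branch statistics ---
  gfp_res <- NULL; tfr_res <- NULL
  if (have_meg && !is.null(meg_gfp_c)) {
    say("GFP permutation interval test")
    interval <- permutation_interval_test(meg_gfp_c, meg_gfp_i, meg_times,
                                          n_perm = cfg$n_perm_interval,
                                          seed = stage_seeds[["interval"]])
    widx <- time_index(meg_times, cfg$analysis_window)
    gfp_test <- window_mean_test(rowMeans(meg_gfp_c[, widx, drop = FALSE]),
                                 rowMeans(meg_gfp_i[, widx, drop = FALSE]))
    gfp_res <- list(interval_test = interval, window_test = gfp_test,
                    times = meg_times)
    say("TFR permutation map")
    tmap <- tfr_permutation_test(tfr_c, tfr_i, meg_times, cfg$tfr$freqs,
                                 n_perm = cfg$n_perm_tfr,
                                 seed = stage_seeds[["tfr"]])
    beta_rows <- which(cfg$tfr$freqs >= cfg$beta_band[1] &
                       cfg$tfr$freqs <= cfg$beta_band[2])
    beta_diff <- colMeans(Reduce(`+`, tfr_i)[beta_rows, , drop = FALSE] -
                          Reduce(`+`, tfr_c)[beta_rows, , drop = FALSE]) / n_subj
    sig_beta <- tmap$mask[beta_rows, , drop = FALSE] &
                (tmap$t_map[beta_rows, , drop = FALSE] < 0)
    sig_cols <- which(colSums(sig_beta) > 0)
    tfr_res <- list(test = tmap,
                    beta_band = cfg$beta_band,
                    beta_diff_series = beta_diff,
                    beta_sig_window = if (length(sig_cols) > 0)
                      range(meg_times[sig_cols]) else NULL)
  }

  report <- list(
    erp = list(window_test = erp_test, cz_means = cz_means,
               peak_latency_ms = latency, max_site = max_site,
               site_effects = site_effects,
               grand_average = if (keep_intermediates)
                 list(congruent = ga_c, incongruent = ga_i, difference = ga_diff),
               times = times),
    classification = cls,
    gfp = gfp_res,
    tfr = tfr_res,
    features = list(
      peak_latency_ms = latency,
      scalp_maximum = max_site,
      erp_window_effect_uV = unname(erp_test$means["incongruent"] -
                                    erp_test$means["congruent"]),
      erp_window_p = erp_test$p,
      gfp_window_p = if (!is.null(gfp_res)) gfp_res$window_test$p,
      gfp_interval_ms = if (!is.null(gfp_res) &&
                            nrow(gfp_res$interval_test$intervals) > 0)
        unlist(gfp_res$interval_test$intervals[1, ]),
      beta_sig_window_ms = if (!is.null(tfr_res)) tfr_res$beta_sig_window,
      accuracy = cls$accuracy, sensitivity = cls$sensitivity,
      specificity = cls$specificity, classification_p = cls$p_perm
    ),
    subject_evokeds = if (keep_intermediates) eeg_evokeds,
    gfp_matrices = if (keep_intermediates)
      list(congruent = meg_gfp_c, incongruent = meg_gfp_i),
    tfr_subject_averages = if (keep_intermediates)
      list(congruent = tfr_c, incongruent = tfr_i),
    provenance = list(seed = cfg$seed, analysis_seed = cfg$analysis_seed,
                      stage_seeds = as.list(stage_seeds),
                      n_subjects = n_subj,
                      package_version = as.character(packageVersion("rn400")))
  )
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  f <- x$features
  cat("<pipeline_report>\n")
  cat(sprintf("  ERP: peak latency %.1f ms at %s; window effect %.2f uV (p = %.4g)\n",
              f$peak_latency_ms, f$scalp_maximum, f$erp_window_effect_uV,
              f$erp_window_p))
  if (!is.null(f$gfp_window_p)) {
    iv <- if (!is.null(f$gfp_interval_ms))
      sprintf("%g..%g ms", f$gfp_interval_ms[1], f$gfp_interval_ms[2]) else "none"
    cat(sprintf("  GFP: significant interval %s; window test p = %.4g\n", iv,
                f$gfp_window_p))
  }
  if (!is.null(f$beta_sig_window_ms)) {
    cat(sprintf("  TFR: significant beta decrease %g..%g ms\n",
                f$beta_sig_window_ms[1], f$beta_sig_window_ms[2]))
  }
  cat(sprintf("  Classification: accuracy %.2f%%, sensitivity %.3f, specificity %.3f (p = %.4g)\n",
              f$accuracy, f$sensitivity, f$specificity, f$classification_p))
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' Serializes the scalar results and test summaries (not the bulky
#' intermediate arrays) together with the provenance block.
#'
#' @param report a `pipeline_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    features = report$features,
    erp = list(t = report$erp$window_test$t, df = report$erp$window_test$df,
               p = report$erp$window_test$p,
               means = as.list(report$erp$window_test$means),
               sem = as.list(report$erp$window_test$sem)),
    classification = list(confusion = report$classification$confusion,
                          accuracy = report$classification$accuracy,
                          sensitivity = report$classification$sensitivity,
                          specificity = report$classification$specificity,
                          p_perm = report$classification$p_perm,
                          folds = report$classification$folds,
                          repeats = report$classification$repeats),
    gfp = if (!is.null(report$gfp))
      list(intervals = report$gfp$interval_test$intervals,
           n_perm = report$gfp$interval_test$n_perm,
           window_test = list(t = report$gfp$window_test$t,
                              p = report$gfp$window_test$p,
                              means = as.list(report$gfp$window_test$means))),
    provenance = report$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' EDF write-then-read round trip
#'
#' Convenience wrapper around [write_edf()] and [read_edf()] used to verify
#' that serialization preserves the recording within 16-bit quantization.
#'
#' @param rec a [continuous_recording].
#' @param path EDF path (written, then read back).
#' @return The re-read [continuous_recording].
#' @export
io_roundtrip <- function(rec, path) {
  write_edf(rec, path)
  back <- read_edf(path)
  check_that(identical(back$channels$label, rec$channels$label),
             "channel labels changed in round trip")
  check_that(identical(back$channels$kind, rec$channels$kind),
             "channel kinds changed in round trip")
  back
}
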