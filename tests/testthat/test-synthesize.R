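test_that("noiseless synthesis reconstructs the injected template exactly", {
  ev <- generate_event_sequence(seed = 3)
  p <- eeg_only_params(noise_sigma = 0, blink_rate = 0, beta_amplitude = 0)
  rec <- synthesize_subject(p, ev, seed = 4)
  ep <- epoch_recording(rec, ev, condition = "incongruent",
                        channels = c("Fz", "Cz", "Pz"))
  avg <- conditional_average(ep, "incongruent")
  tmpl <- rec$ground_truth$condition_templates$incongruent
  # compare up to 600 ms: beyond that the next block's tone response overlaps
  idx <- which(avg$times <= 600)
  expect_lt(max(abs(avg$data[, idx] - tmpl[, idx])), 1e-9)
})

test_that("the recording is an exact superposition of its components", {
  ev <- generate_event_sequence(sequence_config(n_blocks = 6), seed = 5)
  p <- subject_params(meg_channels = 4L)
  full <- synthesize_subject(p, ev, seed = 11)
  parts <- lapply(c("evoked", "beta", "noise", "blinks"), function(comp)
    synthesize_subject(p, ev, seed = 11, include = comp))
  total <- Reduce(`+`, lapply(parts, function(r) r$data))
  expect_lt(max(abs(full$data - total)), 1e-9)
})

test_that("synthesis is deterministic given the seed", {
  ev <- generate_event_sequence(sequence_config(n_blocks = 4), seed = 6)
  p <- subject_params(meg_channels = 2L)
  a <- synthesize_subject(p, ev, seed = 8)
  b <- synthesize_subject(p, ev, seed = 8)
  expect_identical(a$data, b$data)
  c <- synthesize_subject(p, ev, seed = 9)
  expect_false(identical(a$data, c$data))
})

test_that("too-short recordings and invalid parameters are rejected", {
  ev <- generate_event_sequence(sequence_config(n_blocks = 2), seed = 1)
  expect_error(synthesize_subject(eeg_only_params(), ev, seed = 1,
                                  duration = 5), "shorter")
  expect_error(subject_params(noise_sigma = -1), "sigma")
  expect_error(subject_params(beta_desync_depth = 1.5), "desync")
  expect_error(subject_params(sample_rate = 30), "sample_rate")
})

test_that("without blinks the EOG leaves no trace in the EEG", {
  ev <- generate_event_sequence(sequence_config(n_blocks = 12), seed = 2)
  p0 <- eeg_only_params(blink_rate = 0)
  rec0 <- synthesize_subject(p0, ev, seed = 21)
  r0 <- cor(rec0$data["Fz", ], rec0$data["veog", ])
  expect_lt(abs(r0), 0.05)
  p1 <- eeg_only_params()  # default 8 blinks/min
  rec1 <- synthesize_subject(p1, ev, seed = 21)
  r1 <- cor(rec1$data["Fz", ], rec1$data["veog", ])
  expect_gt(r1, 0.1)
})

test_that("trial averaging obeys the 1/sqrt(n) noise law", {
  # Monte-Carlo over 50 seeds. Blinks and the beta oscillation are disabled
  # so the residual isolates the stochastic background term the law predicts.
  p <- eeg_only_params(blink_rate = 0, beta_amplitude = 0)
  ratios <- numeric(50); rms5 <- numeric(50); rms30 <- numeric(50)
  for (s in 1:50) {
    ev <- generate_event_sequence(seed = 1000 + s)
    rec <- synthesize_subject(p, ev, seed = 2000 + s)
    ep <- epoch_recording(rec, ev, condition = "congruent",
                          channels = c("Fz", "Cz", "Pz"))
    tmpl <- rec$ground_truth$condition_templates$congruent
    a30 <- conditional_average(ep, "congruent")$data
    rms30[s] <- sqrt(mean((a30 - tmpl)^2))
    ratios[s] <- rms30[s] / (p$noise_sigma / sqrt(30))
    ep5 <- ep
    ep5$data <- ep$data[1:5, , , drop = FALSE]
    ep5$labels <- ep$labels[1:5]
    a5 <- conditional_average(ep5, "congruent")$data
    rms5[s] <- sqrt(mean((a5 - tmpl)^2))
  }
  expect_gt(mean(ratios), 0.75)
  expect_lt(mean(ratios), 1.25)
  # residual shrinks like 1/sqrt(n): 5 -> 30 trials gives sqrt(6)
  expect_equal(mean(rms5) / mean(rms30), sqrt(6), tolerance = 0.15)
})

test_that("induced beta desynchronization leaves no phase-locked average", {
  # evoked templates disabled, desync enabled: condition averages must be
  # statistically indistinguishable (50 seeds)
  templates0 <- list(congruent = list(), incongruent = list())
  p <- eeg_only_params(noise_sigma = 0, blink_rate = 0)
  diffs <- vapply(1:50, function(s) {
    ev <- generate_event_sequence(seed = 100 + s)
    rec <- synthesize_subject(p, ev, templates0, seed = 300 + s)
    ep <- epoch_recording(rec, ev, channels = "Cz")
    d <- conditional_average(ep, "incongruent")$data -
         conditional_average(ep, "congruent")$data
    widx <- which(epoch_times() >= 335 & epoch_times() <= 440)
    mean(d[1, widx])
  }, numeric(1))
  expect_gt(t.test(diffs)$p.value, 0.001)
})

test_that("cohorts are reproducible and respect degenerate distributions", {
  spec <- cohort_spec(params = subject_params(meg_channels = 2L),
                      sequence = sequence_config(n_blocks = 4))
  a <- generate_cohort(3, spec, seed = 7)
  b <- generate_cohort(3, spec, seed = 7)
  expect_identical(lapply(a, function(s) s$recording$data),
                   lapply(b, function(s) s$recording$data))
  expect_equal(length(a), 3)
  # zero-variance cohort: identical ground-truth templates across subjects
  z <- cohort_spec(params = subject_params(meg_channels = 0L),
                   sequence = sequence_config(n_blocks = 2),
                   amp_jitter = 0, latency_jitter_ms = 0)
  cz <- generate_cohort(2, z, seed = 3)
  expect_identical(cz[[1]]$ground_truth$condition_templates,
                   cz[[2]]$ground_truth$condition_templates)
  expect_error(cohort_spec(amp_jitter = -0.1), "degenerate")
  expect_error(generate_cohort(1, z, seed = 1), "n_subjects")
})

test_that("a default cohort carries full-length event tables per subject", {
  # structural claim only, so the MEG sensor array is dropped for speed
  spec <- cohort_spec(params = eeg_only_params())
  cohort <- generate_cohort(15, spec, seed = 7)
  expect_equal(length(cohort), 15)
  for (s in cohort) {
    expect_equal(length(unique(s$events$block)), 60)
    expect_equal(nrow(s$events), 420)
    expect_s3_class(s$recording, "continuous_recording")
  }
})
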