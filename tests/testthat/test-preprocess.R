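test_that("notch filter suppresses the line frequency by at least 40 dB", {
  srate <- 300
  t <- seq(0, 20, by = 1 / srate)
  rec <- wave_recording(sin(2 * pi * 60 * t), srate)
  out <- apply_filter(rec, "notch", 60)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  atten <- sqrt(mean(out$data[1, mid]^2)) / sqrt(mean(rec$data[1, mid]^2))
  expect_lt(20 * log10(atten), -40)
})

test_that("band-pass rejects DC and preserves in-band amplitude", {
  srate <- 300
  n <- 20 * srate
  dc <- apply_filter(wave_recording(rep(1, n), srate), "bandpass", c(1, 10))
  mid <- seq(round(n * 0.25), round(n * 0.75))
  expect_lt(max(abs(dc$data[1, mid])), 1e-6)
  t <- seq(0, 20, by = 1 / srate)
  s5 <- apply_filter(wave_recording(sin(2 * pi * 5 * t), srate), "bandpass", c(1, 10))
  amp <- max(abs(s5$data[1, mid]))
  expect_equal(amp, 1, tolerance = 0.05)
})

test_that("filters reject invalid cutoffs and empty recordings", {
  rec <- wave_recording(rnorm(300), 300)
  expect_error(apply_filter(rec, "lowpass", 200), "Nyquist")
  expect_error(apply_filter(rec, "bandpass", c(10, 1)), "increasing")
  empty <- continuous_recording(matrix(numeric(0), 1, 0), "Cz", "eeg", 300)
  expect_error(apply_filter(empty, "lowpass", 10), "empty")
})

test_that("downsampling preserves in-band content and sample arithmetic", {
  srate <- 1200
  t <- seq(0, 10, by = 1 / srate)
  rec <- wave_recording(sin(2 * pi * 10 * t), srate)
  down <- resample_recording(rec, 300)
  expect_equal(down$srate, 300)
  expect_equal(ncol(down$data), ceiling(ncol(rec$data) / 4))
  mid <- seq(round(ncol(down$data) * 0.25), round(ncol(down$data) * 0.75))
  expect_equal(max(abs(down$data[1, mid])), 1, tolerance = 0.01)
  # identity and guards
  expect_identical(resample_recording(rec, 1200), rec)
  expect_error(resample_recording(rec, 2400), "upsampling")
  expect_error(resample_recording(rec, 500), "divide")
})

test_that("epoching selects the requested trials and drops boundary cases", {
  ev <- generate_event_sequence(seed = 1)
  n <- 301 * 300
  rec <- continuous_recording(matrix(0, 1, n), "Cz", "eeg", 300)
  ep <- epoch_recording(rec, ev, condition = "congruent")
  expect_equal(dim(ep$data)[1], 30)
  expect_equal(dim(ep$data)[3], 331)   # -200..900 ms at 300 Hz
  expect_error(epoch_recording(rec, ev, window = c(0, 0)), "window")
  expect_error(epoch_recording(rec, ev, kind = "nope"), "no events")
  # event at recording start cannot supply a -200 ms window
  ev0 <- ev
  ev0$onset[ev0$kind == "word_target"][1] <- 0.05
  ev0 <- ev0[order(ev0$onset), ]
  expect_message(ep0 <- epoch_recording(rec, ev0, kind = "word_target"),
                 "dropped")
  expect_equal(attr(ep0, "n_dropped"), 1)
  expect_equal(dim(ep0$data)[1], 59)
})

test_that("baseline correction zeroes the baseline and is idempotent", {
  set.seed(1)
  dat <- array(rnorm(10 * 2 * 331, sd = 5), dim = c(10, 2, 331))
  ep <- make_epochs(dat, labels = rep(c("congruent", "incongruent"), 5))
  bc <- baseline_correct(ep)
  bidx <- which(bc$times >= -100 & bc$times <= 0)
  expect_lt(max(abs(apply(bc$data[, , bidx, drop = FALSE], c(1, 2), mean))), 1e-10)
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)
  # constant trials become all-zero
  epc <- make_epochs(array(3, dim = c(2, 1, 331)), labels = c("congruent", "congruent"))
  expect_true(all(baseline_correct(epc)$data == 0))
  expect_error(baseline_correct(ep, baseline = c(-500, 0)), "outside")
})

test_that("conditional averages obey exact combination rules", {
  set.seed(2)
  dat <- array(rnorm(12 * 3 * 50), dim = c(12, 3, 50))
  ep <- make_epochs(dat, labels = rep(c("congruent", "incongruent"), each = 6),
                    window = c(0, 163.3333), srate = 300)
  # two identical trials average to the trial itself
  ep2 <- make_epochs(dat[c(1, 1), , , drop = FALSE],
                     labels = c("congruent", "congruent"),
                     window = c(0, 163.3333), srate = 300)
  expect_equal(conditional_average(ep2, "congruent")$data, dat[1, , ],
               ignore_attr = TRUE)
  # disjoint subsets combine weighted by trial count
  a <- apply(dat[1:2, , ], c(2, 3), mean)
  b <- apply(dat[3:6, , ], c(2, 3), mean)
  full <- conditional_average(ep, "congruent")$data
  expect_equal((2 * a + 4 * b) / 6, unname(full), tolerance = 1e-12)
  expect_error(conditional_average(ep, "nope"), "no trials")
})

test_that("epoching and averaging commute with channel subsetting", {
  ev <- generate_event_sequence(sequence_config(n_blocks = 4), seed = 3)
  set.seed(4)
  rec <- continuous_recording(matrix(rnorm(3 * 21 * 300), 3),
                              c("Fz", "Cz", "Pz"), rep("eeg", 3), 300)
  full <- conditional_average(
    epoch_recording(rec, ev, kind = "word_target"),
    "congruent")
  sub <- conditional_average(
    epoch_recording(select_channels(rec, "Cz"), ev, kind = "word_target"),
    "congruent")
  expect_equal(sub$data[1, ], full$data["Cz", ], ignore_attr = TRUE)
})

test_that("zero-phase filtering leaves the template peak latency in place", {
  ev <- generate_event_sequence(seed = 5)
  p <- eeg_only_params(noise_sigma = 0, blink_rate = 0, beta_amplitude = 0)
  rec <- synthesize_subject(p, ev, seed = 6)
  cfg <- pipeline_config()
  rec <- preprocess_subject(rec, cfg)
  eb <- eeg_branch_subject(rec, ev, cfg)
  d <- evoked_difference(eb$incongruent, eb$congruent)
  expect_lte(abs(peak_latency(d, "Pz") - 420), 1000 / 300)
  pk <- peak_characterization(d)
  expect_identical(pk$channel, "Pz")
})
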