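sine_epochs <- function(freq, amp = 1, n_trials = 1, srate = 300) {
  times <- epoch_times(srate = srate)
  dat <- array(0, dim = c(n_trials, 1, length(times)))
  for (i in seq_len(n_trials)) dat[i, 1, ] <- amp * sin(2 * pi * freq * times / 1000)
  make_epochs(dat, labels = rep("congruent", n_trials), srate = srate)
}

test_that("the wavelet transform is frequency selective", {
  ep <- sine_epochs(10)
  tfr <- morlet_tfr(ep, tfr_config(freqs = 2:40))
  center <- !tfr$edge_mask[which(tfr$freqs == 10), ]
  prof <- apply(tfr$data[1, , center], 1, mean)
  expect_equal(tfr$freqs[which.max(prof)], 10)
})

test_that("log power is homogeneous: doubling amplitude adds log10(4)", {
  t1 <- morlet_tfr(sine_epochs(10, amp = 1), tfr_config(freqs = c(5, 10, 20)))
  t2 <- morlet_tfr(sine_epochs(10, amp = 2), tfr_config(freqs = c(5, 10, 20)))
  d <- t2$data - t1$data
  above <- t1$data > log10(1e-20) + 1  # away from the floor
  expect_equal(max(abs(d[above] - log10(4))), 0, tolerance = 1e-9)
})

test_that("silent epochs floor cleanly with no non-finite values", {
  ep <- make_epochs(array(0, dim = c(2, 1, 331)),
                    labels = c("congruent", "congruent"))
  tfr <- morlet_tfr(ep, tfr_config(freqs = c(5, 20)))
  expect_true(all(is.finite(tfr$data)))
  expect_true(all(tfr$data == log10(1e-20)))
})

test_that("frequencies above Nyquist are rejected", {
  expect_error(morlet_tfr(sine_epochs(10), tfr_config(freqs = c(10, 200))),
               "Nyquist")
})

test_that("baseline subtraction zeroes stationary maps and flags bursts", {
  cfg <- tfr_config(freqs = seq(5, 40, by = 5))
  stat <- baseline_subtract_tfr(morlet_tfr(sine_epochs(20), cfg))
  # at the driven frequency, away from epoch edges, a stationary oscillation
  # corrects to ~0 (weakly excited rows only carry edge-leakage power and
  # are not informative about stationarity)
  times <- epoch_times()
  row20 <- which(stat$freqs == 20)
  sigma_ms <- 6 / (2 * pi * 20) * 1000
  interior <- times > -200 + 3 * sigma_ms & times < 900 - 3 * sigma_ms
  expect_lt(max(abs(stat$data[1, row20, interior])), 0.05)
  expect_error(baseline_subtract_tfr(stat), "already")

  # burst at 20 Hz around 400 ms riding on a stationary carrier, so the
  # baseline spectrum is well above the power floor
  env <- 0.3 + exp(-(times - 400)^2 / (2 * 50^2))
  burst <- sin(2 * pi * 20 * times / 1000) * env
  epb <- make_epochs(array(burst, dim = c(1, 1, length(times))), labels = "congruent")
  tb <- baseline_subtract_tfr(morlet_tfr(epb, cfg))
  row20 <- which(tb$freqs == 20)
  in_burst <- times >= 350 & times <= 450
  pre <- times >= -50 & times <= 100
  expect_gt(mean(tb$data[1, row20, in_burst]), 0.5)
  expect_lt(max(abs(tb$data[1, row20, pre])),
            mean(tb$data[1, row20, in_burst]) / 2)
  # baseline window of the corrected map averages to zero
  bidx <- times >= -100 & times <= 0
  expect_lt(abs(mean(tb$data[1, row20, bidx])), 1e-12)

  # time-frequency localization: the raw power map of a pure Gaussian burst
  # peaks at its nominal frequency and center
  pure <- sin(2 * pi * 20 * times / 1000) * exp(-(times - 400)^2 / (2 * 50^2))
  epp <- make_epochs(array(pure, dim = c(1, 1, length(times))), labels = "congruent")
  grid <- tfr_config(freqs = 14:26)
  tl <- morlet_tfr(epp, grid)
  m <- arrayInd(which.max(tl$data[1, , ]), dim(tl$data[1, , ]))
  sigma_t_ms <- 6 / (2 * pi * 20) * 1000
  expect_lte(abs(tl$freqs[m[1]] - 20), 1)
  expect_lte(abs(times[m[2]] - 400), 2 * sigma_t_ms)
})

test_that("band averaging reduces the frequency axis correctly", {
  cfg <- tfr_config(freqs = seq(10, 30, by = 5))
  tfr <- morlet_tfr(sine_epochs(20, n_trials = 2), cfg)
  single <- band_average(tfr, c(15, 15))
  expect_equal(single[1, ], tfr$data[1, which(tfr$freqs == 15), ],
               ignore_attr = TRUE)
  full <- band_average(tfr, c(10, 30))
  expect_equal(full[2, ], apply(tfr$data[2, , ], 2, mean), ignore_attr = TRUE)
  expect_error(band_average(tfr, c(50, 60)), "intersect")
  # the band series peaks inside a burst window
  times <- epoch_times()
  burst <- sin(2 * pi * 20 * times / 1000) * exp(-(times - 400)^2 / (2 * 50^2))
  epb <- make_epochs(array(burst, dim = c(1, 1, length(times))), labels = "congruent")
  tb <- baseline_subtract_tfr(morlet_tfr(epb, cfg))
  series <- band_average(tb, c(13, 30))
  expect_true(times[which.max(series[1, ])] >= 300 &&
              times[which.max(series[1, ])] <= 500)
})

test_that("identical condition maps give an empty significance mask", {
  set.seed(3)
  maps <- lapply(1:8, function(i) matrix(rnorm(10 * 50), 10))
  r <- tfr_permutation_test(maps, maps, times = seq(0, 490, by = 10),
                            freqs = 1:10, n_perm = 200, seed = 1)
  expect_false(any(r$mask))
})

test_that("the default cohort shows a significant beta-band decrease", {
  rep <- default_cohort_report()
  tm <- rep$tfr$test
  beta_rows <- which(tm$freqs >= 13 & tm$freqs <= 30)
  win_cols <- which(tm$times >= 335 & tm$times <= 440)
  hit <- tm$mask[beta_rows, win_cols] & (tm$t_map[beta_rows, win_cols] < 0)
  expect_true(any(hit))
  # the desynchronization window summary covers the injected interval
  expect_false(is.null(rep$tfr$beta_sig_window))
  expect_lte(rep$tfr$beta_sig_window[1], 440)
  expect_gte(rep$tfr$beta_sig_window[2], 335)
})
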