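# batch least-squares oracle on the same zero-padded lagged regressors the
# recursion sees
batch_ls_weights <- function(d, refs, m, delta = 0) {
  if (is.vector(refs)) refs <- matrix(refs, ncol = 1)
  n <- length(d)
  X <- do.call(cbind, lapply(seq_len(ncol(refs)), function(j) {
    sapply(0:(m - 1), function(l) c(rep(0, l), refs[seq_len(n - l), j]))
  }))
  solve(crossprod(X) + delta * diag(ncol(X)), crossprod(X, d))
}

blink_train <- function(n, srate, rate_per_min = 10, amp = 150) {
  k <- rn400:::blink_kernel(srate, amp)
  x <- numeric(n)
  times <- runif(rpois(1, rate_per_min * n / srate / 60), 0, (n - length(k)) / srate)
  for (bt in times) x <- rn400:::add_at(x, round(bt * srate) + 1L, k)
  x
}

test_that("all-zero references leave the input untouched", {
  set.seed(1)
  x <- rnorm(500)
  res <- rls_denoise(x, matrix(0, 500, 2))
  expect_equal(res$cleaned, x)
  expect_true(all(res$state$h == 0))
})

test_that("RLS removes the EOG-correlated component and keeps the signal", {
  # 20-seed Monte-Carlo with synthetic blink trains mixed at 0.5
  # the uncontaminated signal is band-limited so its chance correlation with
  # the reference has enough effective degrees of freedom to resolve 0.05
  srate <- 300; n <- 20 * srate
  bp <- signal::butter(4, c(1, 30) / 150, type = "pass")
  c_eog <- numeric(20); c_sig <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    brain <- 10 * scale(rn400:::filter_zerophase(rnorm(n), bp, srate))[, 1]
    eog <- blink_train(n, srate) + rnorm(n, sd = 5)
    eeg <- brain + 0.5 * eog
    res <- rls_denoise(eeg, eog)
    post <- (2 * srate):n  # after 2 s of adaptation
    c_eog[s] <- abs(cor(res$cleaned[post], eog[post]))
    c_sig[s] <- cor(res$cleaned[post], brain[post])
  }
  expect_lt(mean(c_eog), 0.05)
  expect_true(all(c_sig > 0.95))
})

test_that("with no forgetting the weights match the batch LS solution", {
  set.seed(7)
  srate <- 300; n <- 3000
  eog <- cbind(blink_train(n, srate) + rnorm(n, sd = 5),
               rnorm(n, sd = 10))
  true_h <- c(0.4, 0.2, -0.1, 0.15, 0.05, 0)
  X <- do.call(cbind, lapply(1:2, function(j)
    sapply(0:2, function(l) c(rep(0, l), eog[seq_len(n - l), j]))))
  d <- as.numeric(X %*% true_h) + rnorm(n, sd = 2)
  cfg <- rls_config(forgetting_lambda = 1)
  res <- rls_denoise(d, eog, cfg)
  oracle <- as.numeric(batch_ls_weights(d, eog, 3, delta = cfg$init_delta))
  expect_lt(sqrt(sum((res$state$h - oracle)^2)) / sqrt(sum(oracle^2)), 0.01)
})

test_that("cleaning is scale-equivariant in the contaminated channel", {
  set.seed(3)
  eog <- rnorm(1000)
  eeg <- rnorm(1000) + 0.3 * eog
  a <- rls_denoise(eeg, eog)$cleaned
  b <- rls_denoise(5 * eeg, eog)$cleaned
  expect_equal(b, 5 * a, tolerance = 1e-10)
})

test_that("excess error decreases in trend under stationary mixing", {
  set.seed(9)
  n <- 12000
  eog <- rnorm(n, sd = 20)
  brain <- rnorm(n, sd = 5)
  d <- brain + 0.5 * eog
  res <- rls_denoise(d, eog)
  err2 <- (res$cleaned - brain)^2
  q <- split(err2, rep(1:4, each = n / 4))
  means <- vapply(q, mean, numeric(1))
  expect_gt(means[1], means[4])
})

test_that("cleaning does not eat ERP signal when blinks are absent", {
  ev <- generate_event_sequence(seed = 11)
  p <- eeg_only_params(blink_rate = 0, beta_amplitude = 0)
  rec <- synthesize_subject(p, ev, seed = 12)
  cfg <- pipeline_config()
  base <- resample_recording(rec, 300)
  base <- apply_filter(base, "notch", 60)
  base <- apply_filter(base, "lowpass", 100)
  cleaned <- rls_clean_recording(base, cfg$rls)
  diff_wave <- function(r) {
    eb <- eeg_branch_subject(r, ev, cfg)
    evoked_difference(eb$incongruent, eb$congruent)$data
  }
  d0 <- diff_wave(base)
  d1 <- diff_wave(cleaned)
  expect_lt(sqrt(mean((d1 - d0)^2)) / sqrt(mean(d0^2)), 0.05)
})

test_that("configuration guards reject invalid settings", {
  expect_error(rls_config(forgetting_lambda = 0), "forgetting")
  expect_error(rls_config(taps_m = 0), "taps_m")
  expect_error(rls_config(init_delta = 0), "init_delta")
  expect_error(rls_denoise(rnorm(10), rnorm(9)), "length")
})
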