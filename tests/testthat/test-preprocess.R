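test_that("band-pass filtering is zero-phase with the expected band edges", {
  fs <- 500
  # symmetric pulse stays symmetric about its center (duration generous
  # enough for the 0.1 Hz edge's transient to decay)
  n_long <- 60 * fs + 1
  pulse <- exp(-((seq_len(n_long) - (n_long + 1) / 2) / 50)^2)
  yp <- bandpass_zero_phase(pulse, fs, band_spec(0.1, 24))
  expect_lt(max(abs(yp - rev(yp))), 1e-6 * max(abs(yp)))

  n <- 5001
  t <- (seq_len(n) - 1) / fs

  # stop-band oracle: order-4 low-pass applied twice gives
  # |H(50)|^2 = 1/(1 + (50/24)^8) ~ 1/350, far below the 1/40 requirement;
  # measured attenuation also includes filtfilt edge transients
  interior <- 1000:4000
  x50 <- sin(2 * pi * 50 * t)
  y50 <- bandpass_zero_phase(x50, fs, band_spec(0.1, 24))
  atten <- sqrt(mean(y50[interior]^2)) / sqrt(mean(x50[interior]^2))
  expect_lt(atten, 1 / 40)

  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_zero_phase(x10, fs, band_spec(0.1, 24))
  gain <- sqrt(mean(y10[interior]^2)) / sqrt(mean(x10[interior]^2))
  expect_equal(gain, 1, tolerance = 0.05)

  # cross-correlation of an in-band tone peaks at lag zero
  x5 <- sin(2 * pi * 5 * t)
  y5 <- bandpass_zero_phase(x5, fs, band_spec(0.1, 24))
  lags <- -10:10
  cc <- vapply(lags, function(l) {
    cor(x5[interior], y5[interior + l])
  }, numeric(1))
  expect_identical(lags[which.max(cc)], 0L)

  expect_error(bandpass_zero_phase(x5, fs, band_spec(0.1, 300)), "Nyquist")
})

test_that("resampling decimates band-limited signals faithfully", {
  expect_length(resample_to(numeric(5000), 500, 100), 1000L)
  expect_equal(resample_to(rep(3.7, 1000), 500, 100), rep(3.7, 200),
               tolerance = 1e-9)
  fs <- 500
  t <- (0:4999) / fs
  x <- sin(2 * pi * 1 * t)
  y <- resample_to(x, fs, 100)
  t_new <- seq(0, by = 1 / 100, length.out = length(y))
  expect_gt(cor(y, sin(2 * pi * 1 * t_new)), 0.999)
  expect_error(resample_to(x, 100, 500), "upsampling")
})

test_that("average referencing removes the channel mean and is idempotent", {
  set.seed(1)
  eeg <- matrix(rnorm(400), 100, 4)
  ref <- average_reference(eeg)
  expect_lt(max(abs(rowMeans(ref))), 1e-12)
  expect_equal(average_reference(ref), ref, tolerance = 1e-12)
  ab <- cbind(a = rnorm(50), b = rnorm(50))
  expect_equal(average_reference(ab)[, 1], (ab[, 1] - ab[, 2]) / 2,
               ignore_attr = TRUE)
  expect_error(average_reference(matrix(1:5)), "2 channels")
})

test_that("variance-based channel rejection flags only outlying channels", {
  set.seed(2)
  equal <- sapply(1:10, function(i) rnorm(500))
  expect_false(any(flag_noisy_channels(equal)))
  # constructed variances: 9 channels of unit variance, one of variance 100;
  # threshold 3 * (109/10) = 32.7 so only the large one is flagged
  scaled <- equal
  scaled <- sweep(scaled, 2, apply(scaled, 2, sd), "/")
  scaled[, 10] <- scaled[, 10] * 10
  expect_identical(which(flag_noisy_channels(scaled)), 10L)
  expect_false(any(flag_noisy_channels(scaled, factor = Inf)))
})

test_that("EMG envelope tracks the RMS of the band-passed signal", {
  expect_true(all(emg_envelope(numeric(2000), 500) == 0))
  set.seed(3)
  x <- rnorm(50000)
  env <- emg_envelope(x, 500)
  expect_true(all(env >= 0))
  bp <- bandpass_zero_phase(x, 500, band_spec(20, 249, 4))
  interior <- 2000:48000
  expect_equal(mean(env[interior]), sd(bp[interior]), tolerance = 0.1)
  expect_error(emg_envelope(x, 500, win_s = 0.001), "window")
})

test_that("column z-scoring follows the sample-sd convention", {
  expect_equal(zscore_columns(matrix(c(1, 2, 3))), matrix(c(-1, 0, 1)),
               ignore_attr = TRUE)
  set.seed(4)
  X <- matrix(rnorm(300), 100, 3)
  Z <- zscore_columns(X)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_equal(apply(Z, 2, sd), rep(1, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(zscore_columns(Z), Z, tolerance = 1e-12, ignore_attr = TRUE)
  X[, 2] <- 5
  colnames(X) <- c("a", "flat", "c")
  expect_error(zscore_columns(X), "flat")
})

test_that("the conditioning chain preserves inter-channel correlation structure", {
  set.seed(5)
  fs <- 500
  n <- 30000
  mk <- function() bandpass_zero_phase(rnorm(n), fs, band_spec(1, 20, 4))
  base <- mk()
  X <- cbind(base + 0.5 * mk(), base + 0.5 * mk(), -base + 0.5 * mk())
  r_before <- cor(X)
  Y <- resample_to(bandpass_zero_phase(X, fs, band_spec(0.1, 24)), fs, 100)
  expect_lt(max(abs(r_before - cor(Y))), 0.02)
})

test_that("session preprocessing re-references, rejects and logs", {
  gt <- default_ground_truth(6, fs = 100, seed = 8)
  ses <- generate_session(gt, duration_s = 30, fs = 100, seed = 9)$session
  ses$eeg[, 3] <- ses$eeg[, 3] * 50  # make one channel grossly noisy
  pre <- preprocess_session(ses, band = band_spec(0.1, 24), fs_out = 100)
  expect_true(pre$preprocessed)
  expect_identical(pre$log$dropped_noisy, "EEG3")
  expect_false("EEG3" %in% colnames(pre$eeg))
  expect_equal(dim(pre$emg_env), dim(ses$emg))
  expect_lt(max(abs(colMeans(pre$accel))), 1e-10)
  # steering passes through untouched at the analysis rate
  expect_identical(pre$steering$values, ses$steering$values)
})
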