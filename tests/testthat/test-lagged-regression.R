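test_that("lag design shifts, orders and zero-pads as documented", {
  x <- rnorm(50)
  expect_equal(lag_design(x, c(0, 0), 100), matrix(x), ignore_attr = TRUE)

  imp <- numeric(100); imp[10] <- 1
  D <- lag_design(imp, c(0, 0.02), 100)
  expect_identical(ncol(D), 3L)
  expect_identical(vapply(1:3, function(j) which(D[, j] == 1), integer(1)),
                   c(10L, 11L, 12L))

  # two channels, three lags: channel-major, lag-minor column order
  X <- cbind(a = seq_len(30), b = -seq_len(30))
  D2 <- lag_design(X, c(0, 0.02), 100)
  expect_identical(ncol(D2), 6L)
  expect_equal(D2[, 1], X[, 1], ignore_attr = TRUE)
  expect_equal(D2[4:30, 2], X[3:29, 1], ignore_attr = TRUE)  # lag 1 of channel a
  expect_equal(D2[, 4], X[, 2], ignore_attr = TRUE)          # lag 0 of channel b

  expect_error(lag_design(rnorm(10), c(0, 1), 100), "longer")
})

test_that("ridge solutions match brute-force normal equations and shrink correctly", {
  set.seed(10)
  x <- matrix(rnorm(2000 * 3), 2000, 3)
  D <- lag_design(x, c(0, 0.19), 100)   # 20 lags x 3 channels
  w0 <- matrix(rnorm(60), 60, 1)
  y <- D %*% w0 + rnorm(2000)
  for (lambda in c(0, 1, 100)) {
    fit <- ridge_solve(D, y, lambda)
    expect_lt(max(abs(fit$weights - ridge_oracle(D, y, lambda))), 1e-8)
  }
  # shrinkage limit
  big <- ridge_solve(D, y, 1e12)
  expect_lt(max(abs(big$weights)), 1e-6)
  # noiseless recovery at negligible lambda
  fit0 <- ridge_solve(D, D %*% w0, 1e-10)
  expect_lt(max(abs(fit0$weights - w0)), 1e-6)
})

test_that("first-difference penalty smooths the weights", {
  set.seed(11)
  x <- rnorm(3000)
  D <- lag_design(x, c(0, 0.3), 100)
  y <- D %*% rnorm(31) + 5 * rnorm(3000)
  rough <- ridge_solve(D, y, 10, penalty = "identity")$weights
  smooth <- ridge_solve(D, y, 1e4, penalty = "first_difference")$weights
  expect_lt(sum(diff(smooth[, 1])^2), sum(diff(rough[, 1])^2))
})

test_that("cross-validated fits recover structure and stay honest on noise", {
  set.seed(12)
  fs <- 50
  s <- generate_steering(120, fs, 2, seed = 13)$values
  k <- make_kernel(-0.5, 0.1, 1, c(-1, 0), fs)
  D <- lag_design(s, c(-1, 0), fs)
  y <- D %*% k$weights
  fit <- cross_validated_fit(s, y, c(-1.5, 0.5), fs,
                             lambda_grid = grid_coarse, n_folds = 5,
                             lambda_mode = "global")
  expect_gt(fit$cv$mean_r, 0.99)

  # independent signals decode at chance
  noise_fit <- cross_validated_fit(rnorm(6000), rnorm(6000), c(0, 0.1), 100,
                                   lambda_grid = grid_coarse, n_folds = 10,
                                   lambda_mode = "global")
  expect_lt(abs(noise_fit$cv$mean_r), 0.1)

  # folds partition the session contiguously with near-equal sizes
  b <- cv_fold_bounds(6001, 10)
  expect_identical(b$start[1], 1L)
  expect_identical(b$end[10], 6001L)
  expect_true(all(b$start[-1] == head(b$end, -1) + 1L))
  expect_lte(diff(range(b$end - b$start + 1L)), 1L)
  expect_error(cv_fold_bounds(100, 1), "k")
})

test_that("two-fold cross-validation equals two direct ridge solves", {
  set.seed(14)
  fs <- 100
  x <- rnorm(2000)
  y <- 0.5 * x + rnorm(2000)
  lambda <- 10
  fit <- cross_validated_fit(x, y, c(0, 0.05), fs, lambda_grid = lambda,
                             n_folds = 2, lambda_mode = "global")
  # brute-force oracle with the same global column standardisation
  D <- lag_design(x, c(0, 0.05), fs)
  Ds <- sweep(D, 2, apply(D, 2, sd), "/")
  halves <- list(1:1000, 1001:2000)
  manual <- vapply(1:2, function(f) {
    tr <- halves[[3 - f]]; te <- halves[[f]]
    w <- ridge_oracle(Ds[tr, ], y[tr], lambda)
    pred <- sweep(Ds[te, ], 2, colMeans(Ds[tr, ])) %*% w + mean(y[tr])
    cor(pred[, 1], y[te])
  }, numeric(1))
  expect_equal(fit$cv$fold_r, manual, tolerance = 1e-8)
  expect_error(cross_validated_fit(x, y, c(0, 0.05), fs, lambda_grid = lambda,
                                   n_folds = 2, lambda_mode = "nested"),
               "3 folds")
})

test_that("nested and global lambda selection agree on easy problems", {
  set.seed(15)
  fs <- 50
  s <- generate_steering(120, fs, 2, seed = 16)$values
  y <- lag_design(s, c(-0.5, 0), fs) %*% rnorm(26) + 0.5 * rnorm(6000)
  nested <- cross_validated_fit(s, y, c(-1, 0.5), fs,
                                lambda_grid = grid_coarse, n_folds = 5,
                                lambda_mode = "nested")
  global <- cross_validated_fit(s, y, c(-1, 0.5), fs,
                                lambda_grid = grid_coarse, n_folds = 5,
                                lambda_mode = "global")
  expect_gt(nested$cv$mean_r, 0.9)
  expect_equal(nested$cv$mean_r, global$cv$mean_r, tolerance = 0.05)
  expect_length(nested$cv$lambda_per_fold, 5L)
})

test_that("anticipation windows follow the [-(a+size), -a] rule", {
  expect_equal(anticipation_to_window(1.2), c(-2.7, -1.2))
  expect_equal(anticipation_to_window(0), c(-1.5, 0))
  expect_equal(anticipation_to_window(12), c(-13.5, -12))
  expect_error(anticipation_to_window(-1), "anticipation")
})

test_that("the encoder recovers kernels and reports the documented shapes", {
  gt <- default_ground_truth(4, fs = 50,
                             artifact_gains = c(emg = 0, accel = 0, eog = 0),
                             noise_sd = 0.2, seed = 2)
  ses <- generate_session(gt, duration_s = 120, fs = 50, seed = 3,
                          steering_cutoff_hz = 2)$session
  enc <- fit_encoder(ses$steering, ses$eeg, window = c(-1.5, 0.5), fs = 50,
                     lambda_grid = grid_coarse, n_folds = 5,
                     lambda_mode = "global")
  expect_identical(dim(enc$model$weights), c(101L, 1L, 4L))
  # peak latency matches the ground-truth bump (SNR = 5 per channel)
  for (ch in 1:4) {
    est_peak <- enc$model$lags_s[which.max(abs(enc$model$weights[, 1, ch]))]
    true_peak <- gt$kernel_lags_s[which.max(abs(gt$kernels[, ch]))]
    expect_lt(abs(est_peak - true_peak), 2.5 / 50)
  }
  # all-zero EEG gives identically zero weights
  z <- fit_encoder(ses$steering, matrix(0, nrow(ses$eeg), 2), fs = 50,
                   lambda_grid = 1, n_folds = 3, lambda_mode = "global")
  expect_true(all(z$model$weights == 0))
})

test_that("decoding weakens with anticipation and sweeps are deterministic", {
  ses <- clean_session(n_channels = 4, fs = 25, duration_s = 240, seed = 17,
                       cutoff = 0.5)$session
  r0 <- fit_decoder(ses$eeg, ses$steering, 0, fs = 25,
                    lambda_grid = grid_coarse, n_folds = 5,
                    lambda_mode = "global")
  r3 <- fit_decoder(ses$eeg, ses$steering, 3, fs = 25,
                    lambda_grid = grid_coarse, n_folds = 5,
                    lambda_mode = "global")
  expect_gt(r0$cv$mean_r, r3$cv$mean_r)
  expect_equal(r0$model$window, c(-1.5, 0))
  pred <- predict(r0$model, ses$eeg)
  expect_length(pred, length(ses$steering$values))

  # default anticipation schedule has the canonical 13 entries
  expect_length(eval(formals(anticipation_sweep)$anticipations), 13L)

  sw1 <- anticipation_sweep(ses$eeg, ses$steering, anticipations = c(0, 1.5, 6),
                            fs = 25, lambda_grid = grid_coarse, n_folds = 5,
                            lambda_mode = "global")
  sw2 <- anticipation_sweep(ses$eeg, ses$steering, anticipations = c(0, 1.5, 6),
                            fs = 25, lambda_grid = grid_coarse, n_folds = 5,
                            lambda_mode = "global")
  expect_identical(sw1$curve, sw2$curve)
  expect_lt(cor(sw1$curve$anticipation_s, sw1$curve$mean_r,
                method = "spearman"), 0)
  expect_error(anticipation_sweep(ses$eeg, ses$steering,
                                  anticipations = numeric(0), fs = 25),
               "empty")
})

test_that("combined decoding concatenates streams and validates inputs", {
  ses <- clean_session(n_channels = 3, fs = 25, duration_s = 120,
                       seed = 18)$session
  streams <- list(eeg = ses$eeg, emg = ses$emg, accel = ses$accel,
                  eog = ses$eog)
  comb <- combined_decode(streams, ses$steering, 0.3, fs = 25,
                          lambda_grid = grid_coarse, n_folds = 5,
                          lambda_mode = "global")
  direct <- fit_decoder(cbind(ses$eeg, ses$emg, ses$accel, ses$eog),
                        ses$steering, 0.3, fs = 25,
                        lambda_grid = grid_coarse, n_folds = 5,
                        lambda_mode = "global")
  expect_equal(comb$cv$fold_r, direct$cv$fold_r, tolerance = 1e-12)
  expect_error(combined_decode(streams[c("eeg", "emg")], ses$steering, 0.3,
                               fs = 25),
               "accel")
})

test_that("decoding is driven by the low-frequency band", {
  ses <- clean_session(n_channels = 6, fs = 50, duration_s = 240,
                       seed = 19)$session
  dec <- function(eeg) {
    fit_decoder(eeg, ses$steering, 0.3, fs = 50, lambda_grid = grid_coarse,
                n_folds = 10, lambda_mode = "global")$cv$mean_r
  }
  r_broad <- dec(bandpass_zero_phase(ses$eeg, 50, band_spec(0.1, 24)))
  r_low <- dec(bandpass_zero_phase(ses$eeg, 50, band_spec(0.1, 3)))
  r_high <- dec(bandpass_zero_phase(ses$eeg, 50, band_spec(3, 24)))
  expect_lt(abs(r_broad - r_low), 0.05)
  cfg <- decoder_config(0.3, 1.5, fs = 50, lambda_grid = grid_coarse,
                        n_folds = 10, lambda_mode = "global")
  null <- shuffled_fold_null(bandpass_zero_phase(ses$eeg, 50, band_spec(3, 24)),
                             ses$steering, cfg, n_iter = 15, seed = 20)
  expect_lt(r_high, baseline_threshold(null, 95))
})

test_that("pearson_r matches its closed-form cases", {
  x <- rnorm(100)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  t5 <- (0:999) / 1000
  expect_lt(abs(pearson_r(sin(2 * pi * 5 * t5), cos(2 * pi * 5 * t5))), 1e-6)
  expect_error(pearson_r(x, rep(1, 100)), "zero-variance")
  expect_error(pearson_r(x, rnorm(50)), "unequal")
})
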