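# Shared fixtures, built in code. Problem sizes (duration, rate, channel
# count, grid density) are scaled down for test runtime; generator condition
# values (noise level, gains, kernel shapes) stay at package defaults.

# coarse ridge grid spanning the default interval, one value per two decades
grid_coarse <- 10^seq(-1, 7, by = 2)

# brain-only session: anticipatory kernels, background noise, no artifacts
clean_session <- function(n_channels = 6, fs = 50, duration_s = 240,
                          seed = 4, cutoff = 0.5) {
  gt <- default_ground_truth(n_channels, fs = fs,
                             artifact_gains = c(emg = 0, accel = 0, eog = 0),
                             noise_sd = 1, seed = seed)
  generate_session(gt, duration_s = duration_s, fs = fs, seed = seed + 100L,
                   steering_cutoff_hz = cutoff)
}

# artifact-only session: zero kernels, default artifact gains
artifact_session <- function(n_channels = 24, fs = 50, duration_s = 180,
                             seed = 7) {
  gt <- default_ground_truth(n_channels, fs = fs, noise_sd = 1, seed = seed)
  gt$kernels[] <- 0
  generate_session(gt, duration_s = duration_s, fs = fs, seed = seed + 100L)
}

# brute-force centered ridge solution (normal equations), the independent
# oracle for the lagged ridge engine
ridge_oracle <- function(D, y, lambda) {
  y <- as.matrix(y)
  Dc <- sweep(D, 2, colMeans(D))
  yc <- sweep(y, 2, colMeans(y))
  solve(crossprod(Dc) + lambda * diag(ncol(D)), crossprod(Dc, yc))
}
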