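# Synthetic driving-session generator.
#
# Emulates the multimodal recordings of a simulated-driving experiment with a
# known, recoverable ground truth: a smooth band-limited steering signal, EEG
# channels that encode it through anticipatory lag kernels on top of 1/f
# background noise, and nuisance streams (EMG, accelerometers, EOG) that are
# themselves related to steering at (or near) zero lag and leak into the EEG
# through fixed mixing vectors.

#' Generate a band-limited continuous steering signal
#'
#' Low-pass filtered Gaussian noise (order-2 zero-phase Butterworth),
#' demeaned and rescaled to unit variance. Only the smoothness and
#' autocorrelation of the steering trace matter to the downstream analysis,
#' so no vehicle or track model is involved.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Low-pass cutoff in Hz (must be below Nyquist). The
#'   default of 0.5 Hz gives slow, lap-like steering dynamics; raise it when
#'   a broader excitation spectrum is required (e.g. kernel-identification
#'   experiments).
#' @param seed Integer seed; the same arguments and seed give bit-identical
#'   output.
#' @return A `steering_signal` object: list with `values`, `fs`,
#'   `duration_s`.
#' @examples
#' s <- generate_steering(10, 100, 0.5, seed = 1)
#' length(s$values)  # 1000
#' @export
generate_steering <- function(duration_s, fs = 100, cutoff_hz = 0.5, seed = 1) {
  if (!is.finite(duration_s) || duration_s <= 0) {
    stopf("generate_steering(): duration_s must be positive")
  }
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stopf("generate_steering(): cutoff_hz must lie in (0, fs/2)")
  }
  n <- round(duration_s * fs)
  x <- with_seed(seed, stats::rnorm(n))
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  v <- signal::filtfilt(bf, x)
  v <- v - mean(v)
  v <- v / stats::sd(v)
  structure(list(values = v, fs = fs, duration_s = duration_s),
            class = "steering_signal")
}

#' Build a ground-truth lag kernel from Gaussian bumps
#'
#' Sum of Gaussian bumps sampled at `1/fs` over `lag_window`. Under the
#' package's lag convention `eeg(t) = sum_tau k(tau) * s(t - tau)`, a bump at
#' a negative center means the EEG deflection precedes the steering action.
#'
#' @param centers_s Bump centers in seconds (inside `lag_window`).
#' @param widths_s Bump standard deviations in seconds (> 0).
#' @param amplitudes Bump amplitudes (recycled against centers).
#' @param lag_window Length-2 numeric `(tmin_s, tmax_s)`.
#' @param fs Sampling rate in Hz.
#' @return List with `lags_s` (lag grid) and `weights` (kernel values).
#' @export
make_kernel <- function(centers_s, widths_s, amplitudes,
                        lag_window = c(-1.2, 0), fs = 100) {
  if (length(lag_window) != 2L || lag_window[1] > lag_window[2]) {
    stopf("make_kernel(): invalid lag_window")
  }
  k <- max(length(centers_s), length(amplitudes), length(widths_s))
  centers_s <- rep_len(centers_s, k)
  widths_s <- rep_len(widths_s, k)
  amplitudes <- rep_len(amplitudes, k)
  if (any(widths_s <= 0)) stopf("make_kernel(): widths must be positive")
  if (any(centers_s < lag_window[1] | centers_s > lag_window[2])) {
    stopf("make_kernel(): bump center outside lag_window")
  }
  lags <- seq(round(lag_window[1] * fs), round(lag_window[2] * fs)) / fs
  w <- numeric(length(lags))
  for (i in seq_len(k)) {
    w <- w + amplitudes[i] * exp(-(lags - centers_s[i])^2 / (2 * widths_s[i]^2))
  }
  list(lags_s = lags, weights = w)
}

#' 1/f (pink) background noise
#'
#' Spectral shaping of white Gaussian noise: amplitude scaled by
#' `f^(-exponent/2)` so the power spectrum falls as `1/f^exponent`. The DC
#' bin is zeroed; output is rescaled to unit variance. Draws from the current
#' RNG stream.
#'
#' @param n Number of samples.
#' @param exponent Spectral exponent of the power spectrum (default 1).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, exponent = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)  # symmetric frequency index
  scale <- c(0, f[-1]^(-exponent / 2))
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y <- y - mean(y)
  y / stats::sd(y)
}

#' Construct a ground-truth description for the session generator
#'
#' @param kernels Matrix `n_lags x n_channels` of per-channel lag kernels.
#' @param kernel_lags_s Lag grid (seconds) shared by all kernels.
#' @param artifact_gains Named numeric gains (`emg`, `accel`, `eog`), all
#'   `>= 0`; scalar gain applied to each nuisance stream's projection into
#'   the EEG.
#' @param noise_sd Standard deviation of the 1/f background noise.
#' @param eog_lead_s Seconds by which the ocular signal leads steering
#'   (gaze typically precedes the steering action).
#' @param seed Integer seed used for the fixed artifact mixing vectors.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(kernels, kernel_lags_s,
                         artifact_gains = c(emg = 0.5, accel = 1, eog = 0.5),
                         noise_sd = 1, eog_lead_s = 0.4, seed = 1) {
  kernels <- as_matrix(kernels)
  if (nrow(kernels) != length(kernel_lags_s)) {
    stopf("ground_truth(): kernels rows must match kernel_lags_s length")
  }
  gains <- c(emg = 0, accel = 0, eog = 0)
  gains[names(artifact_gains)] <- artifact_gains
  if (any(gains < 0)) stopf("ground_truth(): artifact gains must be >= 0")
  if (noise_sd < 0) stopf("ground_truth(): noise_sd must be >= 0")
  structure(list(kernels = kernels, kernel_lags_s = kernel_lags_s,
                 artifact_gains = gains, noise_sd = noise_sd,
                 eog_lead_s = eog_lead_s, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Default ground truth: anticipatory kernels across channels
#'
#' One Gaussian bump per channel with centers spread over
#' `[-1.0, -0.3]` s (EEG leading the action by 0.3-1.0 s), width 0.15 s,
#' alternating sign, L1-normalised so each channel's kernel output has
#' roughly unit scale for a unit-variance steering signal.
#'
#' @param n_channels Number of EEG channels (default 24; at least 23 are
#'   needed downstream so the CCA noise matrix can be padded to a square
#'   mapping).
#' @param fs Sampling rate in Hz.
#' @param kernel_support Lag interval containing all bump centers.
#' @inheritParams ground_truth
#' @return A `ground_truth` object.
#' @export
default_ground_truth <- function(n_channels = 24, fs = 100,
                                 kernel_support = c(-1.0, -0.3),
                                 artifact_gains = c(emg = 0.5, accel = 1,
                                                    eog = 0.5),
                                 noise_sd = 1, eog_lead_s = 0.4, seed = 1) {
  centers <- seq(kernel_support[1], kernel_support[2],
                 length.out = n_channels)
  window <- c(kernel_support[1] - 0.2, min(0, kernel_support[2] + 0.2))
  kern <- NULL
  for (ch in seq_len(n_channels)) {
    k <- make_kernel(centers[ch], 0.15, (-1)^(ch + 1), window, fs)
    w <- k$weights / sum(abs(k$weights))
    kern <- cbind(kern, w)
    lags <- k$lags_s
  }
  colnames(kern) <- paste0("EEG", seq_len(n_channels))
  ground_truth(kern, lags, artifact_gains = artifact_gains,
               noise_sd = noise_sd, eog_lead_s = eog_lead_s, seed = seed)
}

#' Generate a synthetic driving session
#'
#' Builds temporally aligned streams at a common rate:
#' * EEG: `kernel (x) steering + noise_sd * pinknoise + sum(gain_s * stream_s
#'   %*% M_s)`, with per-stream mixing matrices `M_s` drawn once from the
#'   ground-truth seed (a stationary artifact subspace for CCA to find);
#' * accelerometers (T x 12): smoothed `|dS/dt|` plus small channel noise
#'   (instantaneous with respect to the action);
#' * EMG (T x 4): broadband noise amplitude-modulated by smoothed `|dS/dt|`;
#' * EOG (T x 3): smoothed steering advanced by `eog_lead_s`, plus noise.
#'
#' @param gt A `ground_truth` object.
#' @param duration_s Session length in seconds.
#' @param fs Common sampling rate (Hz); the analysis rate of 100 Hz by
#'   default. A higher raw rate (e.g. 500 Hz) only exercises the resampler.
#' @param seed Integer seed for the stream realisations.
#' @param steering_cutoff_hz Low-pass cutoff of the steering trace.
#' @param nuisance_informative When `TRUE` (default) the nuisance streams
#'   derive from the actual steering trace (muscles, motion and gaze follow
#'   the action). When `FALSE` they derive from an independent surrogate
#'   steering trace with the same spectrum, giving structurally realistic
#'   but steering-uninformative nuisances — the control condition for
#'   combined-decoding analyses.
#' @return List with elements `session` (a `steering_session`) and
#'   `ground_truth`.
#' @export
generate_session <- function(gt, duration_s = 600, fs = 100, seed = 1,
                             steering_cutoff_hz = 0.5,
                             nuisance_informative = TRUE) {
  if (!inherits(gt, "ground_truth")) stopf("generate_session(): gt must be a ground_truth")
  support_s <- diff(range(gt$kernel_lags_s))
  if (duration_s < 2 * support_s) {
    stopf("generate_session(): duration_s must be at least twice the kernel support (%.2f s)",
          support_s)
  }
  n_ch <- ncol(gt$kernels)
  steering <- generate_steering(duration_s, fs, steering_cutoff_hz,
                                seed = seed)
  s <- steering$values
  n <- length(s)

  # nuisance streams follow either the actual steering or an independent
  # surrogate with the same spectrum (uninformative control condition)
  s_nuis <- if (nuisance_informative) s else {
    generate_steering(duration_s, fs, steering_cutoff_hz, seed = seed + 3L)$values
  }

  # instantaneous "motion intensity": smoothed |dS/dt|, zero lag vs action
  ds <- c(0, diff(s_nuis)) * fs
  rate <- moving_average(abs(ds), round(0.25 * fs))
  rate_z <- (rate - mean(rate)) / stats::sd(rate)
  rate_mod <- rate / mean(rate)  # non-negative modulation, mean 1

  # smoothed steering, advanced for the ocular stream (eyes lead the wheel)
  s_smooth <- moving_average(s_nuis, round(0.2 * fs))
  adv <- -round(gt$eog_lead_s * fs)  # x(t - adv) = s_smooth(t + lead)
  s_adv <- shift_signal(s_smooth, adv)

  streams <- with_seed(seed + 1L, {
    accel <- sapply(seq_len(12), function(j) rate_z + 0.15 * stats::rnorm(n))
    emg <- sapply(seq_len(4), function(j) stats::rnorm(n) * (0.2 + rate_mod))
    eog <- sapply(seq_len(3), function(j) {
      c(1, 0.8, 0.6)[j] * s_adv + 0.1 * stats::rnorm(n)
    })
    list(accel = accel, emg = emg, eog = eog)
  })

  # fixed artifact mixing vectors, drawn once from the ground-truth seed
  mix <- with_seed(gt$seed, {
    list(emg = matrix(stats::rnorm(4 * n_ch, sd = 1 / sqrt(4)), 4, n_ch),
         accel = matrix(stats::rnorm(12 * n_ch, sd = 1 / sqrt(12)), 12, n_ch),
         eog = matrix(stats::rnorm(3 * n_ch, sd = 1 / sqrt(3)), 3, n_ch))
  })

  # cortical part: lagged convolution with the ground-truth kernels
  lag_samples <- round(gt$kernel_lags_s * fs)
  D <- vapply(lag_samples, function(k) shift_signal(s, k), numeric(n))
  eeg <- D %*% gt$kernels

  if (gt$noise_sd > 0) {
    eeg <- eeg + gt$noise_sd *
      with_seed(seed + 2L, sapply(seq_len(n_ch), function(ch) pink_noise(n)))
  }
  g <- gt$artifact_gains
  scale_cols <- function(m) sweep(m, 2, apply(m, 2, stats::sd), "/")
  if (g[["emg"]] > 0) eeg <- eeg + g[["emg"]] * scale_cols(streams$emg) %*% mix$emg
  if (g[["accel"]] > 0) eeg <- eeg + g[["accel"]] * scale_cols(streams$accel) %*% mix$accel
  if (g[["eog"]] > 0) eeg <- eeg + g[["eog"]] * scale_cols(streams$eog) %*% mix$eog

  colnames(eeg) <- colnames(gt$kernels)
  colnames(streams$emg) <- paste0("EMG", 1:4)
  colnames(streams$accel) <- paste0("ACC", 1:12)
  colnames(streams$eog) <- paste0("EOG", 1:3)
  edge <- length(lag_samples)

  session <- structure(list(
    eeg = eeg, emg = streams$emg, accel = streams$accel, eog = streams$eog,
    steering = steering, fs = fs, seed = as.integer(seed),
    edge_samples = edge, preprocessed = FALSE, log = list()),
    class = "steering_session")
  check_finite(eeg, "generated EEG")
  list(session = session, ground_truth = gt)
}

#' @export
print.steering_session <- function(x, ...) {
  cat(sprintf("<steering_session> %d samples @ %g Hz | EEG %d ch, EMG %d, accel %d, EOG %d%s\n",
              nrow(x$eeg), x$fs, ncol(x$eeg), ncol(x$emg), ncol(x$accel),
              ncol(x$eog), if (isTRUE(x$preprocessed)) " (preprocessed)" else ""))
  invisible(x)
}
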