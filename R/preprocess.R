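# Signal conditioning: zero-phase band-pass filtering, downsampling,
# re-referencing, noisy-channel rejection, EMG envelope extraction and
# z-scoring.

#' Band specification for zero-phase Butterworth filtering
#'
#' @param low_hz High-pass edge (Hz); `0` disables the high-pass.
#' @param high_hz Low-pass edge (Hz); must be below Nyquist at filter time.
#' @param order Butterworth order applied in *each* direction (the
#'   forward-backward pass doubles the effective order).
#' @return A `band_spec` object.
#' @export
band_spec <- function(low_hz = 0.1, high_hz = 24, order = 4) {
  if (low_hz < 0 || high_hz <= low_hz) stopf("band_spec(): need 0 <= low < high")
  if (order < 1) stopf("band_spec(): order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order),
            class = "band_spec")
}

# Butterworth design as second-order sections (numerically stable even for
# edges far below Nyquist, where the expanded transfer-function form loses
# precision). Analog prototype poles, LP/HP transform, bilinear mapping.
butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stopf("butter_sos(): cutoff must lie in (0, fs/2)")
  wa <- tan(pi * fc / fs)  # prewarped analog cutoff (bilinear, T = 2)
  k <- seq_len(order)
  pa <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # left half-plane
  sa <- if (type == "low") wa * pa else wa / pa
  pd <- (1 + sa) / (1 - sa)
  z0 <- if (type == "low") -1 else 1
  # overall gain fixed at the reference frequency (DC for LP, Nyquist for HP)
  zref <- if (type == "low") 1 else -1
  gain <- abs(prod(zref - pd)) / abs(zref - z0)^order
  # conjugate pole pairs -> biquads (odd orders add one real-pole section)
  pos <- pd[Im(pd) > 1e-12]
  real_p <- Re(pd[abs(Im(pd)) <= 1e-12])
  sections <- lapply(pos, function(p) {
    list(b = c(1, -2 * z0, 1), a = c(1, -2 * Re(p), Mod(p)^2))
  })
  for (p in real_p) {
    sections <- c(sections, list(list(b = c(1, -z0, 0), a = c(1, -p, 0))))
  }
  list(sections = sections, gain = gain)
}

sos_filt <- function(sos, v) {
  for (s in sos$sections) v <- as.numeric(signal::filter(s$b, s$a, v))
  v * sos$gain
}

sos_filtfilt <- function(sos, v) {
  v <- sos_filt(sos, v)
  rev(sos_filt(sos, rev(v)))
}

#' Zero-phase band-pass filter
#'
#' Order-`order` Butterworth high-pass and low-pass applied in cascade as
#' second-order sections, each forward and backward, giving zero net phase
#' and an effective order of `order + order` per edge. Edge transients are
#' suppressed by odd-symmetric reflection padding sized to a few time
#' constants of the slowest band edge.
#'
#' @param x Numeric vector or `T x N` matrix (columns filtered
#'   independently).
#' @param fs Sampling rate (Hz).
#' @param band A [band_spec()].
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, band = band_spec()) {
  if (!inherits(band, "band_spec")) stopf("bandpass_zero_phase(): band must be a band_spec")
  if (band$high_hz >= fs / 2) stopf("bandpass_zero_phase(): band edge >= Nyquist")
  check_finite(x, "filter input")
  lp <- butter_sos(band$order, band$high_hz, fs, "low")
  hp <- if (band$low_hz > 0) butter_sos(band$order, band$low_hz, fs, "high")
        else NULL
  n_in <- if (is.matrix(x)) nrow(x) else length(x)
  f_slow <- if (band$low_hz > 0) band$low_hz else band$high_hz
  pad <- min(n_in - 1L, ceiling(6 * fs / f_slow))
  filt1 <- function(v) {
    n <- length(v)
    ext <- c(2 * v[1] - v[(pad + 1):2],
             v,
             2 * v[n] - v[(n - 1):(n - pad)])
    ext <- sos_filtfilt(lp, ext)
    if (!is.null(hp)) ext <- sos_filtfilt(hp, ext)
    ext[(pad + 1):(pad + n)]
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, filt1)
    dimnames(out) <- dimnames(x)
    out
  } else filt1(x)
}

#' Downsample an already band-limited signal
#'
#' Integer-factor decimation; anti-aliasing is the caller's responsibility
#' (the pipeline band-passes before downsampling).
#'
#' @param x Vector or matrix (rows are samples).
#' @param fs_in,fs_out Input/output sampling rates; `fs_in / fs_out` must be
#'   a positive integer.
#' @return Resampled signal with `round(T * fs_out / fs_in)` samples.
#' @export
resample_to <- function(x, fs_in, fs_out) {
  if (fs_out > fs_in) stopf("resample_to(): upsampling is not supported")
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) > 1e-9) {
    stopf("resample_to(): fs_in / fs_out must be an integer factor")
  }
  ratio <- round(ratio)
  if (is.matrix(x)) x[seq(1, nrow(x), by = ratio), , drop = FALSE]
  else x[seq(1, length(x), by = ratio)]
}

#' Re-reference EEG to the channel average
#'
#' @param eeg `T x N` matrix, `N >= 2`.
#' @return Matrix with each time sample's channel mean removed.
#' @export
average_reference <- function(eeg) {
  eeg <- as_matrix(eeg)
  if (ncol(eeg) < 2) stopf("average_reference(): need at least 2 channels")
  eeg - rowMeans(eeg)
}

#' Flag channels with outlying variance
#'
#' A channel is flagged when its variance exceeds `factor` times the mean
#' variance across all channels.
#'
#' @param eeg `T x N` matrix.
#' @param factor Multiple of the mean variance (default 3).
#' @return Logical mask of length `N` (`TRUE` = noisy).
#' @export
flag_noisy_channels <- function(eeg, factor = 3) {
  eeg <- as_matrix(eeg)
  if (ncol(eeg) < 2) stopf("flag_noisy_channels(): need at least 2 channels")
  v <- apply(eeg, 2, stats::var)
  v > factor * mean(v)
}

#' EMG linear envelope
#'
#' Band-pass filtering (20 Hz to just below Nyquist by default) followed by
#' a centered sliding-window RMS (250 ms default, truncated at the edges).
#'
#' @param x Vector or matrix of raw EMG.
#' @param fs Sampling rate (Hz).
#' @param band Length-2 numeric `(low, high)`; `high` is clipped below
#'   Nyquist.
#' @param win_s RMS window length in seconds.
#' @return Envelope, same shape as `x`, non-negative.
#' @export
emg_envelope <- function(x, fs, band = c(20, min(249, fs / 2 - 1)),
                         win_s = 0.25) {
  win <- round(win_s * fs)
  if (win < 2) stopf("emg_envelope(): window shorter than 2 samples")
  if (fs <= 2 * band[1]) stopf("emg_envelope(): fs too low for the EMG band")
  band <- c(band[1], min(band[2], fs / 2 - 1e-6))
  env1 <- function(v) {
    if (all(v == 0)) return(numeric(length(v)))
    f <- bandpass_zero_phase(v, fs, band_spec(band[1], band[2], order = 4))
    sqrt(moving_average(f^2, win))
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, env1)
    dimnames(out) <- dimnames(x)
    out
  } else env1(x)
}

#' Z-score matrix columns
#'
#' Sample standard deviation convention (`n - 1` denominator).
#'
#' @param X Numeric matrix.
#' @return Matrix with each column of mean 0 and sd 1.
#' @export
zscore_columns <- function(X) {
  X <- as_matrix(X)
  sds <- apply(X, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stopf("zscore_columns(): constant column(s): %s", paste(nm, collapse = ", "))
  }
  scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Preprocess a session
#'
#' The conditioning chain applied to a raw session: EEG (and EOG) band-pass
#' filtered and downsampled to `fs_out`, optional a-priori channel
#' exclusion, re-referencing to the channel average, variance-based noisy
#' channel rejection; EMG kept in two forms (filtered like the EEG, and its
#' envelope); accelerometers z-scored; steering passed through untouched
#' apart from decimation to the common rate.
#'
#' @param session A `steering_session`.
#' @param band [band_spec()] for EEG/EOG filtering; `NULL` skips filtering
#'   (useful when the synthetic content is already inside the band).
#' @param fs_out Analysis rate (Hz).
#' @param exclude_channels Optional character/integer vector of EEG channels
#'   to drop before re-referencing (montage-based exclusion).
#' @param noisy_factor Variance factor for [flag_noisy_channels()].
#' @return The session with conditioned streams, `preprocessed = TRUE`, and
#'   a log of dropped channels and settings. The EMG envelope is stored as
#'   `session$emg_env`.
#' @export
preprocess_session <- function(session, band = band_spec(0.1, 24),
                               fs_out = 100, exclude_channels = NULL,
                               noisy_factor = 3) {
  fs <- session$fs
  eeg <- session$eeg
  eog <- session$eog
  emg <- session$emg
  if (!is.null(band)) {
    eeg <- bandpass_zero_phase(eeg, fs, band)
    eog <- bandpass_zero_phase(eog, fs, band)
    emg_like <- bandpass_zero_phase(emg, fs, band)
  } else emg_like <- emg
  # envelope band: 20 Hz high edge requires fs > 40; at lower (scaled-down)
  # rates the high-pass edge adapts to fs/4
  env_low <- min(20, fs / 4)
  emg_env <- emg_envelope(emg, fs, band = c(env_low, min(249, fs / 2 - 1)))

  if (fs_out < fs) {
    eeg <- resample_to(eeg, fs, fs_out)
    eog <- resample_to(eog, fs, fs_out)
    emg_like <- resample_to(emg_like, fs, fs_out)
    emg_env <- resample_to(emg_env, fs, fs_out)
    accel <- resample_to(session$accel, fs, fs_out)
    sv <- resample_to(session$steering$values, fs, fs_out)
    steering <- structure(list(values = sv, fs = fs_out,
                               duration_s = session$steering$duration_s),
                          class = "steering_signal")
  } else {
    accel <- session$accel
    steering <- session$steering
  }

  dropped_a_priori <- character(0)
  if (!is.null(exclude_channels)) {
    idx <- if (is.character(exclude_channels)) {
      match(exclude_channels, colnames(eeg))
    } else as.integer(exclude_channels)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      dropped_a_priori <- colnames(eeg)[idx]
      eeg <- eeg[, -idx, drop = FALSE]
    }
  }
  eeg <- average_reference(eeg)
  noisy <- flag_noisy_channels(eeg, noisy_factor)
  dropped_noisy <- colnames(eeg)[noisy]
  if (any(noisy)) eeg <- eeg[, !noisy, drop = FALSE]

  out <- session
  out$eeg <- eeg
  out$eog <- eog
  out$emg <- emg_like
  out$emg_env <- emg_env
  out$accel <- zscore_columns(accel)
  out$steering <- steering
  out$fs <- if (fs_out < fs) fs_out else fs
  out$preprocessed <- TRUE
  out$log <- list(
    band = if (is.null(band)) NULL else unclass(band),
    fs_in = fs, fs_out = out$fs, noisy_factor = noisy_factor,
    dropped_a_priori = dropped_a_priori, dropped_noisy = dropped_noisy,
    sd_convention = "sample (n-1)")
  out
}
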