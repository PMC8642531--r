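# Reversible CCA-based removal of EEG components correlated with measured
# nuisance recordings (EMG, accelerometers, EOG).
#
# The nuisance block is padded with white-noise columns until it matches the
# EEG channel count, which makes the EEG-side canonical transform square and
# hence invertible: zeroing selected canonical components and back-projecting
# is then an exact identity when no component is removed. CCA here targets
# instantaneous correlations only — no lagged copies of the nuisance streams
# are included — so anticipated/delayed cortical signal is spared by design.

#' Assemble the nuisance ("noise") matrix
#'
#' Concatenates, in order: EMG filtered like the EEG (4), EMG envelopes (4),
#' accelerometer channels (12), bipolar EOG (3), then unit-variance white
#' noise columns until `n_target` columns are reached.
#'
#' @param emg_like `T x 4` EMG preprocessed like the EEG.
#' @param emg_env `T x 4` EMG envelopes.
#' @param accel `T x 12` accelerometer block.
#' @param eog `T x 3` EOG block.
#' @param n_target Total column count (the EEG channel count); must be at
#'   least the number of real columns.
#' @param seed Seed for the padding columns.
#' @return A `noise_matrix` object: list with `values`, `column_labels`,
#'   `n_real`, `seed`.
#' @export
build_noise_matrix <- function(emg_like, emg_env, accel, eog, n_target,
                               seed = 1) {
  blocks <- list(emg = as_matrix(emg_like), emg_env = as_matrix(emg_env),
                 accel = as_matrix(accel), eog = as_matrix(eog))
  T_n <- unique(vapply(blocks, nrow, integer(1)))
  if (length(T_n) != 1L) stopf("build_noise_matrix(): streams differ in length")
  X <- do.call(cbind, blocks)
  n_real <- ncol(X)
  if (n_target < n_real) {
    stopf("build_noise_matrix(): n_target (%d) < number of real columns (%d)",
          n_target, n_real)
  }
  labels <- c(rep("emg", ncol(blocks$emg)), rep("emg_env", ncol(blocks$emg_env)),
              rep("accel", ncol(blocks$accel)), rep("eog", ncol(blocks$eog)))
  n_pad <- n_target - n_real
  if (n_pad > 0) {
    pad <- with_seed(seed, matrix(stats::rnorm(T_n * n_pad), T_n, n_pad))
    X <- cbind(X, pad)
    labels <- c(labels, rep("white_noise", n_pad))
  }
  colnames(X) <- make.unique(labels)
  structure(list(values = X, column_labels = labels, n_real = n_real,
                 seed = as.integer(seed)),
            class = "noise_matrix")
}

#' Canonical correlation analysis of two multichannel blocks
#'
#' Whitens each centered block by SVD (relative singular-value cutoff
#' `rank_tol`), then takes the SVD of the whitened cross-product. Returns
#' transforms `W1` (noise side) and `W2` (EEG side) such that the columns of
#' `X W1` and `Y W2` are pairwise maximally correlated and mutually
#' uncorrelated within each block, with canonical correlations `rho` in
#' non-increasing order. Sign convention: the largest-magnitude element of
#' each `W2` column is positive (the paired `W1` column is flipped with it).
#'
#' @param X `T x J1` nuisance block.
#' @param Y `T x J2` EEG block.
#' @param rank_tol Relative singular-value cutoff for whitening.
#' @return A `cca_decomposition`: `W1`, `W2`, `rho`, column means of both
#'   blocks, and the numerical ranks used.
#' @export
fit_cca <- function(X, Y, rank_tol = 1e-10) {
  X <- as_matrix(X); Y <- as_matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("fit_cca(): X and Y differ in length")
  if (nrow(X) <= max(ncol(X), ncol(Y))) {
    stopf("fit_cca(): need more samples than channels (T = %d, J = %d)",
          nrow(X), max(ncol(X), ncol(Y)))
  }
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  sx <- svd(Xc); sy <- svd(Yc)
  rx <- sum(sx$d > rank_tol * sx$d[1]); ry <- sum(sy$d > rank_tol * sy$d[1])
  if (rx < ncol(X) || ry < ncol(Y)) {
    message(sprintf("fit_cca(): rank-deficient input (rank X = %d/%d, rank Y = %d/%d); regularised whitening",
                    rx, ncol(X), ry, ncol(Y)))
  }
  Ux <- sx$u[, seq_len(rx), drop = FALSE]
  Uy <- sy$u[, seq_len(ry), drop = FALSE]
  sv <- svd(crossprod(Ux, Uy))
  rho <- pmin(pmax(sv$d, 0), 1)
  W1 <- sx$v[, seq_len(rx), drop = FALSE] %*% (sv$u / sx$d[seq_len(rx)])
  W2 <- sy$v[, seq_len(ry), drop = FALSE] %*% (sv$v / sy$d[seq_len(ry)])
  # deterministic signs: largest-|.| element of each W2 column positive
  for (j in seq_len(ncol(W2))) {
    i <- which.max(abs(W2[, j]))
    if (W2[i, j] < 0) { W2[, j] <- -W2[, j]; W1[, j] <- -W1[, j] }
  }
  structure(list(W1 = W1, W2 = W2, rho = rho, mean_x = mx, mean_y = my,
                 rank_x = rx, rank_y = ry, rank_tol = rank_tol),
            class = "cca_decomposition")
}

#' Select canonical components to remove
#'
#' Marks for removal the leading components whose canonical correlation
#' strictly exceeds the given percentile (linear interpolation) of the
#' distribution of correlations across all components of this decomposition.
#'
#' @param rho Non-increasing canonical correlations.
#' @param percentile Percentile cutoff (default 90; an arbitrary but
#'   conservative choice, kept configurable).
#' @return Logical removal mask (a prefix of the component list).
#' @export
select_noise_components <- function(rho, percentile = 90) {
  if (length(rho) == 0L) stopf("select_noise_components(): empty rho")
  if (is.unsorted(rev(rho))) stopf("select_noise_components(): rho must be non-increasing")
  thr <- pctile(rho, percentile)
  rho > thr
}

#' Remove canonical components and back-project
#'
#' Rotates the EEG into canonical space (`Y W2`), zeroes the masked
#' components, and maps back through `W2^{-1}`; column means are removed
#' before the rotation and restored afterwards. With an empty mask this is
#' the identity — the reason the nuisance block is padded to a square
#' mapping. When the EEG itself is exactly rank-deficient (e.g. after
#' average referencing, which removes one dimension), the centered data lie
#' entirely in the retained subspace and the back-projection uses the
#' pseudo-inverse, which is still an exact identity on the data. A mapping
#' with fewer components than the EEG rank (an unpadded nuisance block)
#' would compress the data and is refused.
#'
#' @param Y `T x J` EEG block (same channel order used in [fit_cca()]).
#' @param decomp A `cca_decomposition` whose component count equals the EEG
#'   rank.
#' @param mask Logical removal mask over components.
#' @return Denoised EEG matrix, same shape as `Y`.
#' @export
remove_components <- function(Y, decomp, mask) {
  Y <- as_matrix(Y)
  W2 <- decomp$W2
  if (ncol(W2) < decomp$rank_y) {
    stopf("remove_components(): only %d components for EEG of rank %d (noise matrix not padded?); back-projection would compress the data",
          ncol(W2), decomp$rank_y)
  }
  if (length(mask) != ncol(W2)) stopf("remove_components(): mask length mismatch")
  Yc <- sweep(Y, 2, decomp$mean_y)
  Z <- Yc %*% W2
  Z[, mask] <- 0
  if (nrow(W2) == ncol(W2)) {
    Yden <- Z %*% solve(W2)
  } else {
    sv <- svd(W2)
    pos <- sv$d > 1e-12 * sv$d[1]
    # Moore-Penrose inverse: exact on the span of the retained subspace
    W2p <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    Yden <- Z %*% W2p
  }
  out <- sweep(Yden, 2, decomp$mean_y, "+")
  dimnames(out) <- dimnames(Y)
  out
}

#' CCA-denoise a preprocessed session
#'
#' Builds the nuisance matrix from the session's EMG (filtered-like-EEG and
#' envelope forms), accelerometer and EOG streams, pads it to the EEG
#' channel count, fits CCA, removes the components above the percentile
#' cutoff and back-projects.
#'
#' @param session A preprocessed `steering_session` (must carry `emg_env`;
#'   run [preprocess_session()] first).
#' @param percentile Component-selection percentile (default 90).
#' @param seed Seed for the white-noise padding.
#' @return List: `session` (with denoised EEG), `decomposition`, `mask`,
#'   `noise_matrix`.
#' @export
denoise_eeg <- function(session, percentile = 90, seed = 1) {
  if (is.null(session$emg_env)) {
    stopf("denoise_eeg(): session has no EMG envelope; run preprocess_session() first")
  }
  nm <- build_noise_matrix(session$emg, session$emg_env, session$accel,
                           session$eog, n_target = ncol(session$eeg),
                           seed = seed)
  dec <- fit_cca(nm$values, session$eeg)
  mask <- select_noise_components(dec$rho, percentile)
  den <- remove_components(session$eeg, dec, mask)
  out <- session
  out$eeg <- den
  out$log$cca <- list(percentile = percentile, n_removed = sum(mask),
                      rho = dec$rho, seed = seed)
  list(session = out, decomposition = dec, mask = mask, noise_matrix = nm)
}
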