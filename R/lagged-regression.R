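# Lagged linear regression (LLR): lag design matrices, ridge solutions,
# cross-validated forward (encoding) and backward (decoding) models, and the
# anticipation sweep.
#
# Lag convention (canonical throughout the package):
#     y(t) = sum_{tau in [tmin, tmax]} w(tau) * x(t - tau)
# For the forward model (x = steering, y = EEG) a negative tau means the EEG
# deflection precedes the steering action. The decoder's user-facing
# anticipation window [-(a + size), -a] — "use only EEG recorded at least a
# seconds before the steering sample" — maps onto engine lags [a, a + size]
# by a single sign flip, performed in `fit_decoder()`.

steering_values <- function(s) {
  if (inherits(s, "steering_signal")) s$values else as.numeric(s)
}

#' Build a lag design matrix
#'
#' Column `(c, tau)` holds channel `c` of `x` delayed by `tau` samples
#' (`x_c(t - tau)`), zero-padded at the edges. Columns are ordered
#' channel-major, lag-minor: all lags of channel 1, then all lags of
#' channel 2, and so on.
#'
#' @param x Vector or `T x C` matrix.
#' @param window Length-2 lag window in seconds `(tmin, tmax)`,
#'   `tmin <= tmax`.
#' @param fs Sampling rate (Hz).
#' @return `T x (C * L)` matrix, `L` the number of integer-sample lags in
#'   the window.
#' @export
lag_design <- function(x, window, fs) {
  x <- as_matrix(x)
  if (length(window) != 2L || window[1] > window[2]) {
    stopf("lag_design(): invalid lag window")
  }
  lags <- seq(round(window[1] * fs), round(window[2] * fs))
  n <- nrow(x)
  if (length(lags) > n) stopf("lag_design(): lag window longer than the signal")
  L <- length(lags)
  C <- ncol(x)
  D <- matrix(0, n, C * L)
  for (c in seq_len(C)) {
    xc <- x[, c]
    for (l in seq_len(L)) {
      D[, (c - 1L) * L + l] <- shift_signal(xc, lags[l])
    }
  }
  attr(D, "lags") <- lags
  attr(D, "n_channels") <- C
  D
}

#' Ridge regression solution
#'
#' Solves `w = (D'D + lambda * M)^{-1} D'y` on internally centered data;
#' the intercept restores the means. `M` is the identity by default, or a
#' first-difference (temporal smoothing) roughness penalty, or any
#' user-supplied `p x p` matrix. At `lambda = 0` a singular system falls
#' back to the minimum-norm pseudo-inverse solution with a warning.
#'
#' @param D `T x p` design matrix.
#' @param y Response vector or `T x K` matrix.
#' @param lambda Non-negative ridge parameter.
#' @param penalty `"identity"`, `"first_difference"`, or a `p x p` matrix.
#'   The first-difference form penalises squared differences of adjacent
#'   lag weights within each channel block (requires `D` from
#'   [lag_design()], whose lag attributes define the blocks).
#' @return List with `weights` (`p x K`) and `bias` (length `K`).
#' @export
ridge_solve <- function(D, y, lambda, penalty = "identity") {
  y <- as_matrix(y)
  if (nrow(D) != nrow(y)) stopf("ridge_solve(): D and y differ in length")
  if (lambda < 0) stopf("ridge_solve(): lambda must be >= 0")
  mux <- colMeans(D); muy <- colMeans(y)
  Dc <- sweep(D, 2, mux); yc <- sweep(y, 2, muy)
  XtX <- crossprod(Dc)
  Xty <- crossprod(Dc, yc)
  M <- penalty_matrix(penalty, ncol(D), attr(D, "lags"), attr(D, "n_channels"))
  A <- XtX + lambda * M
  w <- tryCatch(solve(A, Xty), error = function(e) NULL)
  if (is.null(w)) {
    warning("ridge_solve(): singular system; using pseudo-inverse", call. = FALSE)
    sv <- svd(A)
    pos <- sv$d > 1e-12 * sv$d[1]
    w <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], Xty)) / sv$d[pos])
  }
  bias <- muy - drop(crossprod(w, mux))
  list(weights = w, bias = bias)
}

penalty_matrix <- function(penalty, p, lags = NULL, n_channels = NULL) {
  if (is.matrix(penalty)) {
    if (!all(dim(penalty) == p)) stopf("ridge penalty matrix has wrong dimensions")
    return(penalty)
  }
  if (identical(penalty, "identity")) return(diag(p))
  if (identical(penalty, "first_difference")) {
    if (is.null(lags) || is.null(n_channels)) {
      stopf("first_difference penalty needs a design from lag_design()")
    }
    L <- length(lags)
    d1 <- diff(diag(L))          # (L-1) x L first-difference operator
    B <- crossprod(d1) + 1e-6 * diag(L)  # keep the penalty positive definite
    M <- matrix(0, p, p)
    for (c in seq_len(n_channels)) {
      idx <- (c - 1L) * L + seq_len(L)
      M[idx, idx] <- B
    }
    return(M)
  }
  stopf("unknown penalty '%s'", penalty)
}

#' Default regularisation grid
#'
#' Thirteen log-spaced values, one per decade from `1e-3` to `1e9`.
#' @return Numeric vector.
#' @export
default_lambda_grid <- function() 10^seq(-3, 9)

#' Contiguous cross-validation folds
#'
#' Partitions `[1, n]` into `k` contiguous blocks whose sizes differ by at
#' most one sample. Contiguous (rather than randomly sampled) folds avoid
#' train/test leakage through the strong serial correlation of steering.
#'
#' @param n Number of samples.
#' @param k Number of folds.
#' @return Data frame with `start` and `end` indices per fold.
#' @export
cv_fold_bounds <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2 || k > n) stopf("cv_fold_bounds(): need 2 <= k <= n")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  end <- cumsum(sizes)
  data.frame(start = c(1L, head(end, -1L) + 1L), end = end)
}

# -- internal CV engine -------------------------------------------------------

# Per-fold sufficient statistics of a (standardized) design and response.
fold_stats <- function(D, Y, bounds) {
  lapply(seq_len(nrow(bounds)), function(f) {
    idx <- bounds$start[f]:bounds$end[f]
    Df <- D[idx, , drop = FALSE]
    Yf <- Y[idx, , drop = FALSE]
    list(XtX = crossprod(Df), Xty = crossprod(Df, Yf),
         sx = colSums(Df), sy = colSums(Yf), n = length(idx))
  })
}

train_stats <- function(stats, folds) {
  XtX <- Reduce(`+`, lapply(stats[folds], `[[`, "XtX"))
  Xty <- Reduce(`+`, lapply(stats[folds], `[[`, "Xty"))
  sx <- Reduce(`+`, lapply(stats[folds], `[[`, "sx"))
  sy <- Reduce(`+`, lapply(stats[folds], `[[`, "sy"))
  n <- sum(vapply(stats[folds], `[[`, numeric(1), "n"))
  mux <- sx / n; muy <- sy / n
  list(XtXc = XtX - n * tcrossprod(mux),
       Xtyc = Xty - n * tcrossprod(mux, muy),
       mux = mux, muy = muy, n = n)
}

# Weights for every lambda on one training set. Identity penalty uses a
# single eigendecomposition so the whole grid costs one factorisation.
solve_grid <- function(ts, lambdas, penaltyM = NULL) {
  if (is.null(penaltyM)) {
    e <- eigen(ts$XtXc, symmetric = TRUE)
    d <- pmax(e$values, 0)
    B <- crossprod(e$vectors, ts$Xtyc)
    lapply(lambdas, function(l) e$vectors %*% (B / (d + l)))
  } else {
    lapply(lambdas, function(l) solve(ts$XtXc + l * penaltyM, ts$Xtyc))
  }
}

safe_r <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

# Mean Pearson r across outputs on one held-out fold.
eval_fold <- function(w, ts, D, Y, bounds, f) {
  idx <- bounds$start[f]:bounds$end[f]
  pred <- sweep(D[idx, , drop = FALSE], 2, ts$mux) %*% w
  pred <- sweep(pred, 2, ts$muy, "+")
  mean(vapply(seq_len(ncol(Y)), function(k) {
    safe_r(pred[, k], Y[idx, k])
  }, numeric(1)))
}

#' Cross-validated lagged ridge fit
#'
#' Fits `y(t) = sum_tau w(tau) x(t - tau)` over a lag window with ridge
#' regularisation and k-fold cross-validation on contiguous folds.
#'
#' Two regularisation protocols are available:
#' * `"nested"` (default): for each outer fold, lambda is chosen by
#'   leave-one-training-fold-out validation inside the training folds only,
#'   the model is refit on the full training set at that lambda, and scored
#'   on the held-out fold — no optimistic bias. Needs at least 3 folds.
#' * `"global"`: one lambda maximising the mean held-out correlation across
#'   folds, the simpler protocol of common TRF toolboxes.
#'
#' The final reported model is refit on all data at the modal (nested) or
#' selected (global) lambda. Design columns are standardized before solving
#' and the weights are returned on the original scale.
#'
#' @param x Predictor vector or `T x C` matrix.
#' @param y Response vector or `T x K` matrix.
#' @param window Lag window in seconds (engine convention above).
#' @param fs Sampling rate (Hz).
#' @param lambda_grid Candidate ridge parameters.
#' @param n_folds Number of contiguous folds (>= 2).
#' @param lambda_mode `"nested"` or `"global"`.
#' @param penalty `"identity"` or `"first_difference"` (see [ridge_solve()]).
#' @param direction Stored in the model: `"forward"` or `"backward"`.
#' @return List with `model` (a `trf_model`: weight array `L x C x K`,
#'   bias, lambda, window, fs) and `cv` (a `cv_result`: per-fold r, mean r,
#'   per-fold lambdas, fold boundaries).
#' @export
cross_validated_fit <- function(x, y, window, fs,
                                lambda_grid = default_lambda_grid(),
                                n_folds = 10,
                                lambda_mode = c("nested", "global"),
                                penalty = "identity",
                                direction = "forward") {
  lambda_mode <- match.arg(lambda_mode)
  if (length(lambda_grid) < 1) stopf("cross_validated_fit(): empty lambda grid")
  X <- as_matrix(if (inherits(x, "steering_signal")) x$values else x)
  Y <- as_matrix(if (inherits(y, "steering_signal")) y$values else y)
  if (nrow(X) != nrow(Y)) stopf("cross_validated_fit(): x and y differ in length")
  if (n_folds < 2) stopf("cross_validated_fit(): need at least 2 folds")
  if (lambda_mode == "nested" && n_folds < 3) {
    stopf("cross_validated_fit(): nested lambda selection needs >= 3 folds")
  }
  D <- lag_design(X, window, fs)
  lags <- attr(D, "lags")
  L <- length(lags); C <- ncol(X); K <- ncol(Y)
  col_sd <- apply(D, 2, stats::sd)
  col_sd[col_sd == 0] <- 1
  D <- sweep(D, 2, col_sd, "/")
  attr(D, "lags") <- lags; attr(D, "n_channels") <- C

  bounds <- cv_fold_bounds(nrow(D), n_folds)
  st <- fold_stats(D, Y, bounds)
  penaltyM <- if (identical(penalty, "identity")) NULL
              else penalty_matrix(penalty, ncol(D), lags, C)

  nl <- length(lambda_grid)
  fold_r <- numeric(n_folds)
  lambda_fold <- numeric(n_folds)

  if (lambda_mode == "global") {
    rmat <- matrix(NA_real_, nl, n_folds)
    for (f in seq_len(n_folds)) {
      ts <- train_stats(st, setdiff(seq_len(n_folds), f))
      ws <- solve_grid(ts, lambda_grid, penaltyM)
      for (i in seq_len(nl)) rmat[i, f] <- eval_fold(ws[[i]], ts, D, Y, bounds, f)
    }
    best <- which.max(rowMeans(rmat))
    fold_r <- rmat[best, ]
    lambda_fold[] <- lambda_grid[best]
    lambda_final <- lambda_grid[best]
  } else {
    for (f in seq_len(n_folds)) {
      train <- setdiff(seq_len(n_folds), f)
      inner_r <- matrix(NA_real_, nl, length(train))
      for (j in seq_along(train)) {
        i_val <- train[j]
        ts_in <- train_stats(st, setdiff(train, i_val))
        ws <- solve_grid(ts_in, lambda_grid, penaltyM)
        for (i in seq_len(nl)) {
          inner_r[i, j] <- eval_fold(ws[[i]], ts_in, D, Y, bounds, i_val)
        }
      }
      best <- which.max(rowMeans(inner_r))
      lambda_fold[f] <- lambda_grid[best]
      ts <- train_stats(st, train)
      w <- solve_grid(ts, lambda_grid[best], penaltyM)[[1]]
      fold_r[f] <- eval_fold(w, ts, D, Y, bounds, f)
    }
    tab <- table(lambda_fold)
    modal <- as.numeric(names(tab)[tab == max(tab)])
    lambda_final <- min(modal)
  }

  ts_all <- train_stats(st, seq_len(n_folds))
  w_std <- solve_grid(ts_all, lambda_final, penaltyM)[[1]]
  w_orig <- w_std / col_sd
  mux_orig <- ts_all$mux * col_sd
  bias <- ts_all$muy - drop(crossprod(w_orig, mux_orig))

  model <- structure(list(
    direction = direction,
    window = window,
    lags_s = lags / fs,
    weights = array(w_orig, dim = c(L, C, K)),
    bias = bias,
    lambda = lambda_final,
    fs = fs,
    penalty = penalty), class = "trf_model")
  cv <- structure(list(
    fold_r = fold_r,
    mean_r = mean(fold_r),
    lambda_grid = lambda_grid,
    lambda_selected = lambda_final,
    lambda_per_fold = lambda_fold,
    fold_bounds = bounds,
    lambda_mode = lambda_mode), class = "cv_result")
  list(model = model, cv = cv)
}

#' Predict from a fitted TRF model
#'
#' @param object A `trf_model`.
#' @param x New predictor data (vector or `T x C` matrix) at the model's
#'   sampling rate; for a backward model, pass the EEG.
#' @param ... Unused.
#' @return Predicted response (`T x K` matrix, or vector when `K = 1`).
#' @export
predict.trf_model <- function(object, x, ...) {
  X <- as_matrix(if (inherits(x, "steering_signal")) x$values else x)
  D <- lag_design(X, range(object$lags_s), object$fs)
  K <- dim(object$weights)[3]
  w <- matrix(object$weights, ncol = K)
  pred <- sweep(D %*% w, 2, object$bias, "+")
  if (K == 1) drop(pred) else pred
}

#' @export
print.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<trf_model> %s | window [%g, %g] s | %d lags x %d inputs x %d outputs | lambda = %g\n",
              x$direction, x$window[1], x$window[2], d[1], d[2], d[3], x$lambda))
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mean r = %.3f over %d folds | lambda = %g (%s)\n",
              x$mean_r, length(x$fold_r), x$lambda_selected, x$lambda_mode))
  invisible(x)
}

#' Fit the forward (encoding) model: steering -> EEG
#'
#' Estimates the temporal response function per EEG channel over a lag
#' window (default `[-1.5, 0.5]` s). Negative lags describe EEG activity
#' preceding the steering action.
#'
#' @param steering `steering_signal` or numeric vector.
#' @param eeg `T x N` EEG matrix.
#' @param window Lag window in seconds.
#' @param fs Sampling rate (Hz).
#' @param ... Passed to [cross_validated_fit()].
#' @return List with `model` (weights `L x 1 x N`) and `cv`.
#' @export
fit_encoder <- function(steering, eeg, window = c(-1.5, 0.5), fs, ...) {
  cross_validated_fit(steering_values(steering), eeg, window, fs,
                      direction = "forward", ...)
}

#' Anticipation-window arithmetic
#'
#' Maps an anticipation of `a` seconds and a window size into the decoder's
#' latency window `[-(a + size), -a]`: the decoder may only use EEG recorded
#' at least `a` seconds before the steering sample being predicted.
#'
#' @param anticipation_s Anticipation in seconds (>= 0).
#' @param size_s Window size in seconds (> 0), default 1.5.
#' @return Length-2 numeric window.
#' @examples
#' anticipation_to_window(1.2)  # c(-2.7, -1.2)
#' @export
anticipation_to_window <- function(anticipation_s, size_s = 1.5) {
  if (anticipation_s < 0) stopf("anticipation_to_window(): anticipation must be >= 0")
  if (size_s <= 0) stopf("anticipation_to_window(): size must be > 0")
  c(-(anticipation_s + size_s), -anticipation_s)
}

#' Fit a backward (decoding) model: EEG -> steering
#'
#' Reconstructs the steering signal from EEG restricted to
#' `[t - (a + size), t - a]`, i.e. EEG at least `a` seconds in the past.
#' Scored by Pearson's correlation between predicted and actual steering on
#' held-out folds.
#'
#' @param eeg `T x N` EEG (or any feature) matrix.
#' @param steering `steering_signal` or numeric vector.
#' @param anticipation_s Anticipation in seconds.
#' @param size_s Decoder window size in seconds (default 1.5).
#' @param fs Sampling rate (Hz).
#' @param ... Passed to [cross_validated_fit()].
#' @return List with `model` (user-facing `window = [-(a+size), -a]`) and
#'   `cv`.
#' @export
fit_decoder <- function(eeg, steering, anticipation_s, size_s = 1.5, fs, ...) {
  user_win <- anticipation_to_window(anticipation_s, size_s)
  engine_win <- c(-user_win[2], -user_win[1])  # documented sign flip
  fit <- cross_validated_fit(eeg, steering_values(steering), engine_win, fs,
                             direction = "backward", ...)
  fit$model$window <- user_win
  fit$model$anticipation_s <- anticipation_s
  fit
}

#' Decode steering across a set of anticipations
#'
#' Fits one cross-validated decoder per anticipation (default: the 13-point
#' schedule 0-3 s in 0.3 s steps plus 6 and 12 s) and collects the decoding
#' curve.
#'
#' @inheritParams fit_decoder
#' @param anticipations Anticipations in seconds.
#' @return List with `curve` (data frame: anticipation_s, mean_r, lambda)
#'   and `cv` (list of `cv_result`, one per anticipation).
#' @export
anticipation_sweep <- function(eeg, steering,
                               anticipations = c(seq(0, 3, by = 0.3), 6, 12),
                               size_s = 1.5, fs, ...) {
  if (length(anticipations) == 0) stopf("anticipation_sweep(): empty anticipation list")
  cvs <- vector("list", length(anticipations))
  for (i in seq_along(anticipations)) {
    cvs[[i]] <- fit_decoder(eeg, steering, anticipations[i], size_s, fs, ...)$cv
  }
  curve <- data.frame(
    anticipation_s = anticipations,
    mean_r = vapply(cvs, `[[`, numeric(1), "mean_r"),
    lambda = vapply(cvs, `[[`, numeric(1), "lambda_selected"))
  list(curve = curve, cv = cvs)
}

#' Multimodal (combined) decoding with a time-reversed-EEG control
#'
#' Concatenates EEG, EMG, accelerometer and EOG channels into one design and
#' decodes steering from the combination. With `reverse_eeg = TRUE` the EEG
#' block is time-reversed before lagging (the nuisance streams are left
#' untouched), rendering the EEG temporally meaningless while preserving its
#' marginal statistics — the control quantifying the EEG's own contribution.
#'
#' @param streams Named list with elements `eeg`, `emg`, `accel`, `eog`
#'   (matrices with equal row counts).
#' @param steering `steering_signal` or numeric vector.
#' @param anticipation_s Anticipation in seconds.
#' @param size_s Decoder window size (s).
#' @param fs Sampling rate (Hz).
#' @param reverse_eeg Time-reverse the EEG block before lagging.
#' @param ... Passed to [cross_validated_fit()].
#' @return List with `model` and `cv` (as [fit_decoder()]).
#' @export
combined_decode <- function(streams, steering, anticipation_s, size_s = 1.5,
                            fs, reverse_eeg = FALSE, ...) {
  needed <- c("eeg", "emg", "accel", "eog")
  missing <- setdiff(needed, names(streams))
  if (length(missing)) {
    stopf("combined_decode(): missing stream(s): %s", paste(missing, collapse = ", "))
  }
  eeg <- as_matrix(streams$eeg)
  if (reverse_eeg) eeg <- eeg[rev(seq_len(nrow(eeg))), , drop = FALSE]
  X <- cbind(eeg, as_matrix(streams$emg), as_matrix(streams$accel),
             as_matrix(streams$eog))
  fit_decoder(X, steering, anticipation_s, size_s, fs, ...)
}

#' Pearson product-moment correlation
#'
#' @param a,b Numeric vectors of equal length (>= 2) with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stopf("pearson_r(): unequal lengths")
  if (length(a) < 2) stopf("pearson_r(): need at least 2 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stopf("pearson_r(): undefined for zero-variance input")
  }
  stats::cor(a, b)
}
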