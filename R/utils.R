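# Shared low-level helpers.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Linear-interpolation percentile
#'
#' One percentile definition shared across the package (CCA component
#' selection and null-distribution baselines): linear interpolation between
#' order statistics, i.e. `stats::quantile(..., type = 7)`.
#'
#' @param x Numeric vector.
#' @param percentile Percentile in `[0, 100]`.
#' @return The interpolated percentile value.
#' @export
pctile <- function(x, percentile) {
  if (length(x) == 0L) stopf("pctile(): empty input")
  if (!is.finite(percentile) || percentile < 0 || percentile > 100) {
    stopf("pctile(): percentile must be in [0, 100]")
  }
  unname(stats::quantile(x, probs = percentile / 100, type = 7, names = FALSE))
}

# x(t - k) with zero padding: positive k delays the signal.
shift_signal <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  if (k >= n || k <= -n) return(out)
  if (k >= 0) out[(k + 1L):n] <- x[1L:(n - k)]
  else out[1L:(n + k)] <- x[(1L - k):n]
  out
}

# Centered moving-average smoother with truncated edge windows.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

as_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}
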