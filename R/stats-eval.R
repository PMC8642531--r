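# Null baselines, permutation tests, group-level TRF significance and the
# repeated-measures ANOVA battery.

#' Decoder configuration for null-distribution runs
#'
#' Bundles the decoder settings reused across the observed fit and the
#' shuffled-fold null so that both run under identical conditions.
#'
#' @param anticipation_s Anticipation (s).
#' @param size_s Decoder window size (s).
#' @param fs Sampling rate (Hz).
#' @param lambda_grid Ridge grid.
#' @param n_folds Number of folds.
#' @param lambda_mode `"nested"` or `"global"`.
#' @return A named list of class `decoder_config`.
#' @export
decoder_config <- function(anticipation_s = 0.3, size_s = 1.5, fs = 100,
                           lambda_grid = default_lambda_grid(), n_folds = 10,
                           lambda_mode = "nested") {
  structure(list(anticipation_s = anticipation_s, size_s = size_s, fs = fs,
                 lambda_grid = lambda_grid, n_folds = n_folds,
                 lambda_mode = lambda_mode), class = "decoder_config")
}

decode_with_config <- function(eeg, steering, cfg) {
  fit_decoder(eeg, steering, cfg$anticipation_s, cfg$size_s, cfg$fs,
              lambda_grid = cfg$lambda_grid, n_folds = cfg$n_folds,
              lambda_mode = cfg$lambda_mode)
}

# Reassemble the EEG with fold blocks permuted: steering fold i is paired
# with EEG fold perm[i]. Fold sizes differ by at most one sample; length
# mismatches are fixed by truncation / edge replication.
permute_eeg_folds <- function(eeg, bounds, perm) {
  out <- matrix(0, nrow(eeg), ncol(eeg))
  for (i in seq_len(nrow(bounds))) {
    tgt <- bounds$start[i]:bounds$end[i]
    src <- bounds$start[perm[i]]:bounds$end[perm[i]]
    if (length(src) >= length(tgt)) {
      out[tgt, ] <- eeg[src[seq_along(tgt)], , drop = FALSE]
    } else {
      pad <- c(src, rep(src[length(src)], length(tgt) - length(src)))
      out[tgt, ] <- eeg[pad, , drop = FALSE]
    }
  }
  out
}

#' Shuffled-fold null distribution of decoding correlations
#'
#' Re-runs the cross-validated decoding `n_iter` times, each time after
#' randomising the fold identities: steering fold `i` is paired with a
#' uniformly drawn EEG fold `j` (the identity permutation is allowed). The
#' mean held-out correlation of each run forms the null distribution.
#'
#' @param eeg `T x N` EEG (or feature) matrix.
#' @param steering `steering_signal` or numeric vector.
#' @param cfg A [decoder_config()].
#' @param n_iter Number of null iterations (default 100).
#' @param seed Integer seed for the permutations.
#' @return A `null_distribution`: `values` (length `n_iter`), `n_iter`,
#'   `seed`, and `percentile_baselines` for the 50th, 95th and 99th
#'   percentiles.
#' @export
shuffled_fold_null <- function(eeg, steering, cfg, n_iter = 100, seed = 1) {
  if (n_iter < 1) stopf("shuffled_fold_null(): n_iter must be >= 1")
  eeg <- as_matrix(eeg)
  s <- steering_values(steering)
  bounds <- cv_fold_bounds(nrow(eeg), cfg$n_folds)
  perms <- with_seed(seed, replicate(n_iter, sample(cfg$n_folds),
                                     simplify = FALSE))
  vals <- vapply(perms, function(p) {
    decode_with_config(permute_eeg_folds(eeg, bounds, p), s, cfg)$cv$mean_r
  }, numeric(1))
  baselines <- vapply(c(50, 95, 99), function(p) pctile(vals, p), numeric(1))
  names(baselines) <- c("p50", "p95", "p99")
  structure(list(values = vals, n_iter = n_iter, seed = as.integer(seed),
                 percentile_baselines = baselines, config = cfg),
            class = "null_distribution")
}

#' Percentile baseline of a null distribution
#'
#' Linear-interpolation percentile of the null decoding correlations; the
#' conventional chance level is the 95th percentile (the 99th is also in
#' use and available via `percentile = 99`).
#'
#' @param null A `null_distribution` (or bare numeric vector).
#' @param percentile Percentile in `[0, 100]`.
#' @return Numeric threshold.
#' @export
baseline_threshold <- function(null, percentile = 95) {
  vals <- if (inherits(null, "null_distribution")) null$values else null
  if (length(vals) == 0L) stopf("baseline_threshold(): empty null")
  pctile(vals, percentile)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' @param pvals P-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical mask (`TRUE` = rejected).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stopf("fdr_bh(): p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Permutation p-value against a null distribution
#'
#' Add-one estimator `p = (1 + #{null at least as extreme}) / (n + 1)`;
#' two-tailed compares absolute values.
#'
#' @param observed_r Observed statistic.
#' @param null A `null_distribution` or numeric vector.
#' @param two_tailed Compare `|null| >= |observed|` (default) or
#'   `null >= observed`.
#' @return P-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed_r, null, two_tailed = TRUE) {
  vals <- if (inherits(null, "null_distribution")) null$values else null
  if (length(vals) == 0L) stopf("permutation_pvalue(): empty null")
  extreme <- if (two_tailed) sum(abs(vals) >= abs(observed_r))
             else sum(vals >= observed_r)
  (1 + extreme) / (length(vals) + 1)
}

#' Group-level significance of TRF weights
#'
#' Wilcoxon signed-rank test of the weights against zero at every
#' (lag, channel) across subjects, FDR-corrected across latencies within
#' each channel.
#'
#' @param trf_stack Array `subjects x lags x channels`.
#' @param alpha Significance level after correction.
#' @return Logical `lags x channels` mask.
#' @export
encoder_group_significance <- function(trf_stack, alpha = 0.05) {
  d <- dim(trf_stack)
  if (length(d) != 3L) stopf("encoder_group_significance(): need a subjects x lags x channels array")
  n_subj <- d[1]
  if (n_subj < 2) stopf("encoder_group_significance(): need at least 2 subjects")
  if (n_subj < 6) warning("fewer than 6 subjects: signed-rank test has little power",
                          call. = FALSE)
  p <- matrix(NA_real_, d[2], d[3])
  for (ch in seq_len(d[3])) {
    for (l in seq_len(d[2])) {
      x <- trf_stack[, l, ch]
      p[l, ch] <- suppressWarnings(
        stats::wilcox.test(x, mu = 0, exact = n_subj < 10,
                           correct = TRUE)$p.value)
    }
  }
  mask <- matrix(FALSE, d[2], d[3])
  for (ch in seq_len(d[3])) mask[, ch] <- fdr_bh(p[, ch], alpha)
  attr(mask, "p") <- p
  mask
}

#' Repeated-measures ANOVA (one- or two-way)
#'
#' One-way: `data` is a `subjects x levels` matrix. Two-way: a
#' `subjects x levels1 x levels2` array; both main effects and the
#' interaction are reported. Backed by a multivariate linear model with a
#' within-subject design (`car::Anova`, type III). For effects with at
#' least 3 levels, Mauchly's sphericity test is run and the
#' Greenhouse-Geisser correction is applied to the reported p-value when
#' sphericity is violated (`mauchly_p < 0.05`). Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Matrix or 3-d array as above (no missing cells).
#' @return Data frame of class `rm_anova` with one row per effect:
#'   `effect`, `F`, `df_effect`, `df_error`, `p` (uncorrected), `eta_p2`,
#'   `mauchly_p`, `gg_epsilon`, `p_gg`, `gg_applied`, `p_reported`.
#' @export
rm_anova <- function(data) {
  if (any(!is.finite(data))) stopf("rm_anova(): missing or non-finite cells")
  d <- dim(data)
  if (is.matrix(data)) {
    if (d[2] < 2) stopf("rm_anova(): need at least 2 levels")
    idata <- data.frame(level = factor(seq_len(d[2])))
    idesign <- ~level
    Y <- data
    effects <- "level"
  } else if (length(d) == 3L) {
    Y <- matrix(data, d[1], d[2] * d[3])  # f1 varies fastest, matching expand.grid
    idata <- expand.grid(f1 = factor(seq_len(d[2])), f2 = factor(seq_len(d[3])))
    idesign <- ~ f1 * f2
    effects <- c("f1", "f2", "f1:f2")
  } else stopf("rm_anova(): data must be a matrix or 3-d array")
  if (d[1] < 2) stopf("rm_anova(): need at least 2 subjects")

  mlm <- stats::lm(Y ~ 1)
  aov_res <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  s <- summary(aov_res, multivariate = FALSE)
  ut <- s$univariate.tests
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments

  rows <- lapply(effects, function(eff) {
    ss_eff <- ut[eff, "Sum Sq"]
    ss_err <- ut[eff, "Error SS"]
    mauchly_p <- if (!is.null(sph) && eff %in% rownames(sph)) {
      sph[eff, "p-value"]
    } else NA_real_
    gg_eps <- if (!is.null(adj) && eff %in% rownames(adj)) {
      adj[eff, "GG eps"]
    } else NA_real_
    p_gg <- if (!is.null(adj) && eff %in% rownames(adj)) {
      adj[eff, "Pr(>F[GG])"]
    } else NA_real_
    gg_applied <- isTRUE(!is.na(mauchly_p) && mauchly_p < 0.05)
    p_unc <- ut[eff, "Pr(>F)"]
    data.frame(
      effect = eff,
      F = ut[eff, "F value"],
      df_effect = ut[eff, "num Df"],
      df_error = ut[eff, "den Df"],
      p = p_unc,
      eta_p2 = ss_eff / (ss_eff + ss_err),
      mauchly_p = mauchly_p,
      gg_epsilon = gg_eps,
      p_gg = p_gg,
      gg_applied = gg_applied,
      p_reported = if (gg_applied && !is.na(p_gg)) p_gg else p_unc,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rm_anova", class(out))
  out
}
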