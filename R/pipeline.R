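# End-to-end experiment runner, configuration and session persistence.

#' Pipeline configuration
#'
#' Defaults follow the reference analysis settings: 0.1-24 Hz band, 100 Hz
#' analysis rate, 90th-percentile CCA component cutoff, encoder window
#' `[-1.5, 0.5]` s, the 13-point anticipation schedule, ridge grid
#' `1e-3..1e9`, 10 folds, 100 null iterations, 95th-percentile baseline.
#' Any field may be overridden for scaled-down runs.
#'
#' @param band Length-2 numeric `(low, high)` in Hz, or `NULL` to skip
#'   filtering.
#' @param fs_out Analysis sampling rate (Hz).
#' @param cca_percentile CCA component-selection percentile.
#' @param encoder_window Encoder lag window (s).
#' @param decoder_size_s Decoder window size (s).
#' @param anticipations Anticipation schedule (s).
#' @param lambda_grid Ridge grid.
#' @param n_folds Cross-validation folds.
#' @param null_n_iter Shuffled-fold null iterations.
#' @param baseline_percentile Null baseline percentile.
#' @param null_anticipation_s Anticipation at which the null is computed.
#' @param lambda_mode `"nested"` or `"global"`.
#' @param denoise Run CCA denoising.
#' @param decoder_channels Optional number of EEG channels used by the
#'   decoding stages (the leading channels after preprocessing). Denoising
#'   always uses the full montage; limiting the decoder's channel count
#'   keeps the lagged design tractable in scaled-down runs. `NULL` = all.
#' @param seed Top-level seed; every random draw in a run derives from it.
#' @param generator List of [generate_session()] arguments used when no
#'   session is supplied (`n_channels`, `duration_s`, `fs`, plus any
#'   [default_ground_truth()] fields).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(band = c(0.1, 24), fs_out = 100,
                            cca_percentile = 90,
                            encoder_window = c(-1.5, 0.5),
                            decoder_size_s = 1.5,
                            anticipations = c(seq(0, 3, by = 0.3), 6, 12),
                            lambda_grid = default_lambda_grid(),
                            n_folds = 10, null_n_iter = 100,
                            baseline_percentile = 95,
                            null_anticipation_s = 0.3,
                            lambda_mode = "nested",
                            denoise = TRUE, decoder_channels = NULL,
                            seed = 1,
                            generator = list(n_channels = 24,
                                             duration_s = 600, fs = 100)) {
  structure(list(band = band, fs_out = fs_out, cca_percentile = cca_percentile,
                 encoder_window = encoder_window,
                 decoder_size_s = decoder_size_s,
                 anticipations = anticipations, lambda_grid = lambda_grid,
                 n_folds = n_folds, null_n_iter = null_n_iter,
                 baseline_percentile = baseline_percentile,
                 null_anticipation_s = null_anticipation_s,
                 lambda_mode = lambda_mode, denoise = denoise,
                 decoder_channels = decoder_channels,
                 seed = as.integer(seed), generator = generator),
            class = "pipeline_config")
}

#' Run the full experiment
#'
#' Preprocess -> (optional) CCA denoise -> encoder fit -> anticipation sweep
#' (raw EEG and, when denoising is on, denoised EEG) -> shuffled-fold null
#' baseline -> permutation p-values. All seeds derive from `config$seed` and
#' the run is deterministic. When `out_dir` is given, tabular outputs (CSV)
#' and a JSON report are written there.
#'
#' @param config A [pipeline_config()].
#' @param session Optional `steering_session`; generated from
#'   `config$generator` when `NULL`.
#' @param out_dir Optional output directory.
#' @return A report list: config, stage timings, encoder CV, sweep curves,
#'   null baseline, permutation p-values.
#' @export
run_experiment <- function(config = pipeline_config(), session = NULL,
                           out_dir = NULL) {
  t0 <- proc.time()[3]
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- round(proc.time()[3] - t0, 2)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("run_experiment(): stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if (is.null(session)) {
    session <- stage("simulate", {
      gen <- config$generator
      gt <- do.call(default_ground_truth, c(
        list(n_channels = gen$n_channels %||% 24,
             fs = gen$fs %||% config$fs_out,
             seed = config$seed),
        gen[intersect(names(gen), c("kernel_support", "artifact_gains",
                                    "noise_sd", "eog_lead_s"))]))
      generate_session(gt, duration_s = gen$duration_s %||% 600,
                       fs = gen$fs %||% config$fs_out,
                       seed = config$seed)$session
    })
  }
  tick("simulate")

  band <- if (is.null(config$band)) NULL
          else if (inherits(config$band, "band_spec")) config$band
          else band_spec(config$band[1], config$band[2])
  pre <- stage("preprocess", preprocess_session(session, band = band,
                                                fs_out = config$fs_out))
  tick("preprocess")

  den <- NULL
  if (isTRUE(config$denoise)) {
    den <- stage("denoise", denoise_eeg(pre, percentile = config$cca_percentile,
                                        seed = config$seed + 10L))
    tick("denoise")
  }

  dec_cols <- function(eeg) {
    if (is.null(config$decoder_channels)) eeg
    else eeg[, seq_len(min(config$decoder_channels, ncol(eeg))), drop = FALSE]
  }

  enc <- stage("encoder", fit_encoder(pre$steering, pre$eeg,
                                      window = config$encoder_window,
                                      fs = pre$fs,
                                      lambda_grid = config$lambda_grid,
                                      n_folds = config$n_folds,
                                      lambda_mode = config$lambda_mode))
  tick("encoder")

  sweep_raw <- stage("sweep_eeg", anticipation_sweep(
    dec_cols(pre$eeg), pre$steering, anticipations = config$anticipations,
    size_s = config$decoder_size_s, fs = pre$fs,
    lambda_grid = config$lambda_grid, n_folds = config$n_folds,
    lambda_mode = config$lambda_mode))
  tick("sweep_eeg")

  sweep_den <- NULL
  if (!is.null(den)) {
    sweep_den <- stage("sweep_eeg_den", anticipation_sweep(
      dec_cols(den$session$eeg), pre$steering, anticipations = config$anticipations,
      size_s = config$decoder_size_s, fs = pre$fs,
      lambda_grid = config$lambda_grid, n_folds = config$n_folds,
      lambda_mode = config$lambda_mode))
    tick("sweep_eeg_den")
  }

  cfg_dec <- decoder_config(anticipation_s = config$null_anticipation_s,
                            size_s = config$decoder_size_s, fs = pre$fs,
                            lambda_grid = config$lambda_grid,
                            n_folds = config$n_folds,
                            lambda_mode = config$lambda_mode)
  null <- stage("null", shuffled_fold_null(dec_cols(pre$eeg), pre$steering, cfg_dec,
                                           n_iter = config$null_n_iter,
                                           seed = config$seed + 20L))
  baseline <- baseline_threshold(null, config$baseline_percentile)
  tick("null")

  pvals <- vapply(sweep_raw$cv, function(cv) {
    permutation_pvalue(cv$mean_r, null)
  }, numeric(1))

  cfg_plain <- unclass(config)
  if (inherits(cfg_plain$band, "band_spec")) {
    cfg_plain$band <- unclass(cfg_plain$band)
  }
  report <- list(
    config = cfg_plain,
    seed = config$seed,
    channels = colnames(pre$eeg),
    dropped_channels = pre$log$dropped_noisy,
    encoder = list(mean_r = enc$cv$mean_r, lambda = enc$cv$lambda_selected),
    sweep_eeg = sweep_raw$curve,
    sweep_eeg_den = if (!is.null(sweep_den)) sweep_den$curve else NULL,
    cca = if (!is.null(den)) list(n_removed = sum(den$mask),
                                  rho = den$decomposition$rho) else NULL,
    null_values = null$values,
    baseline = baseline,
    baseline_percentile = config$baseline_percentile,
    p_permutation = data.frame(anticipation_s = config$anticipations,
                               p = pvals),
    timings_s = timings,
    denoise_enabled = isTRUE(config$denoise))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sweep_raw$curve,
                     file.path(out_dir, "sweep_eeg.csv"), row.names = FALSE)
    if (!is.null(sweep_den)) {
      utils::write.csv(sweep_den$curve,
                       file.path(out_dir, "sweep_eeg_den.csv"), row.names = FALSE)
    }
    utils::write.csv(report$p_permutation,
                     file.path(out_dir, "permutation_pvalues.csv"),
                     row.names = FALSE)
    enc_w <- enc$model$weights[, 1, ]
    enc_df <- data.frame(lag_s = enc$model$lags_s, enc_w)
    names(enc_df) <- c("lag_s", report$channels)
    utils::write.csv(enc_df, file.path(out_dir, "encoder_trf.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      report[c("config", "seed", "encoder", "baseline",
               "baseline_percentile", "timings_s", "denoise_enabled",
               "dropped_channels")],
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, null = "null")
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- session persistence ------------------------------------------------------

write_numeric_csv <- function(m, path) {
  m <- as_matrix(m)
  header <- paste(colnames(m) %||% paste0("V", seq_len(ncol(m))), collapse = ",")
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(header, rows), path)
}

read_numeric_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as.matrix(df)
}

#' Save / load a session container
#'
#' The container is a directory holding one full-precision CSV per stream
#' (`eeg.csv`, `emg.csv`, `accel.csv`, `eog.csv`, `steering.csv` with
#' columns `time_s, angle`) plus `meta.json` with sampling rates, labels,
#' seed and the preprocessing flag. Values are written with 17 significant
#' digits, so the round trip is bit-exact for doubles.
#'
#' @param session A `steering_session`.
#' @param path Directory path (created if needed).
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_numeric_csv(session$eeg, file.path(path, "eeg.csv"))
  write_numeric_csv(session$emg, file.path(path, "emg.csv"))
  write_numeric_csv(session$accel, file.path(path, "accel.csv"))
  write_numeric_csv(session$eog, file.path(path, "eog.csv"))
  s <- session$steering
  st <- cbind(time_s = (seq_along(s$values) - 1) / s$fs, angle = s$values)
  write_numeric_csv(st, file.path(path, "steering.csv"))
  if (!is.null(session$emg_env)) {
    write_numeric_csv(session$emg_env, file.path(path, "emg_env.csv"))
  }
  meta <- list(fs = session$fs, steering_fs = s$fs,
               steering_duration_s = s$duration_s,
               eeg_labels = colnames(session$eeg),
               seed = session$seed,
               preprocessed = isTRUE(session$preprocessed),
               edge_samples = session$edge_samples)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stopf("load_session(): missing meta.json in %s", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("fs", "steering_fs")) {
    if (is.null(meta[[field]])) stopf("load_session(): meta.json lacks '%s'", field)
  }
  need <- c("eeg", "emg", "accel", "eog", "steering")
  for (stream in need) {
    if (!file.exists(file.path(path, paste0(stream, ".csv")))) {
      stopf("load_session(): missing required stream '%s'", stream)
    }
  }
  st <- read_numeric_csv(file.path(path, "steering.csv"))
  if (is.unsorted(st[, "time_s"], strictly = TRUE)) {
    stopf("load_session(): steering time axis is not strictly increasing")
  }
  steering <- structure(list(values = unname(st[, "angle"]),
                             fs = as.numeric(meta$steering_fs),
                             duration_s = as.numeric(
                               meta$steering_duration_s %||%
                                 (nrow(st) / meta$steering_fs))),
                        class = "steering_signal")
  env_path <- file.path(path, "emg_env.csv")
  structure(list(
    eeg = read_numeric_csv(file.path(path, "eeg.csv")),
    emg = read_numeric_csv(file.path(path, "emg.csv")),
    accel = read_numeric_csv(file.path(path, "accel.csv")),
    eog = read_numeric_csv(file.path(path, "eog.csv")),
    emg_env = if (file.exists(env_path)) read_numeric_csv(env_path) else NULL,
    steering = steering, fs = as.numeric(meta$fs),
    seed = meta$seed, edge_samples = meta$edge_samples,
    preprocessed = isTRUE(meta$preprocessed), log = list()),
    class = "steering_session")
}
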