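#' Patient-wise evaluation
#'
#' MAE and MAPE between a predicted and a reference heart-rate series,
#' computed per subject over jointly-defined windows and then aggregated
#' across subjects (never pooled over windows), mirroring the patient-wise
#' reporting convention.
#'
#' @name evaluation
NULL

# align two hr_series data frames on window_index, keeping jointly-defined
# windows only
align_series <- function(pred, ref) {
  m <- merge(pred[, c("window_index", "hr_bpm")],
             ref[, c("window_index", "hr_bpm")],
             by = "window_index", suffixes = c("_pred", "_ref"))
  m[!is.na(m$hr_bpm_pred) & !is.na(m$hr_bpm_ref), ]
}

#' Mean absolute error between two heart-rate series
#'
#' `(1/m) * sum |HR_pred_t - HR_true_t|` over the `m` windows where both
#' series are defined; windows undefined on either side are skipped and `m`
#' reduced accordingly.
#'
#' @param pred,ref data frames with columns `window_index` and `hr_bpm`.
#' @return MAE in bpm, or `NA` (with a warning) when no window is jointly
#'   defined.
#' @export
hr_mae <- function(pred, ref) {
  m <- align_series(pred, ref)
  if (nrow(m) == 0) {
    warning("no jointly-defined windows: MAE undefined")
    return(NA_real_)
  }
  mean(abs(m$hr_bpm_pred - m$hr_bpm_ref))
}

#' Mean absolute percentage error between two heart-rate series
#'
#' `100 * (1/m) * sum |HR_pred_t - HR_true_t| / HR_true_t` over
#' jointly-defined windows.
#'
#' @inheritParams hr_mae
#' @return MAPE in percent, or `NA` with a warning when no window is jointly
#'   defined; errors if any included reference value is non-positive.
#' @export
hr_mape <- function(pred, ref) {
  m <- align_series(pred, ref)
  if (nrow(m) == 0) {
    warning("no jointly-defined windows: MAPE undefined")
    return(NA_real_)
  }
  if (any(m$hr_bpm_ref <= 0)) stop("non-positive reference heart rate")
  100 * mean(abs(m$hr_bpm_pred - m$hr_bpm_ref) / m$hr_bpm_ref)
}

#' Aggregate per-subject values
#'
#' Arithmetic mean and sample (n-1) standard deviation across subjects. With
#' a single subject the SD is reported as 0 and flagged.
#'
#' @param values numeric vector, one value per subject.
#' @return List with `mean`, `sd` and `degenerate` (TRUE when n = 1).
#' @export
aggregate_subjects <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no subject values to aggregate")
  if (length(values) == 1)
    return(list(mean = values, sd = 0, degenerate = TRUE))
  list(mean = mean(values), sd = stats::sd(values), degenerate = FALSE)
}

#' Evaluate one method over a cohort
#'
#' @param per_subject list of data frames, one per subject, each holding a
#'   `pred` and `ref` pair of series (see [hr_mae]).
#' @param method label (`"algorithm"` or `"cnn"`).
#' @return An `eval_report`: per-subject table (subject_id, mae_bpm,
#'   mape_pct, n_windows_used, n_windows_excluded) plus patient-wise
#'   aggregates.
#' @export
eval_report <- function(per_subject, method = c("algorithm", "cnn")) {
  method <- match.arg(method)
  rows <- lapply(per_subject, function(s) {
    joint <- align_series(s$pred, s$ref)
    data.frame(subject_id = s$pred$subject_id[1],
               mae_bpm = hr_mae(s$pred, s$ref),
               mape_pct = hr_mape(s$pred, s$ref),
               n_windows_used = nrow(joint),
               n_windows_excluded = nrow(s$pred) - nrow(joint))
  })
  tab <- do.call(rbind, rows)
  structure(list(method = method, per_subject = tab,
                 aggregate = list(mae = aggregate_subjects(tab$mae_bpm),
                                  mape = aggregate_subjects(tab$mape_pct))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> method: %s, %d subjects\n", x$method,
              nrow(x$per_subject)))
  cat(sprintf("  patient-wise MAE : %.2f bpm (sd %.2f)\n",
              x$aggregate$mae$mean, x$aggregate$mae$sd))
  cat(sprintf("  patient-wise MAPE: %.2f %% (sd %.2f)\n",
              x$aggregate$mape$mean, x$aggregate$mape$sd))
  invisible(x)
}

#' Default pipeline configuration
#'
#' Flat key-value configuration shared by the pipeline stages; any subset can
#' be overridden.
#'
#' @return Named list of configuration keys.
#' @export
default_config <- function() {
  list(filter.low_hz = 2, filter.high_hz = 10, filter.order = 2,
       window.samples = 400L, window.max_repaired_frac = 0.25,
       repair.spike_z = 5, repair.sat_run_min = 3L,
       jpeak.coarse_cutoff_hz = 6, jpeak.search_halfwidth_s = 0.25,
       jpeak.suppress_span_s = 1, jpeak.min_peak_frac = 0.1,
       ppg.prominence = 0.3, ppg.refractory_s = 0.33,
       cnn.epochs = 30L, cnn.batch_size = 64L, cnn.l2 = 1e-4,
       cnn.width_factor = 1, cnn.train_fraction = 2 / 3,
       simulate.subjects = 6L, simulate.duration_s = 600,
       seed = 1L)
}

# belt recording -> repaired, filtered, segmented windows
preprocess_belt <- function(belt, profile_adc, cfg) {
  rep_rec <- repair(belt, adc_limits = profile_adc,
                    sat_run_min = cfg$repair.sat_run_min,
                    spike_z = cfg$repair.spike_z)
  filt <- bandpass(rep_rec, cfg$filter.low_hz, cfg$filter.high_hz,
                   cfg$filter.order)
  segment(filt, cfg$window.samples, cfg$window.max_repaired_frac)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a cohort, preprocesses every belt stream (repair, band-pass,
#' windowing), derives the PPG reference series, runs the algorithmic
#' detector on every subject and — when `method` includes `"cnn"` — trains
#' the network on a subject-level split and predicts on the held-out
#' subjects, then reports patient-wise MAE/MAPE per method.
#'
#' @param config configuration list as from [default_config]; missing keys
#'   take their defaults.
#' @param method methods to run, subset of `c("algorithm", "cnn")`.
#' @param sessions optional pre-generated cohort (from [generate_cohort]);
#'   simulated per the config when `NULL`.
#' @param cnn_targets `"ppg"` (train on PPG-reference heart rates, as with
#'   real data) or `"ground_truth"` (train on simulator truth).
#' @return List of `eval_report`s, one per method, plus `sessions` and, for
#'   the CNN, the split and training history.
#' @export
run_pipeline <- function(config = list(), method = c("algorithm", "cnn"),
                         sessions = NULL, cnn_targets = "ppg") {
  cfg <- utils::modifyList(default_config(), config)
  method <- match.arg(method, several.ok = TRUE)
  if (is.null(sessions))
    sessions <- generate_cohort(cfg$simulate.subjects, cfg$simulate.duration_s,
                                seed = cfg$seed)
  prep <- lapply(sessions, function(s) {
    ws <- preprocess_belt(s$belt, s$profile$adc_limits, cfg)
    ref <- ppg_reference_hr(s$ppg, cfg$window.samples,
                            prominence = cfg$ppg.prominence,
                            refractory_s = cfg$ppg.refractory_s)
    list(session = s, ws = ws, ref = ref)
  })
  out <- list(sessions = sessions)
  if ("algorithm" %in% method) {
    per_subject <- lapply(prep, function(p) {
      det <- detect_jpeaks(p$ws, cfg$jpeak.coarse_cutoff_hz,
                           cfg$jpeak.search_halfwidth_s,
                           cfg$jpeak.suppress_span_s,
                           cfg$jpeak.min_peak_frac)
      list(pred = hr_series(det, p$ws, "algorithm"), ref = p$ref$hr)
    })
    out$algorithm <- eval_report(per_subject, "algorithm")
  }
  if ("cnn" %in% method) {
    ids <- vapply(prep, function(p) p$ws$subject_id, character(1))
    split <- split_subjects(ids, cfg$cnn.train_fraction, cfg$seed)
    target_of <- function(p) {
      if (cnn_targets == "ground_truth") {
        truth_hr_series(p$session$beats, p$ws)$hr_bpm
      } else p$ref$hr$hr_bpm
    }
    norm_ws <- lapply(prep, function(p) normalize_windows(p$ws))
    tr <- which(ids %in% split$train)
    Xtr <- do.call(rbind, lapply(tr, function(i) {
      w <- norm_ws[[i]]
      w$windows[!w$excluded, , drop = FALSE]
    }))
    ytr <- unlist(lapply(tr, function(i) {
      target_of(prep[[i]])[!norm_ws[[i]]$excluded]
    }))
    normalizer <- target_normalizer(ytr)
    model <- cnn_build(cnn_reference_spec(cfg$cnn.width_factor),
                       seed = cfg$seed)
    fit <- cnn_fit(model, Xtr, ytr, normalizer, epochs = cfg$cnn.epochs,
                   batch_size = cfg$cnn.batch_size,
                   l2_kernel_penalty = cfg$cnn.l2, seed = cfg$seed)
    te <- which(ids %in% split$test)
    per_subject <- lapply(te, function(i) {
      pred <- cnn_predict_hr(fit$model, norm_ws[[i]], normalizer)
      list(pred = pred, ref = prep[[i]]$ref$hr)
    })
    out$cnn <- eval_report(per_subject, "cnn")
    out$cnn_split <- split
    out$cnn_history <- fit$history
    out$cnn_fit <- fit
  }
  out
}

#' Ground-truth per-window heart-rate series
#'
#' Converts simulator beat times into the same per-window HR representation
#' the detectors produce, for exact scoring.
#'
#' @param beats ground-truth beat times in seconds.
#' @param ws the window set defining the timeline.
#' @return Data frame as from [hr_series] with source `"ground_truth"`.
#' @export
truth_hr_series <- function(beats, ws) {
  fs <- ws$fs_hz
  window <- ncol(ws$windows)
  by_window <- lapply(seq_len(nrow(ws$windows)), function(w) {
    t0 <- (ws$start_indices[w] - 1) / fs
    inside <- beats >= t0 & beats < t0 + window / fs
    round((beats[inside] - t0) * fs) + 1L
  })
  hr_series(list(by_window = by_window), ws, source = "ground_truth")
}
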