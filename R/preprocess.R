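#' Pre-elaboration of raw recordings
#'
#' Saturation/outlier repair, 2-10 Hz second-order Butterworth band-pass,
#' 400-sample windowing, per-window normalization, and 100 -> 50 Hz PPG
#' resampling. Together these turn raw reassembled recordings into the
#' filtered, windowed, normalized inputs both heart-rate cores consume.
#'
#' @name preprocessing
NULL

# runs of consecutive TRUE values as an n x 2 matrix of (start, end) indices
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect saturation-artifact spans
#'
#' Runs of at least `run_min` consecutive samples pinned at an ADC limit are
#' taken as saturation; runs separated by less than `bridge_s` seconds are
#' merged into one artifact span, since a single movement episode typically
#' rails the sensor repeatedly with brief excursions in between.
#'
#' @param rec a [recording].
#' @param adc_limits length-2 numeric (min_code, max_code).
#' @param run_min minimum saturated run length in samples (default 3).
#' @param bridge_s merge gap in seconds (default 1).
#' @return Two-column matrix of (start, end) sample indices, possibly empty.
#' @export
detect_saturation_spans <- function(rec, adc_limits, run_min = 3L,
                                    bridge_s = 1) {
  at_limit <- rec$samples <= adc_limits[1] | rec$samples >= adc_limits[2]
  runs <- true_runs(at_limit)
  if (nrow(runs) == 0) return(runs)
  runs <- runs[runs[, 2] - runs[, 1] + 1L >= run_min, , drop = FALSE]
  if (nrow(runs) <= 1) return(runs)
  gap_max <- bridge_s * rec$fs_hz
  merged <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, 1] - merged[nrow(merged), 2] <= gap_max) {
      merged[nrow(merged), 2] <- runs[i, 2]
    } else merged <- rbind(merged, runs[i, ])
  }
  merged
}

#' Repair saturation runs and isolated spikes
#'
#' Two defect classes are replaced by linear interpolation between the nearest
#' intact samples and flagged `repaired`, keeping the overall trend as
#' seamless as possible: (a) saturation spans (see
#' [detect_saturation_spans]); (b) isolated outlier spikes whose robust
#' z-score against a 2 s rolling median exceeds `spike_z`. Samples already
#' flagged `missing` are interpolated the same way. All `ok` samples are left
#' bit-identical.
#'
#' @param rec a [recording].
#' @param adc_limits saturation codes; `NULL` disables saturation repair.
#' @param sat_run_min minimum saturated run length, samples (default 3).
#' @param spike_z robust z-score threshold for spikes (default 5).
#' @return The recording with defective samples interpolated and quality
#'   updated.
#' @export
repair <- function(rec, adc_limits = NULL, sat_run_min = 3L, spike_z = 5) {
  stopifnot(rec$fs_hz > 0)
  n <- length(rec$samples)
  bad <- rec$quality == "missing"
  if (!is.null(adc_limits)) {
    spans <- detect_saturation_spans(rec, adc_limits, sat_run_min,
                                     bridge_s = 0)
    for (i in seq_len(nrow(spans))) bad[spans[i, 1]:spans[i, 2]] <- TRUE
  }
  # spikes: robust z against a 2 s rolling median, scaled by global MAD of
  # the residual; evaluated only on currently-good samples
  k <- 2 * floor(rec$fs_hz) + 1
  if (n > k) {
    med <- stats::runmed(rec$samples, k, endrule = "median")
    resid <- rec$samples - med
    s <- stats::mad(resid[!bad])
    # noiseless signals have zero MAD; fall back to a tiny scale floor so a
    # lone spike on a smooth trend is still caught
    s <- max(s, 1e-9 * max(abs(rec$samples), 1e-300), na.rm = TRUE)
    if (is.finite(s)) bad <- bad | (!bad & abs(resid) > spike_z * s)
  }
  if (!any(bad)) return(rec)
  if (all(bad)) stop("recording entirely defective: nothing to interpolate from")
  good_idx <- which(!bad)
  xout <- which(bad)
  filled <- stats::approx(good_idx, rec$samples[good_idx], xout = xout,
                          rule = 2)$y
  samples <- rec$samples
  samples[xout] <- filled
  quality <- rec$quality
  quality[xout] <- "repaired"
  recording(rec$subject_id, rec$device_kind, rec$fs_hz, rec$t0_ms,
            samples, quality)
}

#' Design the pre-elaboration band-pass filter
#'
#' Second-order digital Butterworth band-pass with -3 dB points at `low_hz`
#' and `high_hz`, the interval containing the dominant BCG waves.
#'
#' @param fs_hz sampling rate, Hz.
#' @param low_hz,high_hz band edges, Hz (defaults 2 and 10).
#' @param order prototype filter order (default 2).
#' @return A `signal::butter` filter object (`b`, `a` coefficients).
#' @export
design_bandpass <- function(fs_hz = 50, low_hz = 2, high_hz = 10, order = 2) {
  if (high_hz >= fs_hz / 2) stop("upper cutoff must be below Nyquist")
  if (low_hz <= 0 || low_hz >= high_hz) stop("invalid band edges")
  signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
}

#' Magnitude response of a digital filter
#'
#' Evaluated analytically from the designed coefficients at the given
#' frequencies.
#'
#' @param filt a filter object with `b` and `a` coefficients.
#' @param f_hz frequencies to evaluate, Hz.
#' @param fs_hz sampling rate, Hz.
#' @return Numeric vector of linear magnitude gains.
#' @export
filter_gain <- function(filt, f_hz, fs_hz) {
  vapply(f_hz, function(f) {
    z <- exp(1i * 2 * pi * f / fs_hz)
    num <- sum(filt$b * z^(-(seq_along(filt$b) - 1)))
    den <- sum(filt$a * z^(-(seq_along(filt$a) - 1)))
    Mod(num / den)
  }, numeric(1))
}

#' Band-pass filter a belt recording
#'
#' Applies the 2-10 Hz second-order Butterworth band-pass in forward (causal)
#' form, matching a streaming deployment. Length and quality mask are
#' preserved.
#'
#' @param rec a belt [recording] at 50 Hz (other rates are rejected unless
#'   the cutoffs are rescaled explicitly via `low_hz`/`high_hz`).
#' @param low_hz,high_hz,order filter design parameters, see
#'   [design_bandpass].
#' @return The filtered recording.
#' @export
bandpass <- function(rec, low_hz = 2, high_hz = 10, order = 2) {
  if (rec$fs_hz != 50 && missing(low_hz) && missing(high_hz))
    stop("bandpass defaults assume 50 Hz; rescale cutoffs explicitly")
  filt <- design_bandpass(rec$fs_hz, low_hz, high_hz, order)
  y <- as.numeric(signal::filter(filt, rec$samples))
  recording(rec$subject_id, rec$device_kind, rec$fs_hz, rec$t0_ms,
            y, rec$quality)
}

#' Split a recording into 400-sample analysis windows
#'
#' Consecutive, non-overlapping windows of exactly `window` samples (8 s at
#' 50 Hz); any trailing remainder is dropped. Windows whose repaired+missing
#' sample fraction exceeds `max_repaired_frac` are marked excluded with
#' reason `"saturation"` (or `"missing"` when missing samples dominate).
#'
#' @param rec a [recording] with at least `window` samples.
#' @param window window length in samples (default 400).
#' @param max_repaired_frac exclusion threshold on the defective-sample
#'   fraction (default 0.25).
#' @return An object of class `window_set`: list with `subject_id`, `fs_hz`,
#'   `windows` (n x window matrix), `start_indices` (1-based sample index of
#'   each window in the source), `start_times_ms`, `excluded` (logical),
#'   `reason` (character, `NA` where included).
#' @export
segment <- function(rec, window = 400L, max_repaired_frac = 0.25) {
  n <- length(rec$samples)
  n_win <- n %/% window
  if (n_win == 0) {
    warning("recording shorter than one window: empty window set")
    return(structure(list(subject_id = rec$subject_id, fs_hz = rec$fs_hz,
                          windows = matrix(numeric(0), 0, window),
                          start_indices = integer(0),
                          start_times_ms = numeric(0),
                          excluded = logical(0), reason = character(0)),
                     class = "window_set"))
  }
  idx <- seq_len(n_win * window)
  windows <- matrix(rec$samples[idx], nrow = n_win, ncol = window, byrow = TRUE)
  qual <- matrix(rec$quality[idx] != "ok", nrow = n_win, ncol = window,
                 byrow = TRUE)
  miss <- matrix(rec$quality[idx] == "missing", nrow = n_win, ncol = window,
                 byrow = TRUE)
  bad_frac <- rowMeans(qual)
  excluded <- bad_frac > max_repaired_frac
  reason <- rep(NA_character_, n_win)
  reason[excluded] <- ifelse(rowMeans(miss)[excluded] > bad_frac[excluded] / 2,
                             "missing", "saturation")
  start_indices <- (seq_len(n_win) - 1L) * window + 1L
  structure(list(subject_id = rec$subject_id, fs_hz = rec$fs_hz,
                 windows = windows,
                 start_indices = start_indices,
                 start_times_ms = rec$t0_ms +
                   (start_indices - 1) * 1000 / rec$fs_hz,
                 excluded = excluded, reason = reason),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> subject %s: %d windows of %d samples, %d excluded\n",
              x$subject_id, nrow(x$windows), ncol(x$windows), sum(x$excluded)))
  invisible(x)
}

#' Normalize each window to zero mean and unit variance
#'
#' Applied per window, since both cores consume windows independently.
#' Zero-variance windows cannot be normalized and are marked excluded with
#' reason `"flat"`, their samples untouched. Idempotent.
#'
#' @param ws a [segment] window set.
#' @return The window set with non-excluded windows standardized.
#' @export
normalize_windows <- function(ws) {
  n_win <- nrow(ws$windows)
  if (n_win == 0) return(ws)
  mu <- rowMeans(ws$windows)
  centred <- ws$windows - mu
  v <- rowSums(centred^2) / ncol(ws$windows)
  flat <- v <= 0
  act <- !ws$excluded & !flat
  ws$windows[act, ] <- centred[act, , drop = FALSE] / sqrt(v[act])
  newly_flat <- flat & !ws$excluded
  ws$excluded <- ws$excluded | flat
  ws$reason[newly_flat] <- "flat"
  ws
}

#' Resample a 100 Hz PPG recording to the 50 Hz belt timeline
#'
#' Output sample `k` (0-based) is the linear interpolant of the source at
#' time `k / 50` s; with an exact 2:1 ratio this selects every other source
#' sample, and linear interpolation is exact on affine signals. A target
#' sample inherits `repaired`/`missing` if either flanking source sample
#' carries the flag.
#'
#' @param rec an oximeter [recording] at 100 Hz.
#' @return The recording resampled to 50 Hz, length `floor(n/2)`.
#' @export
resample_linear <- function(rec) {
  if (rec$fs_hz != 100)
    stop("resample_linear handles only the 100 -> 50 Hz oximeter case")
  n_out <- length(rec$samples) %/% 2L
  src <- 2L * (seq_len(n_out) - 1L) + 1L   # exact alignment: even source idx
  samples <- rec$samples[src]
  quality <- rec$quality[src]
  nxt <- pmin(src + 1L, length(rec$samples))
  worse <- rec$quality[nxt] != "ok" & quality == "ok"
  quality[worse] <- rec$quality[nxt][worse]
  recording(rec$subject_id, rec$device_kind, 50, rec$t0_ms, samples, quality)
}
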