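#' PPG gold-standard reference
#'
#' The finger pulse oximeter produces a clean photoplethysmography signal
#' whose systolic peaks mark heartbeats. After resampling to the shared 50 Hz
#' timeline and 8-second windowing, peaks are located by the method of local
#' maxima and minima and the reference heart rate follows as
#' `HR = 60 * Fs / Ns` with `Ns` the mean inter-peak interval in samples.
#'
#' @name ppg_reference
NULL

#' Detect systolic peaks in one PPG window
#'
#' Accepted peaks are local maxima that (a) exceed the window median by at
#' least `prominence` times the window's (max - median) range — so a DC
#' offset changes nothing — and (b) are separated by more than `refractory_s`
#' (default 0.33 s, capping rates at ~180 bpm; the larger peak wins a
#' conflict). Local minima validate alternation: every accepted peak is
#' flanked by lower turning points, which holds for strict local maxima by
#' construction.
#'
#' @param x one 400-sample PPG window at 50 Hz.
#' @param fs_hz sampling rate, Hz (default 50).
#' @param prominence threshold fraction of the (max - median) range
#'   (default 0.3).
#' @param refractory_s minimum peak separation, seconds (default 0.33).
#' @return Sorted window-local peak indices (possibly empty, e.g. for a flat
#'   window).
#' @export
detect_ppg_peaks <- function(x, fs_hz = 50, prominence = 0.3,
                             refractory_s = 0.33) {
  ext <- find_extrema(x)
  pk <- ext$index[ext$kind == "peak"]
  if (length(pk) == 0) return(integer(0))
  med <- stats::median(x)
  rng <- max(x) - med
  if (rng <= 0) return(integer(0))
  pk <- pk[x[pk] >= med + prominence * rng]
  if (length(pk) <= 1) return(pk)
  suppress_false_peaks(pk, x, fs_hz, span_s = 2 * refractory_s)
}

#' Reference heart rate from PPG peaks in one window
#'
#' `HR = 60 * Fs / Ns`, with `Ns` the mean inter-peak interval in samples;
#' undefined (`NA`) with fewer than two peaks.
#'
#' @param idx sorted window-local peak indices.
#' @param fs_hz sampling rate, Hz.
#' @return Heart rate in bpm, or `NA`.
#' @export
hr_true <- function(idx, fs_hz = 50) hr_from_beats(idx, fs_hz)

#' Reference heart-rate series for a PPG recording
#'
#' Resamples the 100 Hz oximeter stream to 50 Hz, segments it into 400-sample
#' windows aligned with the belt windows, detects systolic peaks per window,
#' and computes the per-window reference heart rate.
#'
#' @param rec an oximeter [recording] at 100 Hz.
#' @param window window length in samples (default 400).
#' @param ... passed to [detect_ppg_peaks].
#' @return List with `hr` (data frame as from [hr_series], source `"ppg"`),
#'   `by_window` (window-local peak indices) and `window_set`.
#' @export
ppg_reference_hr <- function(rec, window = 400L, ...) {
  rec50 <- resample_linear(rec)
  ws <- segment(rec50, window = window)
  by_window <- lapply(seq_len(nrow(ws$windows)), function(w) {
    if (ws$excluded[w]) return(NULL)
    detect_ppg_peaks(ws$windows[w, ], ws$fs_hz, ...)
  })
  det <- list(by_window = by_window)
  list(hr = hr_series(det, ws, source = "ppg"),
       by_window = by_window, window_set = ws)
}
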