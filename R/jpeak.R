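#' Algorithmic J-peak detection
#'
#' The algorithmic heart-rate core: ejection waves are enhanced by cubing the
#' band-passed signal (sign kept intact), a coarse low-passed version locates
#' candidate IJK complexes, valley-peak-valley triplets of the fine signal are
#' scored with weights (-1, +1, -1) on the coarse amplitudes, false peaks
#' closer than the heartbeat interval are suppressed, and per-window heart
#' rate follows from the mean J-J distance.
#'
#' @name jpeak_algorithm
NULL

#' Cube a signal keeping its sign
#'
#' `x^3` elementwise: enhances large deflections relative to small ones while
#' preserving sign and ordering.
#'
#' @param x numeric vector.
#' @return `x^3`.
#' @export
cube <- function(x) x^3

#' Coarse envelope of the cubed signal
#'
#' Second-order Butterworth low-pass (default cutoff 6 Hz), applied
#' zero-phase so envelope maxima stay aligned with the complexes they
#' summarize. The cutoff must sit well above the heart-rate fundamental yet
#' below the intra-complex detail: cubing concentrates each beat's energy
#' into a narrow J burst roughly 0.1 s wide, and a cutoff near 6 Hz turns
#' that burst into one localized bump per beat. Substantially lower cutoffs
#' blur the bump over several competing fine-signal extrema and triplet
#' scoring loses its discrimination.
#'
#' @param x cubed signal.
#' @param fs_hz sampling rate, Hz (> 2 * cutoff).
#' @param cutoff_hz low-pass cutoff, Hz.
#' @return Smoothed signal, same length.
#' @export
coarse_envelope <- function(x, fs_hz, cutoff_hz = 6) {
  if (cutoff_hz >= fs_hz / 2) stop("cutoff must be below Nyquist")
  filt <- signal::butter(2, cutoff_hz / (fs_hz / 2), type = "low")
  as.numeric(signal::filtfilt(filt, x))
}

#' Locate alternating local extrema
#'
#' Local peaks (strictly greater than both neighbours) and valleys (strictly
#' smaller); plateaus collapse to their first sample. Because strictly
#' monotone segments separate successive extrema, the output alternates
#' valley/peak by construction.
#'
#' @param x numeric vector.
#' @return Data frame with columns `index` (1-based) and `kind`
#'   (`"valley"`/`"peak"`), ordered by index.
#' @export
find_extrema <- function(x) {
  n <- length(x)
  empty <- data.frame(index = integer(0), kind = character(0))
  if (n < 3) return(empty)
  r <- rle(x)
  firsts <- cumsum(r$lengths) - r$lengths + 1L   # first sample of each plateau
  xc <- r$values
  m <- length(xc)
  if (m < 3) return(empty)
  i <- 2:(m - 1)
  is_peak <- xc[i] > xc[i - 1] & xc[i] > xc[i + 1]
  is_valley <- xc[i] < xc[i - 1] & xc[i] < xc[i + 1]
  keep <- is_peak | is_valley
  data.frame(index = firsts[i][keep],
             kind = ifelse(is_peak[keep], "peak", "valley"))
}

#' Score and select IJK triplets inside coarse search spans
#'
#' Within each search span (a neighbourhood around a coarse-envelope maximum)
#' every valley-peak-valley triplet of consecutive fine-signal extrema is
#' scored as `-a(i) + a(j) - a(k)` with `a(.)` read from the coarse signal,
#' and the highest-scoring triplet's peak becomes the provisional J. Ties go
#' to the earlier peak; spans with fewer than three extrema yield no
#' candidate.
#'
#' @param extrema data frame from [find_extrema] on the fine (band-passed)
#'   signal.
#' @param coarse coarse envelope, same length as the fine signal.
#' @param spans two-column matrix of (start, end) sample indices.
#' @return Data frame with columns `i_idx`, `j_idx`, `k_idx`, `score`, one
#'   row per span that produced a winner.
#' @export
select_complexes <- function(extrema, coarse, spans) {
  out <- list()
  for (s in seq_len(nrow(spans))) {
    inside <- extrema$index >= spans[s, 1] & extrema$index <= spans[s, 2]
    ex <- extrema[inside, , drop = FALSE]
    if (nrow(ex) < 3) next
    best <- NULL
    for (p in 1:(nrow(ex) - 2)) {
      if (ex$kind[p] != "valley" || ex$kind[p + 1] != "peak" ||
          ex$kind[p + 2] != "valley") next
      sc <- -coarse[ex$index[p]] + coarse[ex$index[p + 1]] -
        coarse[ex$index[p + 2]]
      if (is.null(best) || sc > best$score)
        best <- list(i = ex$index[p], j = ex$index[p + 1],
                     k = ex$index[p + 2], score = sc)
    }
    if (!is.null(best))
      out[[length(out) + 1L]] <- data.frame(i_idx = best$i, j_idx = best$j,
                                            k_idx = best$k, score = best$score)
  }
  if (length(out) == 0)
    return(data.frame(i_idx = integer(0), j_idx = integer(0),
                      k_idx = integer(0), score = numeric(0)))
  do.call(rbind, out)
}

#' Suppress false peaks by non-maximum suppression
#'
#' A provisional J survives iff its amplitude in the band-passed signal is the
#' maximum among all provisional Js within half the suppression span of it
#' (default span 1 s, the typical heartbeat interval). Ties go to the earlier
#' index; surviving peaks are strictly increasing with consecutive gaps
#' greater than `span_s / 2`.
#'
#' @param js sorted provisional J sample indices.
#' @param x band-passed signal (amplitude source).
#' @param fs_hz sampling rate, Hz.
#' @param span_s suppression span, seconds (default 1).
#' @return Surviving J indices, strictly increasing.
#' @export
suppress_false_peaks <- function(js, x, fs_hz, span_s = 1) {
  js <- unique(sort(js))
  if (length(js) <= 1) return(js)
  half <- span_s / 2 * fs_hz
  amp <- x[js]
  keep <- vapply(seq_along(js), function(i) {
    near <- which(abs(js - js[i]) <= half)
    best <- near[order(-amp[near], js[near])][1]
    best == i
  }, logical(1))
  js[keep]
}

#' Detect J-peaks across a window set
#'
#' Runs the full algorithmic chain per non-excluded window: cube ->
#' coarse envelope -> fine extrema -> triplet scoring inside search spans
#' around each coarse maximum -> false-peak suppression. Window-local indices
#' are mapped back to recording coordinates.
#'
#' @param ws a [segment] window set of the band-passed belt signal.
#' @param coarse_cutoff_hz coarse low-pass cutoff, Hz (default 6, see
#'   [coarse_envelope]).
#' @param search_halfwidth_s half-width of the search span around each coarse
#'   maximum, seconds (default 0.25: IJK width ~0.12 s plus margin).
#' @param span_s false-peak suppression span, seconds (default 1).
#' @param min_peak_frac only coarse maxima reaching this fraction of the
#'   window's largest coarse amplitude open a search span (default 0.1);
#'   cubing leaves genuine J bursts far above residual noise bumps, so a low
#'   relative threshold discards noise-born spans without touching beats.
#' @return List with `peaks`, a data frame (subject_id, window_index,
#'   peak_index, peak_time_ms, source = "algorithm") in recording
#'   coordinates, and `by_window`, a list of window-local peak index vectors
#'   (`NULL` for excluded windows).
#' @export
detect_jpeaks <- function(ws, coarse_cutoff_hz = 6, search_halfwidth_s = 0.25,
                          span_s = 1, min_peak_frac = 0.1) {
  n_win <- nrow(ws$windows)
  by_window <- vector("list", n_win)
  half <- round(search_halfwidth_s * ws$fs_hz)
  for (w in seq_len(n_win)) {
    if (ws$excluded[w]) next
    x <- ws$windows[w, ]
    cb <- cube(x)
    coarse <- coarse_envelope(cb, ws$fs_hz, coarse_cutoff_hz)
    ext_fine <- find_extrema(x)
    ext_coarse <- find_extrema(coarse)
    cpk <- ext_coarse$index[ext_coarse$kind == "peak"]
    if (length(cpk) > 0 && max(coarse) > 0)
      cpk <- cpk[coarse[cpk] >= min_peak_frac * max(coarse)]
    if (length(cpk) == 0) {
      by_window[[w]] <- integer(0)
      next
    }
    spans <- cbind(pmax(cpk - half, 1L), pmin(cpk + half, length(x)))
    winners <- select_complexes(ext_fine, coarse, spans)
    js <- suppress_false_peaks(winners$j_idx, x, ws$fs_hz, span_s)
    by_window[[w]] <- js
  }
  rows <- lapply(seq_len(n_win), function(w) {
    js <- by_window[[w]]
    if (is.null(js) || length(js) == 0) return(NULL)
    global <- ws$start_indices[w] + js - 1L
    data.frame(subject_id = ws$subject_id, window_index = w,
               peak_index = global,
               peak_time_ms = ws$start_times_ms[w] + (js - 1) * 1000 / ws$fs_hz,
               source = "algorithm")
  })
  peaks <- do.call(rbind, rows)
  if (is.null(peaks))
    peaks <- data.frame(subject_id = character(0), window_index = integer(0),
                        peak_index = integer(0), peak_time_ms = numeric(0),
                        source = character(0))
  list(peaks = peaks, by_window = by_window)
}

#' Heart rate from beats in one window
#'
#' With `n >= 2` peaks, `HR = 60 * fs / mean(successive peak distances)`
#' beats per minute; with fewer, or a value outside the plausible
#' 20-250 bpm range, the undefined sentinel `NA`.
#'
#' @param idx sorted window-local peak indices.
#' @param fs_hz sampling rate, Hz.
#' @return Heart rate in bpm, or `NA`.
#' @export
hr_from_beats <- function(idx, fs_hz) {
  if (length(idx) < 2) return(NA_real_)
  hr <- 60 * fs_hz / mean(diff(idx))
  if (hr < 20 || hr > 250) return(NA_real_)
  hr
}

#' Per-window heart-rate series from detections
#'
#' @param det result of [detect_jpeaks] (or any list of window-local peak
#'   vectors in `by_window`).
#' @param ws the window set the detection ran on.
#' @param source label recorded in the output (`"algorithm"`, `"ppg"`, ...).
#' @return Data frame (subject_id, window_index, window_start_ms, hr_bpm,
#'   n_peaks); `hr_bpm` is `NA` where fewer than two peaks were found or the
#'   window was excluded.
#' @export
hr_series <- function(det, ws, source = "algorithm") {
  n_win <- nrow(ws$windows)
  hr <- vapply(seq_len(n_win), function(w) {
    js <- det$by_window[[w]]
    if (is.null(js)) return(NA_real_)
    hr_from_beats(js, ws$fs_hz)
  }, numeric(1))
  n_peaks <- vapply(seq_len(n_win), function(w) {
    js <- det$by_window[[w]]
    if (is.null(js)) 0L else length(js)
  }, integer(1))
  data.frame(subject_id = ws$subject_id, window_index = seq_len(n_win),
             window_start_ms = ws$start_times_ms, hr_bpm = hr,
             n_peaks = n_peaks, source = source)
}
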