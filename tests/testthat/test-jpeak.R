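test_that("cubing keeps sign and sharpens relative contrast", {
  expect_equal(cube(c(2, -2, 0)), c(8, -8, 0))
  x <- c(0.2, 0.5, 1.5)
  expect_equal(order(cube(x)), order(x))                    # monotone
  expect_gt(abs(cube(3) / cube(2)), abs(3 / 2))             # enhancement
})

test_that("coarse envelope centres on the complex and crushes white noise", {
  expect_equal(coarse_envelope(numeric(200), 50), numeric(200))

  prof <- clean_profile()
  rec <- render_bcg(4.0, 8, prof)
  cb <- cube(bandpass(rec)$samples)
  env <- coarse_envelope(cb, 50)
  expect_lte(abs(which.max(env) - (round(4.0 * 50) + 1)), 5)

  withr::local_seed(4)
  noise <- rnorm(5000)
  expect_gt(var(noise) / var(coarse_envelope(noise, 50, cutoff_hz = 2)), 10)

  expect_error(coarse_envelope(numeric(10), 50, cutoff_hz = 30), "Nyquist")
})

test_that("extrema detection alternates, collapses plateaus, matches the sine oracle", {
  e <- find_extrema(c(0, 1, 0))
  expect_equal(e$index, 2L)
  expect_equal(e$kind, "peak")

  expect_equal(nrow(find_extrema(1:50)), 0)

  # plateau collapses to its first sample
  ep <- find_extrema(c(0, 1, 1, 1, 0))
  expect_equal(ep$index, 2L)

  tt <- (0:399) / 50
  e2 <- find_extrema(sin(2 * pi * tt))
  pk <- e2$index[e2$kind == "peak"]
  vl <- e2$index[e2$kind == "valley"]
  expect_length(pk, 8)
  expect_length(vl, 8)
  expect_true(all(abs(pk - (0:7 * 50 + 13.5)) <= 1))   # analytic peak at t=k+0.25
  expect_true(all(abs(vl - (0:7 * 50 + 38.5)) <= 1))
  # alternation
  kinds <- find_extrema(sin(2 * pi * tt))$kind
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
})

test_that("triplet scoring follows the (-1, +1, -1) weights and picks the arg-max", {
  coarse <- c(-2, 5, -3, 1, 2, 1)
  extrema <- data.frame(index = c(1L, 2L, 3L, 4L, 5L, 6L),
                        kind = c("valley", "peak", "valley",
                                 "valley", "peak", "valley"))
  span <- cbind(1L, 6L)
  win <- select_complexes(extrema, coarse, span)
  # triplet (1,2,3): 2+5+3 = 10; triplet (4,5,6): -1+2-1 = 0
  expect_equal(win$score, 10)
  expect_equal(c(win$i_idx, win$j_idx, win$k_idx), c(1, 2, 3))

  # fewer than three extrema in a span: no candidate, not an error
  empty <- select_complexes(extrema[1:2, ], coarse, span)
  expect_equal(nrow(empty), 0)
})

test_that("triplet selection equals exhaustive enumeration on random windows", {
  withr::local_seed(8)
  brute_force <- function(extrema, coarse, lo, hi) {
    best <- NULL
    for (p in seq_len(nrow(extrema))) {
      for (q in seq_len(nrow(extrema))) {
        for (r in seq_len(nrow(extrema))) {
          if (!(q == p + 1 && r == q + 1)) next   # consecutive extrema
          if (extrema$kind[p] != "valley" || extrema$kind[q] != "peak" ||
              extrema$kind[r] != "valley") next
          if (extrema$index[p] < lo || extrema$index[r] > hi) next
          sc <- -coarse[extrema$index[p]] + coarse[extrema$index[q]] -
            coarse[extrema$index[r]]
          if (is.null(best) || sc > best$score)
            best <- list(j = extrema$index[q], score = sc)
        }
      }
    }
    best
  }
  for (rep in 1:20) {
    x <- cumsum(rnorm(60))               # rough random signal
    coarse <- coarse_envelope(x, 50, 5)
    extrema <- find_extrema(x)
    lo <- sample(1:20, 1); hi <- lo + sample(20:39, 1)
    got <- select_complexes(extrema, coarse, cbind(lo, hi))
    want <- brute_force(extrema, coarse, lo, hi)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$j_idx, want$j)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("false-peak suppression keeps the locally largest peak only", {
  x <- numeric(100)
  x[c(40, 50)] <- c(3, 5)
  expect_equal(suppress_false_peaks(c(40, 50), x, 50), 50)
  expect_equal(suppress_false_peaks(35, x, 50), 35)
  # equal amplitudes: earlier index wins
  x[c(60, 62)] <- c(4, 4)
  expect_equal(suppress_false_peaks(c(60, 62), x, 50), 60)
  # surviving peaks always separated by more than half the span
  withr::local_seed(5)
  for (rep in 1:10) {
    js <- sort(sample(500, 30))
    xx <- runif(500)
    out <- suppress_false_peaks(js, xx, 50)
    if (length(out) > 1) expect_true(all(diff(out) > 25))
  }
  # a clean 60 bpm train (gaps 1 s) passes through untouched
  prof <- clean_profile()
  beats <- make_beat_times(prof, 60)
  ws <- prep_windows(beats, 60, prof)
  det <- detect_jpeaks(ws)
  expect_true(all(unlist(lapply(det$by_window, diff)) > 25))
})

test_that("detection recovers clean beats and ignores empty windows", {
  # one 8 s window with interior beats at 60 bpm
  prof <- clean_profile()
  beats <- 0.5 + 0:7                     # 8 beats, away from window edges
  ws <- prep_windows(beats, 8, prof)
  det <- detect_jpeaks(ws)
  js <- det$by_window[[1]]
  expect_length(js, 8)
  expect_true(all(abs(sort(js) - (round(beats * 50) + 1)) <= 3))

  zero_ws <- segment(recording("s1", "belt", 50, 0, numeric(400)))
  expect_length(detect_jpeaks(zero_ws)$by_window[[1]], 0)
})

test_that("clean full-pipeline detection recovers at least 95% of J-peaks", {
  prof <- clean_profile(mean_hr = 58, seed = 3)
  beats <- make_beat_times(prof, 600)
  ws <- prep_windows(beats, 600, prof)
  det <- detect_jpeaks(ws)
  expect_gte(beat_recall(det$peaks$peak_index, beats), 0.95)
  # detection count within 2% of the true count over the session
  expect_lt(abs(nrow(det$peaks) - length(beats)) / length(beats), 0.02)
})

test_that("detection is deterministic and scale-equivariant", {
  prof <- subject_profile(seed = 6, artifact_events_per_hour = 0)
  beats <- make_beat_times(prof, 120)
  ws <- prep_windows(beats, 120, prof)
  d1 <- detect_jpeaks(ws)
  d2 <- detect_jpeaks(ws)
  expect_identical(d1, d2)

  ws_scaled <- ws
  ws_scaled$windows <- ws$windows * 7.5
  expect_equal(detect_jpeaks(ws_scaled)$peaks$peak_index, d1$peaks$peak_index)
  # output indices strictly increasing
  expect_true(all(diff(d1$peaks$peak_index) > 0))
})

test_that("window heart rate is the mean J-J distance formula", {
  expect_equal(hr_from_beats(c(25, 75, 125, 175), 50), 60)
  expect_true(is.na(hr_from_beats(100, 50)))
  expect_true(is.na(hr_from_beats(integer(0), 50)))
  # gaps 40, 50, 60 -> mean 50 -> 60 bpm
  expect_equal(hr_from_beats(cumsum(c(10, 40, 50, 60)), 50), 60)
  # implausible rates are undefined
  expect_true(is.na(hr_from_beats(c(1, 2, 3), 50)))   # 3000 bpm
})
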