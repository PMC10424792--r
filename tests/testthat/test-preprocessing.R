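test_that("repair leaves clean recordings bit-identical", {
  withr::local_seed(1)
  rec <- recording("s1", "belt", 50, 0, rnorm(500))
  expect_identical(repair(rec, adc_limits = c(-10, 10)), rec)
})

test_that("repair replaces a lone spike with the trend's interpolated value", {
  x <- seq(0, 10, length.out = 501)   # smooth ramp
  spiked <- x
  spiked[250] <- 100 * max(x)
  rec <- recording("s1", "belt", 50, 0, spiked)
  out <- repair(rec, adc_limits = NULL)
  expect_equal(out$quality[250], "repaired")
  expect_equal(out$samples[250], (x[249] + x[251]) / 2, tolerance = 1e-12)
  # samples still flagged ok are bit-identical
  ok <- out$quality == "ok"
  expect_gt(sum(ok), 350)
  expect_identical(out$samples[ok], spiked[ok])
})

test_that("repair flags a one-second saturation run and interpolates through it", {
  withr::local_seed(2)
  x <- sin(2 * pi * 3 * (0:499) / 50) + rnorm(500, 0, 0.05)
  x[201:250] <- 10                     # 1 s pinned at max code
  rec <- recording("s1", "belt", 50, 0, x)
  out <- repair(rec, adc_limits = c(-10, 10))
  expect_true(all(out$quality[201:250] == "repaired"))
  expect_true(all(abs(out$samples[201:250]) < 10))
  expect_error(repair(recording("s1", "belt", 50, 0, rep(10, 100)),
                      adc_limits = c(-10, 10)),
               "entirely")
})

test_that("band-pass has -3 dB edges, flat mid-band, and strong stop-band rejection", {
  filt <- design_bandpass(50, 2, 10, 2)
  peak <- max(filter_gain(filt, seq(2, 10, by = 0.01), 50))
  edge_db <- -20 * log10(filter_gain(filt, c(2, 10), 50) / peak)
  expect_equal(edge_db[1], 3.0103, tolerance = 0.1)
  expect_equal(edge_db[2], 3.0103, tolerance = 0.1)

  # zero in, zero out; length preserved
  rec <- recording("s1", "belt", 50, 0, numeric(400))
  expect_equal(bandpass(rec)$samples, numeric(400))

  # steady-state response: 6 Hz passes within 5%, 0.3 Hz attenuated > 15 dB
  tt <- (0:4999) / 50
  pass <- bandpass(recording("s1", "belt", 50, 0, sin(2 * pi * 6 * tt)))
  expect_lt(abs(max(pass$samples[2000:5000]) - 1), 0.05)
  stop_g <- filter_gain(filt, 0.3, 50) / peak
  expect_gt(-20 * log10(stop_g), 15)

  expect_error(design_bandpass(50, 2, 30), "Nyquist")
})

test_that("segmentation tiles the recording and conserves samples", {
  rec <- recording("s1", "belt", 50, 0, rnorm(4000))
  ws <- segment(rec)
  expect_equal(nrow(ws$windows), 10)
  expect_false(any(ws$excluded))
  expect_equal(ws$start_indices, seq(1, 3601, by = 400))

  ws2 <- segment(recording("s1", "belt", 50, 0, rnorm(4399)))
  expect_equal(nrow(ws2$windows), 10)        # trailing 399 dropped
  expect_equal(nrow(ws2$windows) * 400 + 4399 %% 400, 4399)

  expect_warning(segment(recording("s1", "belt", 50, 0, rnorm(399))),
                 "shorter")
})

test_that("windows over the repaired-fraction threshold are excluded", {
  q <- rep("ok", 400)
  q[101:150] <- "repaired"               # 12.5% of the window
  rec <- recording("s1", "belt", 50, 0, rnorm(400), q)
  expect_true(segment(rec, max_repaired_frac = 0.1)$excluded[1])
  expect_false(segment(rec, max_repaired_frac = 0.25)$excluded[1])
  expect_equal(segment(rec, max_repaired_frac = 0.1)$reason[1], "saturation")
})

test_that("normalization standardizes, flags flat windows, and is idempotent", {
  withr::local_seed(3)
  rec <- recording("s1", "belt", 50, 0, c(rnorm(400, 5, 2), rep(7, 400)))
  ws <- normalize_windows(segment(rec))
  expect_lt(abs(mean(ws$windows[1, ])), 1e-9)
  expect_lt(abs(sum(ws$windows[1, ]^2) / 400 - 1), 1e-6)
  expect_true(ws$excluded[2])
  expect_equal(ws$reason[2], "flat")
  expect_equal(ws$windows[2, ], rep(7, 400))  # untouched
  expect_equal(normalize_windows(ws), ws)     # idempotent
})

test_that("linear resampling halves the rate exactly and is exact on ramps", {
  rec <- recording("s1", "oximeter", 100, 0, rnorm(1000))
  out <- resample_linear(rec)
  expect_length(out$samples, 500)
  expect_equal(out$fs_hz, 50)

  const <- resample_linear(recording("s1", "oximeter", 100, 0, rep(3.3, 200)))
  expect_equal(const$samples, rep(3.3, 100))

  tt <- (0:999) / 100
  ramp <- resample_linear(recording("s1", "oximeter", 100, 0, tt))
  expect_equal(ramp$samples, (0:499) / 50)

  q <- rep("ok", 1000); q[4] <- "repaired"
  flagged <- resample_linear(recording("s1", "oximeter", 100, 0, rnorm(1000), q))
  expect_equal(flagged$quality[2], "repaired")  # flanking source sample flag

  expect_error(resample_linear(recording("s1", "belt", 50, 0, rnorm(10))),
               "100")
})

test_that("filtering and normalization preserve window count and order; most windows survive a default cohort", {
  sess <- generate_session(subject_profile(seed = 23), 1800)
  rep_rec <- repair(sess$belt, adc_limits = sess$profile$adc_limits)
  ws <- segment(bandpass(rep_rec))
  expect_equal(nrow(normalize_windows(ws)$windows), nrow(ws$windows))
  expect_gte(mean(!ws$excluded), 0.80)
})
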