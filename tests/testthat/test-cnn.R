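test_that("the reference architecture counts 18,801 parameters and collapses 400 to 1", {
  spec <- cnn_reference_spec()
  expect_length(spec$layers, 11)
  expect_equal(cnn_count_params(spec), 18801)
  expect_equal(round(cnn_count_params(spec) / 1000, 1), 18.8)
  expect_equal(cnn_length_chain(spec),
               c(400, 200, 100, 50, 25, 13, 7, 4, 2, 1, 1, 1))
  # structural constraints: final layer is a single filter of kernel 1
  last <- spec$layers[[11]]
  expect_equal(last$out_channels, 1)
  expect_equal(last$kernel, 1)
  expect_false(last$batch_norm)
  expect_equal(last$activation, "none")
  expect_true(all(vapply(spec$layers[1:10], `[[`, logical(1), "batch_norm")))

  # width factor doubles channels but not the length chain
  wide <- cnn_reference_spec(width_factor = 2)
  expect_equal(wide$layers[[2]]$out_channels, 32)
  expect_equal(cnn_length_chain(wide), cnn_length_chain(spec))
})

test_that("a built model maps batches to scalars and matches the parameter formula", {
  spec <- cnn_reference_spec()
  model <- cnn_build(spec, seed = 2)
  built <- sum(vapply(model$layers, function(st) {
    length(st$W) + length(st$b) +
      (if (is.null(st$gamma)) 0 else length(st$gamma) + length(st$beta))
  }, numeric(1)))
  expect_equal(built, cnn_count_params(spec))

  withr::local_seed(3)
  X <- matrix(rnorm(7 * 400), 7, 400)
  out <- cnn_predict_raw(model, X)
  expect_length(out, 7)
  expect_identical(out, cnn_predict_raw(model, X))  # deterministic inference

  bad <- cnn_reference_spec()
  bad$layers[[1]]$stride <- 1
  expect_error(cnn_build(bad), "stride chain")
})

test_that("analytic gradients match central finite differences", {
  spec <- structure(list(layers = list(
    list(in_channels = 1, out_channels = 3, kernel = 4, stride = 2,
         batch_norm = TRUE, activation = "leaky_relu"),
    list(in_channels = 3, out_channels = 3, kernel = 3, stride = 4,
         batch_norm = TRUE, activation = "leaky_relu"),
    list(in_channels = 3, out_channels = 1, kernel = 2, stride = 2,
         batch_norm = FALSE, activation = "none")),
    input_len = 16L, width_factor = 1), class = "cnn_spec")
  model <- cnn_build(spec, seed = 5)
  withr::local_seed(9)
  X <- matrix(rnorm(6 * 16), 6, 16)
  y <- rnorm(6)
  fwd <- bcgsleep:::cnn_forward(model, X, training = TRUE)
  grads <- bcgsleep:::cnn_backward(model, fwd, 2 * (fwd$out - y) / 6)
  lossf <- function(m) {
    f <- bcgsleep:::cnn_forward(m, X, training = TRUE)
    mean((f$out - y)^2)
  }
  eps <- 1e-6
  gname <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")
  for (li in seq_along(model$layers)) {
    for (field in intersect(names(model$layers[[li]]), names(gname))) {
      g_an <- grads[[li]][[gname[[field]]]]
      for (j in seq_len(min(length(g_an), 4))) {
        m2 <- model; m2$layers[[li]][[field]][j] <- m2$layers[[li]][[field]][j] + eps
        m3 <- model; m3$layers[[li]][[field]][j] <- m3$layers[[li]][[field]][j] - eps
        g_num <- (lossf(m2) - lossf(m3)) / (2 * eps)
        expect_lt(abs(g_num - g_an[j]) / max(1e-6, abs(g_num)), 1e-4)
      }
    }
  }
})

test_that("the target normalizer inverts exactly and rejects degenerate targets", {
  nm <- target_normalizer(c(50, 60, 70))
  expect_equal(nm$mean_bpm, 60)
  # denormalization at prediction time: raw 0 -> mean, raw 1.5 -> mean+1.5 sd
  ws <- segment(recording("s1", "belt", 50, 0, rep(1, 400)))
  ws <- normalize_windows(ws)                      # excluded (flat)
  model <- cnn_build(cnn_reference_spec(), seed = 1)
  pred <- cnn_predict_hr(model, ws, list(mean_bpm = 60, sd_bpm = 10))
  expect_true(is.na(pred$hr_bpm[1]))               # excluded -> sentinel
  expect_error(target_normalizer(rep(60, 5)), "variance")
  expect_error(target_normalizer(NA_real_), "no defined")
})

test_that("the network has the capacity to memorize a small window set", {
  prof <- subject_profile(seed = 33, artifact_events_per_hour = 0)
  beats <- make_beat_times(prof, 440)
  ws <- normalize_windows(prep_windows(beats, 440, prof))
  truth <- truth_hr_series(beats, ws)
  keep <- which(!ws$excluded & !is.na(truth$hr_bpm))[1:50]
  X <- ws$windows[keep, ]
  y <- truth$hr_bpm[keep]
  model <- cnn_build(cnn_reference_spec(), seed = 1)
  fit <- cnn_fit(model, X, y, epochs = 200, seed = 2)
  expect_lt(fit$history$mae_bpm[200], 1)
})

test_that("training is reproducible and splits never leak subjects", {
  withr::local_seed(4)
  X <- matrix(rnorm(40 * 400), 40, 400)
  y <- runif(40, 45, 75)
  f1 <- cnn_fit(cnn_build(cnn_reference_spec(), seed = 7), X, y,
                epochs = 3, seed = 9)
  f2 <- cnn_fit(cnn_build(cnn_reference_spec(), seed = 7), X, y,
                epochs = 3, seed = 9)
  expect_identical(f1$history, f2$history)

  ids <- sprintf("s%02d", 1:24)
  sp <- split_subjects(ids, 2 / 3, seed = 5)
  expect_length(sp$train, 16)
  expect_length(sp$test, 8)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_error(cnn_fit(cnn_build(cnn_reference_spec(), 1),
                       matrix(0, 0, 400), numeric(0)),
               "empty")
})
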