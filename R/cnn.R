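#' Convolutional heart-rate regressor
#'
#' A compact 11-layer 1-D convolutional network mapping one normalized
#' 400-sample window directly to a heart-rate value. Strided convolutions
#' replace pooling, there are no dense layers, every convolution except the
#' last is followed by batch normalization and a leaky ReLU, and the final
#' layer uses a single filter of kernel size 1 to collapse the feature
#' channels to one scalar. Training minimizes mean squared error on
#' z-normalized heart rates with the Adam optimizer at its default
#' parameters. The network, its gradients and the optimizer are implemented
#' directly in R with dense matrix algebra (im2col convolutions), which is
#' ample for a model of this size.
#'
#' @name hr_cnn
NULL

#' Reference network specification
#'
#' The canonical 11-layer configuration: L1 maps 1 -> 16a channels (kernel 8,
#' stride 2), L2-L9 keep 16a channels (kernel 8, stride 2), L10 16a -> 16a
#' (kernel 7, stride 1), L11 16a -> 1 (kernel 1, stride 1, no batch norm or
#' activation). Under same-padding the length chain is 400 -> 200 -> 100 ->
#' 50 -> 25 -> 13 -> 7 -> 4 -> 2 -> 1 -> 1 -> 1. With `width_factor = 1` the
#' network counts 18,801 trainable parameters (18.8 k).
#'
#' @param width_factor multiply every hidden channel count by this factor
#'   (the `a` knob; default 1).
#' @return List of 11 layer specs (in_channels, out_channels, kernel, stride,
#'   batch_norm, activation), of class `cnn_spec`.
#' @export
cnn_reference_spec <- function(width_factor = 1) {
  ch <- round(16 * width_factor)
  conv <- function(cin, cout, k, s, bn = TRUE,
                   act = if (bn) "leaky_relu" else "none") {
    list(in_channels = cin, out_channels = cout, kernel = k, stride = s,
         batch_norm = bn, activation = act)
  }
  layers <- c(list(conv(1, ch, 8, 2)),
              rep(list(conv(ch, ch, 8, 2)), 8),
              list(conv(ch, ch, 7, 1)),
              list(conv(ch, 1, 1, 1, bn = FALSE)))
  structure(list(layers = layers, input_len = 400L,
                 width_factor = width_factor),
            class = "cnn_spec")
}

#' Count trainable parameters of a network specification
#'
#' Per convolution `kernel * in * out + out`, plus 2 per batch-normalized
#' channel (scale and shift; running statistics are not trainable).
#'
#' @param spec a [cnn_reference_spec]-style specification.
#' @return Integer parameter count.
#' @export
cnn_count_params <- function(spec) {
  sum(vapply(spec$layers, function(l) {
    l$kernel * l$in_channels * l$out_channels + l$out_channels +
      if (l$batch_norm) 2 * l$out_channels else 0
  }, numeric(1)))
}

#' Output length chain of a specification
#'
#' Same-padding strided convolution maps length `n` to `ceiling(n / stride)`.
#'
#' @param spec a network specification.
#' @return Integer vector of length 12: input length followed by each layer's
#'   output length.
#' @export
cnn_length_chain <- function(spec) {
  len <- spec$input_len
  chain <- len
  for (l in spec$layers) {
    len <- ceiling(len / l$stride)
    chain <- c(chain, len)
  }
  chain
}

#' Build a model from a specification
#'
#' Glorot-uniform kernel initialization, zero biases, batch-norm scale 1 /
#' shift 0. Construction fails if the stride chain does not reduce the input
#' length to exactly 1.
#'
#' @param spec a network specification.
#' @param seed integer seed for weight initialization.
#' @return A `cnn_model`: the spec plus per-layer weights.
#' @export
cnn_build <- function(spec, seed = 1L) {
  chain <- cnn_length_chain(spec)
  if (chain[length(chain)] != 1)
    stop("stride chain does not reduce the input length to 1")
  layers <- with_local_seed(seed, lapply(spec$layers, function(l) {
    fan_in <- l$kernel * l$in_channels
    fan_out <- l$kernel * l$out_channels
    lim <- sqrt(6 / (fan_in + fan_out))
    W <- matrix(stats::runif(fan_in * l$out_channels, -lim, lim),
                fan_in, l$out_channels)
    st <- list(W = W, b = numeric(l$out_channels))
    if (l$batch_norm) {
      st$gamma <- rep(1, l$out_channels)
      st$beta <- numeric(l$out_channels)
      st$run_mean <- numeric(l$out_channels)
      st$run_var <- rep(1, l$out_channels)
    }
    st
  }))
  structure(list(spec = spec, layers = layers), class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d layers, %d trainable parameters\n",
              length(x$spec$layers), cnn_count_params(x$spec)))
  invisible(x)
}

BN_EPS <- 1e-3        # batch-norm variance floor
BN_MOMENTUM <- 0.99   # running-statistics decay
LEAKY_SLOPE <- 0.3    # leaky ReLU negative slope

# activations are matrices of shape (batch * len, channels), sample index
# fastest; array(x, c(batch, len, ch)) recovers the tensor layout
conv1d_forward <- function(X, W, b, stride, k, batch, len_in, C_in) {
  len_out <- ceiling(len_in / stride)
  pad_total <- max((len_out - 1L) * stride + k - len_in, 0L)
  pad_left <- pad_total %/% 2L
  Xpad <- array(0, c(batch, len_in + pad_total, C_in))
  Xpad[, pad_left + seq_len(len_in), ] <- array(X, c(batch, len_in, C_in))
  P <- matrix(0, batch * len_out, k * C_in)
  base_t <- (seq_len(len_out) - 1L) * stride
  for (p in seq_len(k)) {
    blk <- Xpad[, base_t + p, , drop = FALSE]
    P[, ((p - 1L) * C_in + 1L):(p * C_in)] <- matrix(blk, batch * len_out, C_in)
  }
  Y <- sweep(P %*% W, 2, b, "+")
  list(Y = Y, P = P, pad_left = pad_left, pad_total = pad_total,
       len_out = len_out)
}

conv1d_backward <- function(cache, W, dY, stride, k, batch, len_in, C_in) {
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- dY %*% t(W)
  dXpad <- array(0, c(batch, len_in + cache$pad_total, C_in))
  base_t <- (seq_len(cache$len_out) - 1L) * stride
  for (p in seq_len(k)) {
    blk <- array(dP[, ((p - 1L) * C_in + 1L):(p * C_in)],
                 c(batch, cache$len_out, C_in))
    dXpad[, base_t + p, ] <-
      dXpad[, base_t + p, , drop = FALSE] + blk
  }
  dX <- dXpad[, cache$pad_left + seq_len(len_in), , drop = FALSE]
  list(dX = matrix(dX, batch * len_in, C_in), dW = dW, db = db)
}

# full forward pass; X is an (n_windows x input_len) matrix
cnn_forward <- function(model, X, training = FALSE) {
  batch <- nrow(X)
  len <- ncol(X)
  act <- matrix(as.vector(X), batch * len, 1)   # rows: sample fastest
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    sp <- model$spec$layers[[li]]
    st <- model$layers[[li]]
    cv <- conv1d_forward(act, st$W, st$b, sp$stride, sp$kernel,
                         batch, len, sp$in_channels)
    y <- cv$Y
    cache <- list(conv = cv, x_in = act, len_in = len)
    if (sp$batch_norm) {
      if (training) {
        mu <- colMeans(y)
        yc <- sweep(y, 2, mu)
        v <- colMeans(yc^2)
      } else {
        mu <- st$run_mean
        yc <- sweep(y, 2, mu)
        v <- st$run_var
      }
      inv_sd <- 1 / sqrt(v + BN_EPS)
      xhat <- sweep(yc, 2, inv_sd, "*")
      y <- sweep(sweep(xhat, 2, st$gamma, "*"), 2, st$beta, "+")
      cache$bn <- list(mu = mu, v = v, inv_sd = inv_sd, xhat = xhat,
                       training = training)
    }
    if (sp$activation == "leaky_relu") {
      cache$pre_act <- y
      y <- ifelse(y > 0, y, LEAKY_SLOPE * y)
    }
    caches[[li]] <- cache
    act <- y
    len <- cv$len_out
  }
  list(out = as.numeric(act), caches = caches, batch = batch)
}

# backward pass from d(out); returns per-layer gradients
cnn_backward <- function(model, fwd, dout) {
  grads <- vector("list", length(model$layers))
  dy <- matrix(dout, ncol = 1)
  for (li in rev(seq_along(model$layers))) {
    sp <- model$spec$layers[[li]]
    st <- model$layers[[li]]
    cache <- fwd$caches[[li]]
    g <- list()
    if (sp$activation == "leaky_relu") {
      dy <- dy * ifelse(cache$pre_act > 0, 1, LEAKY_SLOPE)
    }
    if (sp$batch_norm) {
      bn <- cache$bn
      n <- nrow(dy)
      g$dgamma <- colSums(dy * bn$xhat)
      g$dbeta <- colSums(dy)
      dxhat <- sweep(dy, 2, st$gamma, "*")
      # standard batch-norm backward using batch statistics
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(bn$xhat, 2, colMeans(dxhat * bn$xhat), "*")
      dy <- sweep(t1 - t2, 2, bn$inv_sd, "*")
    }
    cb <- conv1d_backward(cache$conv, st$W, dy, sp$stride, sp$kernel,
                          fwd$batch, cache$len_in, sp$in_channels)
    g$dW <- cb$dW
    g$db <- cb$db
    grads[[li]] <- g
    dy <- cb$dX
  }
  grads
}

#' Fit a target normalizer
#'
#' Mean and SD of heart rates, computed on the training set only and applied
#' in inverse at prediction time.
#'
#' @param hr_bpm training heart rates (NA dropped).
#' @return List with `mean_bpm` and `sd_bpm`; errors if the SD is zero.
#' @export
target_normalizer <- function(hr_bpm) {
  hr <- hr_bpm[!is.na(hr_bpm)]
  if (length(hr) == 0) stop("no defined heart rates to normalize")
  m <- mean(hr)
  s <- stats::sd(hr)
  if (!is.finite(s) || s <= 0) stop("zero-variance heart-rate targets")
  list(mean_bpm = m, sd_bpm = s)
}

#' Train the network
#'
#' Minimizes mean squared error between the normalized target heart rate and
#' the network output with Adam at its default parameters (learning rate
#' 0.001), plus an L2 penalty on the convolution kernels. Runs exactly
#' `epochs` epochs with no early stopping; the final state is returned.
#' Windows with undefined targets must be dropped by the caller.
#'
#' @param model a [cnn_build] model.
#' @param X training windows, `n x 400` matrix (already per-window
#'   normalized).
#' @param y_bpm training heart-rate targets in bpm, length `n`.
#' @param normalizer a [target_normalizer] fitted on the training subjects;
#'   fitted from `y_bpm` when `NULL`.
#' @param epochs number of epochs (default 30).
#' @param batch_size minibatch size (default 64).
#' @param lr,beta1,beta2,adam_eps Adam hyperparameters (Adam defaults).
#' @param l2_kernel_penalty L2 coefficient on convolution kernels
#'   (default 1e-4).
#' @param seed seed for shuffling (weight init is fixed by [cnn_build]).
#' @return List with `model` (trained), `normalizer` and `history`, a data
#'   frame (epoch, loss, mae_bpm, mape_pct) of training-set metrics on the
#'   denormalized scale.
#' @export
cnn_fit <- function(model, X, y_bpm, normalizer = NULL, epochs = 30L,
                    batch_size = 64L, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                    adam_eps = 1e-7, l2_kernel_penalty = 1e-4, seed = 1L) {
  stopifnot(nrow(X) == length(y_bpm))
  keep <- !is.na(y_bpm)
  X <- X[keep, , drop = FALSE]
  y_bpm <- y_bpm[keep]
  if (nrow(X) == 0) stop("empty training set")
  if (is.null(normalizer)) normalizer <- target_normalizer(y_bpm)
  y <- (y_bpm - normalizer$mean_bpm) / normalizer$sd_bpm
  n <- nrow(X)
  adam <- lapply(model$layers, function(st) {
    z <- function(x) array(0, dim = if (is.matrix(x)) dim(x) else length(x))
    s <- list(mW = z(st$W), vW = z(st$W), mb = z(st$b), vb = z(st$b))
    if (!is.null(st$gamma)) {
      s$mg <- z(st$gamma); s$vg <- z(st$gamma)
      s$mB <- z(st$beta); s$vB <- z(st$beta)
    }
    s
  })
  step <- 0L
  upd <- function(li, field, g, mname, vname) {
    adam[[li]][[mname]] <<- beta1 * adam[[li]][[mname]] + (1 - beta1) * g
    adam[[li]][[vname]] <<- beta2 * adam[[li]][[vname]] + (1 - beta2) * g^2
    mhat <- adam[[li]][[mname]] / (1 - beta1^step)
    vhat <- adam[[li]][[vname]] / (1 - beta2^step)
    model$layers[[li]][[field]] <<-
      model$layers[[li]][[field]] - lr * mhat / (sqrt(vhat) + adam_eps)
  }
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        mae_bpm = numeric(0), mape_pct = numeric(0))
  ord_seed <- seed
  for (ep in seq_len(epochs)) {
    ord <- with_local_seed(ord_seed + ep, sample.int(n))
    ep_loss <- 0
    ep_abs <- 0
    ep_ape <- 0
    for (b0 in seq(1, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fwd <- cnn_forward(model, Xb, training = TRUE)
      err <- fwd$out - yb
      loss <- mean(err^2)
      dout <- 2 * err / length(err)
      grads <- cnn_backward(model, fwd, dout)
      step <- step + 1L
      for (li in seq_along(model$layers)) {
        g <- grads[[li]]
        dW <- g$dW + 2 * l2_kernel_penalty * model$layers[[li]]$W
        upd(li, "W", dW, "mW", "vW")
        upd(li, "b", g$db, "mb", "vb")
        if (!is.null(g$dgamma)) {
          upd(li, "gamma", g$dgamma, "mg", "vg")
          upd(li, "beta", g$dbeta, "mB", "vB")
        }
        # running statistics for inference
        sp <- model$spec$layers[[li]]
        if (sp$batch_norm) {
          bn <- fwd$caches[[li]]$bn
          model$layers[[li]]$run_mean <-
            BN_MOMENTUM * model$layers[[li]]$run_mean + (1 - BN_MOMENTUM) * bn$mu
          model$layers[[li]]$run_var <-
            BN_MOMENTUM * model$layers[[li]]$run_var + (1 - BN_MOMENTUM) * bn$v
        }
      }
      pred_bpm <- fwd$out * normalizer$sd_bpm + normalizer$mean_bpm
      true_bpm <- yb * normalizer$sd_bpm + normalizer$mean_bpm
      ep_loss <- ep_loss + loss * length(idx)
      ep_abs <- ep_abs + sum(abs(pred_bpm - true_bpm))
      ep_ape <- ep_ape + sum(abs(pred_bpm - true_bpm) / true_bpm)
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / n,
                                mae_bpm = ep_abs / n,
                                mape_pct = 100 * ep_ape / n))
  }
  list(model = model, normalizer = normalizer, history = history)
}

#' Predict raw (normalized-scale) outputs
#'
#' Inference mode: batch norm uses running statistics.
#'
#' @param model a trained `cnn_model`.
#' @param X `n x 400` matrix of normalized windows.
#' @return Numeric vector of `n` raw network outputs.
#' @export
cnn_predict_raw <- function(model, X) {
  cnn_forward(model, X, training = FALSE)$out
}

#' Predict per-window heart rates
#'
#' Runs the network on every non-excluded window of a normalized window set
#' and denormalizes the outputs; excluded windows get the undefined sentinel.
#'
#' @param model a trained `cnn_model`.
#' @param ws a [normalize_windows] window set.
#' @param normalizer the [target_normalizer] used in training.
#' @return Data frame (subject_id, window_index, window_start_ms, hr_bpm,
#'   n_peaks = NA, source = "cnn").
#' @export
cnn_predict_hr <- function(model, ws, normalizer) {
  n_win <- nrow(ws$windows)
  hr <- rep(NA_real_, n_win)
  act <- which(!ws$excluded)
  if (length(act) > 0) {
    raw <- cnn_predict_raw(model, ws$windows[act, , drop = FALSE])
    hr[act] <- raw * normalizer$sd_bpm + normalizer$mean_bpm
  }
  data.frame(subject_id = ws$subject_id, window_index = seq_len(n_win),
             window_start_ms = ws$start_times_ms, hr_bpm = hr,
             n_peaks = NA_integer_, source = "cnn")
}

#' Subject-level train/test split
#'
#' Randomly assigns subjects to the training set (default two thirds, as in a
#' 16/8 split of 24) before any optimization; no subject contributes windows
#' to both sides.
#'
#' @param subject_ids character vector of unique subject ids.
#' @param train_fraction fraction of subjects in the training set
#'   (default 2/3).
#' @param seed split seed.
#' @return List with `train` and `test` id vectors.
#' @export
split_subjects <- function(subject_ids, train_fraction = 2 / 3, seed = 1L) {
  ids <- unique(subject_ids)
  n_train <- round(length(ids) * train_fraction)
  if (n_train < 1 || n_train >= length(ids))
    stop("split leaves an empty train or test set")
  train <- with_local_seed(seed, sample(ids, n_train))
  list(train = sort(train), test = sort(setdiff(ids, train)))
}
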