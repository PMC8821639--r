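#' Classifier architecture and training hyperparameters
#'
#' The classifier is a small 1D convolutional network: two
#' convolution+ReLU+max-pool stages over the position axis, a dropout
#' layer, then a single fully connected sigmoid output giving the
#' probability that the protein is a pore former. Training minimises the
#' mean squared error between that probability and the 0/1 label.
#'
#' Defaults follow the reference architecture for full-length (2000
#' position) inputs: 25 filters of width 100, a second convolution of 25
#' filters of width 50, pool size 5 and dropout 0.25. For short synthetic
#' sequences use proportionally smaller kernels (see
#' [benchmark_model_config()]).
#'
#' @param conv1_filters,conv1_kernel First convolution: filter count and
#'   width in positions.
#' @param conv2_filters,conv2_kernel Second convolution.
#' @param pool_size Max-pool window (and stride) after each convolution.
#' @param dropout_rate Dropout fraction in \[0, 1) applied after the second
#'   pool during training.
#' @param learning_rate Adam step size.
#' @param epochs,batch_size Training schedule.
#' @param seed Integer seed making initialisation, shuffling and dropout
#'   reproducible.
#' @return A list of class `model_config`. Activation is rectified-linear,
#'   loss is mean squared error, pooling is max; these are fixed by the
#'   architecture.
#' @export
model_config <- function(conv1_filters = 25L, conv1_kernel = 100L,
                         conv2_filters = 25L, conv2_kernel = 50L,
                         pool_size = 5L, dropout_rate = 0.25,
                         learning_rate = 1e-3, epochs = 30L,
                         batch_size = 32L, seed = 1L) {
  stopifnot(conv1_filters >= 1, conv2_filters >= 1,
            conv1_kernel >= 1, conv2_kernel >= 1, pool_size >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(conv1_filters = as.integer(conv1_filters),
                 conv1_kernel = as.integer(conv1_kernel),
                 conv2_filters = as.integer(conv2_filters),
                 conv2_kernel = as.integer(conv2_kernel),
                 pool_size = as.integer(pool_size),
                 dropout_rate = dropout_rate,
                 activation = "relu", loss = "mse", optimizer = "adam",
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Model configuration scaled for the synthetic benchmark
#'
#' Same architecture with kernels 20/10 instead of 100/50, matched to
#' benchmark sequences of 100-400 residues padded to 400 positions.
#' @param conv1_kernel,conv2_kernel,epochs,learning_rate Scaled-down
#'   defaults; see [model_config()].
#' @param ... Further overrides passed to [model_config()].
#' @export
benchmark_model_config <- function(conv1_kernel = 20L, conv2_kernel = 10L,
                                   epochs = 30L, learning_rate = 2e-3, ...) {
  model_config(conv1_kernel = conv1_kernel, conv2_kernel = conv2_kernel,
               epochs = epochs, learning_rate = learning_rate, ...)
}

# Layer-by-layer output lengths along the position axis.
layer_lengths <- function(config, pad_length) {
  p1 <- pad_length - config$conv1_kernel + 1L
  q1 <- p1 %/% config$pool_size
  p2 <- q1 - config$conv2_kernel + 1L
  q2 <- p2 %/% config$pool_size
  list(conv1 = p1, pool1 = q1, conv2 = p2, pool2 = q2)
}

#' Build an untrained classifier
#'
#' Instantiates the layer stack for a given input shape and checks that
#' each kernel fits the (post-pooling) length it convolves over. Weights
#' are initialised during [train_model()], seeded by the configuration.
#'
#' @param config A [model_config()].
#' @param input_shape Integer pair `(pad_length, channels)` the model will
#'   accept, e.g. `c(2000, 33)` for combined encoding.
#' @return An object of class `pf_cnn` with `$config`, `$input_shape`,
#'   `$n_parameters` and unset weights.
#' @examples
#' m <- build_model(model_config(), input_shape = c(2000, 33))
#' m$n_parameters
#' @export
build_model <- function(config, input_shape) {
  stopifnot(inherits(config, "model_config"), length(input_shape) == 2L)
  L <- as.integer(input_shape[1L]); C <- as.integer(input_shape[2L])
  ll <- layer_lengths(config, L)
  if (ll$conv1 < 1L) {
    stop("conv1 kernel (", config$conv1_kernel,
         ") exceeds the input length (", L, ")", call. = FALSE)
  }
  if (ll$pool1 < 1L) {
    stop("pool size ", config$pool_size, " leaves no positions after conv1 (",
         ll$conv1, " positions)", call. = FALSE)
  }
  if (ll$conv2 < 1L) {
    stop("conv2 kernel (", config$conv2_kernel,
         ") exceeds the post-pooling length (", ll$pool1, ")", call. = FALSE)
  }
  if (ll$pool2 < 1L) {
    stop("pool size ", config$pool_size, " leaves no positions after conv2 (",
         ll$conv2, " positions)", call. = FALSE)
  }
  n_par <- (config$conv1_kernel * C + 1L) * config$conv1_filters +
    (config$conv2_kernel * config$conv1_filters + 1L) * config$conv2_filters +
    (ll$pool2 * config$conv2_filters + 1L)
  structure(list(config = config, input_shape = c(L, C),
                 layer_lengths = ll, n_parameters = n_par,
                 weights = NULL, scheme = NULL, version = 1L),
            class = "pf_cnn")
}

#' @export
print.pf_cnn <- function(x, ...) {
  cat("<pf_cnn> input ", x$input_shape[1L], "x", x$input_shape[2L],
      ", conv ", x$config$conv1_filters, "x", x$config$conv1_kernel,
      " -> pool ", x$config$pool_size,
      " -> conv ", x$config$conv2_filters, "x", x$config$conv2_kernel,
      " -> pool -> dropout ", x$config$dropout_rate,
      " -> dense 1 (sigmoid); ", x$n_parameters, " parameters",
      if (is.null(x$weights)) " [untrained]" else " [trained]", "\n", sep = "")
  invisible(x)
}

# ---- network internals -----------------------------------------------------
# Batches are stacked sample-major: an (n*P) x C matrix holds sample i's
# positions in rows (i-1)*P + 1 .. i*P. Convolutions are im2col + one BLAS
# matrix product; max-pooling is a pmax sweep that records argmax offsets
# for the backward pass.

sigmoid <- function(z) 1 / (1 + exp(-z))

.im2col_cache <- new.env(parent = emptyenv())

# Linear indices turning a stacked (n*L) x C activation (or an L x C x n
# array flattened the same way) into the im2col matrix (n*P) x (k*C).
# Cached per shape: the same index matrix is reused every batch.
im2col_index <- function(L, C, k, n, stacked) {
  key <- paste(L, C, k, n, stacked, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- im2col_index_build(L, C, k, n, stacked)
  .im2col_cache[[key]] <- out
  out
}

im2col_index_build <- function(L, C, k, n, stacked) {
  P <- L - k + 1L
  jj <- rep(seq_len(k), each = C)          # kernel offset per column
  cc <- rep(seq_len(C), times = k)         # channel per column
  if (stacked) {
    # element (p, c, i) lives at row (i-1)*L + p, col c of an (n*L) x C matrix
    col_off <- (cc - 1L) * (n * L)
    base <- outer(seq_len(P), jj - 1L, `+`)            # P x kC position part
    base <- base + matrix(col_off, P, k * C, byrow = TRUE)
    samp <- rep((seq_len(n) - 1L) * L, each = P)
    base[rep(seq_len(P), times = n), , drop = FALSE] + samp
  } else {
    # element (p, c, i) lives at p + (c-1)*L + (i-1)*L*C of an L x C x n array
    base <- outer(seq_len(P), jj - 1L, `+`) +
      matrix((cc - 1L) * L, P, k * C, byrow = TRUE)
    samp <- rep((seq_len(n) - 1L) * (L * C), each = P)
    base[rep(seq_len(P), times = n), , drop = FALSE] + samp
  }
}

# Non-overlapping max pool over the position axis of a stacked (n*P) x F
# matrix. Returns pooled (n*Q) x F matrix, argmax offsets, and the row
# index sets used (needed again for the backward scatter).
pool_forward <- function(A, P, n, pool) {
  Q <- P %/% pool
  F_ <- ncol(A)
  rows <- lapply(seq_len(pool), function(j) {
    rep((seq_len(n) - 1L) * P, each = Q) +
      rep(seq(0L, by = pool, length.out = Q), times = n) + j
  })
  best <- A[rows[[1L]], , drop = FALSE]
  amax <- matrix(1L, n * Q, F_)
  if (pool > 1L) {
    for (j in 2L:pool) {
      cand <- A[rows[[j]], , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      amax[upd] <- j
    }
  }
  list(out = best, amax = amax, rows = rows, Q = Q)
}

pool_backward <- function(dOut, pool_fwd, P, n) {
  dA <- matrix(0, n * P, ncol(dOut))
  for (j in seq_along(pool_fwd$rows)) {
    sel <- pool_fwd$amax == j
    if (any(sel)) {
      tmp <- dA[pool_fwd$rows[[j]], , drop = FALSE]
      tmp[sel] <- tmp[sel] + dOut[sel]
      dA[pool_fwd$rows[[j]], ] <- tmp
    }
  }
  dA
}

# Forward pass. x: L x C x n array. Returns scores and, if keep = TRUE,
# the intermediates needed by the backward pass. dropout_mask NULL means
# inference (no dropout).
cnn_forward <- function(w, cfg, ll, x, keep = FALSE, dropout_mask = NULL) {
  d <- dim(x); L <- d[1L]; C <- d[2L]; n <- d[3L]
  p <- cfg$pool_size
  i1 <- im2col_index(L, C, cfg$conv1_kernel, n, stacked = FALSE)
  M1 <- matrix(x[as.vector(i1)], nrow(i1), ncol(i1))
  Z1 <- M1 %*% w$W1 + matrix(w$b1, nrow(M1), cfg$conv1_filters, byrow = TRUE)
  A1 <- pmax(Z1, 0)
  pf1 <- pool_forward(A1, ll$conv1, n, p)
  i2 <- im2col_index(ll$pool1, cfg$conv1_filters, cfg$conv2_kernel, n,
                     stacked = TRUE)
  M2 <- matrix(pf1$out[as.vector(i2)], nrow(i2), ncol(i2))
  Z2 <- M2 %*% w$W2 + matrix(w$b2, nrow(M2), cfg$conv2_filters, byrow = TRUE)
  A2 <- pmax(Z2, 0)
  pf2 <- pool_forward(A2, ll$conv2, n, p)
  # flatten: sample i's (Q2 x F2) block, position-major within channel
  Harr <- array(pf2$out, dim = c(ll$pool2, n, cfg$conv2_filters))
  H <- t(matrix(aperm(Harr, c(1L, 3L, 2L)),
                ll$pool2 * cfg$conv2_filters, n))
  Hd <- if (is.null(dropout_mask)) H else H * dropout_mask
  yhat <- as.vector(sigmoid(Hd %*% w$W3 + w$b3))
  if (!keep) return(yhat)
  list(yhat = yhat, M1 = M1, Z1 = Z1, pf1 = pf1, M2 = M2, Z2 = Z2,
       pf2 = pf2, Hd = Hd, n = n)
}

# Backward pass for MSE loss (mean over the batch). Returns gradients with
# the same shapes as the weights.
cnn_backward <- function(w, cfg, ll, fwd, y, dropout_mask) {
  n <- fwd$n
  yhat <- fwd$yhat
  dz3 <- (2 / n) * (yhat - y) * yhat * (1 - yhat)       # through sigmoid
  dW3 <- crossprod(fwd$Hd, dz3)
  db3 <- sum(dz3)
  dH <- outer(dz3, as.vector(w$W3))                     # n x D
  if (!is.null(dropout_mask)) dH <- dH * dropout_mask
  # unflatten to stacked (n*Q2) x F2
  Darr <- array(t(dH), dim = c(ll$pool2, cfg$conv2_filters, n))
  dP2 <- matrix(aperm(Darr, c(1L, 3L, 2L)), n * ll$pool2, cfg$conv2_filters)
  dA2 <- pool_backward(dP2, fwd$pf2, ll$conv2, n)
  dZ2 <- dA2 * (fwd$Z2 > 0)
  dW2 <- crossprod(fwd$M2, dZ2)
  db2 <- colSums(dZ2)
  dM2 <- tcrossprod(dZ2, w$W2)                          # (n*P2) x (k2*F1)
  # col2im back onto the stacked pool1 output
  dP1 <- matrix(0, n * ll$pool1, cfg$conv1_filters)
  P2 <- ll$conv2
  for (j in seq_len(cfg$conv2_kernel)) {
    tgt <- rep((seq_len(n) - 1L) * ll$pool1, each = P2) + rep(seq_len(P2), n) +
      (j - 1L)
    cols <- ((j - 1L) * cfg$conv1_filters + 1L):(j * cfg$conv1_filters)
    dP1[tgt, ] <- dP1[tgt, , drop = FALSE] + dM2[, cols, drop = FALSE]
  }
  dA1 <- pool_backward(dP1, fwd$pf1, ll$conv1, n)
  dZ1 <- dA1 * (fwd$Z1 > 0)
  dW1 <- crossprod(fwd$M1, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

init_weights <- function(cfg, C, D) {
  k1C <- cfg$conv1_kernel * C
  k2F <- cfg$conv2_kernel * cfg$conv1_filters
  list(
    W1 = matrix(stats::rnorm(k1C * cfg$conv1_filters, sd = sqrt(2 / k1C)),
                k1C, cfg$conv1_filters),
    b1 = numeric(cfg$conv1_filters),
    W2 = matrix(stats::rnorm(k2F * cfg$conv2_filters, sd = sqrt(2 / k2F)),
                k2F, cfg$conv2_filters),
    b2 = numeric(cfg$conv2_filters),
    W3 = matrix(stats::rnorm(D, sd = sqrt(1 / D)), D, 1L),
    b3 = 0
  )
}

adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$w[[nm]] <- state$w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Train the classifier
#'
#' Fits the network by mini-batch Adam on the mean-squared-error loss
#' between the sigmoid output and the 0/1 label, recording accuracy (at
#' threshold 0.5) and loss on the training and validation sets after every
#' epoch. Fully reproducible: the configuration seed drives weight
#' initialisation, epoch shuffling and dropout masks, so the same seed
#' yields the same history and parameters.
#'
#' @param model An untrained [build_model()] result (a trained model is
#'   re-initialised).
#' @param train A `pf_tensors` batch with labels in \{0, 1\}.
#' @param validation Optional `pf_tensors` batch for per-epoch validation
#'   metrics.
#' @param verbose Print per-epoch metrics.
#' @return The trained `pf_cnn` with a `history` tibble attached (columns
#'   `epoch`, `train_loss`, `train_accuracy`, `val_loss`, `val_accuracy`).
#' @export
train_model <- function(model, train, validation = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "pf_cnn"), inherits(train, "pf_tensors"))
  cfg <- model$config
  ll <- model$layer_lengths
  check_shape(model, train)
  y <- train$labels
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("training labels must be 0/1 with no unknowns", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; cannot learn a discrimination",
         call. = FALSE)
  }
  if (!is.null(validation)) check_shape(model, validation)
  n <- length(y)
  D <- ll$pool2 * cfg$conv2_filters
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  w <- init_weights(cfg, model$input_shape[2L], D)
  zero <- lapply(w, function(p) p * 0)
  state <- list(w = w, m = zero, v = zero)
  t_step <- 0L
  hist <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- train$x[, , idx, drop = FALSE]
      yb <- y[idx]
      mask <- if (cfg$dropout_rate > 0) {
        matrix((stats::runif(length(idx) * D) >= cfg$dropout_rate) /
                 (1 - cfg$dropout_rate), length(idx), D)
      } else NULL
      fwd <- cnn_forward(state$w, cfg, ll, xb, keep = TRUE,
                         dropout_mask = mask)
      grads <- cnn_backward(state$w, cfg, ll, fwd, yb, mask)
      t_step <- t_step + 1L
      state <- adam_step(state, grads, cfg$learning_rate, t_step)
    }
    tr <- eval_metrics(state$w, cfg, ll, train)
    va <- if (is.null(validation)) c(loss = NA_real_, accuracy = NA_real_) else
      eval_metrics(state$w, cfg, ll, validation)
    hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                    train_loss = tr[["loss"]],
                                    train_accuracy = tr[["accuracy"]],
                                    val_loss = va[["loss"]],
                                    val_accuracy = va[["accuracy"]])
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f acc %.3f  val_loss %.4f val_acc %.3f",
                      epoch, tr[["loss"]], tr[["accuracy"]],
                      va[["loss"]], va[["accuracy"]]))
    }
  }
  model$weights <- state$w
  model$scheme <- train$scheme
  model$history <- dplyr::bind_rows(hist)
  model
}

eval_metrics <- function(w, cfg, ll, tensors, chunk = 256L) {
  s <- predict_scores(w, cfg, ll, tensors$x, chunk)
  y <- tensors$labels
  c(loss = mean((s - y)^2), accuracy = mean((s >= 0.5) == y))
}

predict_scores <- function(w, cfg, ll, x, chunk = 256L) {
  n <- dim(x)[3L]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx] <- cnn_forward(w, cfg, ll, x[, , idx, drop = FALSE])
  }
  out
}

check_shape <- function(model, tensors) {
  got <- dim(tensors$x)[1:2]
  if (!identical(as.integer(got), as.integer(model$input_shape))) {
    stop("tensor shape (", got[1L], ", ", got[2L],
         ") does not match the model input shape (",
         model$input_shape[1L], ", ", model$input_shape[2L], ")",
         call. = FALSE)
  }
  if (!is.null(model$scheme) && !is.null(tensors$scheme) &&
      !identical(model$scheme, tensors$scheme)) {
    stop("model was trained on '", model$scheme,
         "' encoding but received '", tensors$scheme, "' tensors",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Score sequences with a trained classifier
#'
#' @param object A trained `pf_cnn`.
#' @param tensors A `pf_tensors` batch with the shape (and encoding
#'   scheme) the model was trained for.
#' @param ... Unused.
#' @return A tibble with `id`, `score` in \[0, 1\] and `family`, in input
#'   order. Inference is deterministic: dropout is inactive.
#' @export
predict.pf_cnn <- function(object, tensors, ...) {
  if (is.null(object$weights)) stop("model is untrained", call. = FALSE)
  stopifnot(inherits(tensors, "pf_tensors"))
  check_shape(object, tensors)
  s <- predict_scores(object$weights, object$config, object$layer_lengths,
                      tensors$x)
  tibble::tibble(id = tensors$ids, score = s, label = tensors$labels,
                 family = tensors$family)
}

#' Threshold scores into binary calls
#'
#' @param scores Numeric scores in \[0, 1\] (or a prediction tibble with a
#'   `score` column).
#' @param threshold Decision threshold in \[0, 1\]; a record is called a
#'   pore former when `score >= threshold`.
#' @return Integer 0/1 vector (or the tibble with a `call` column added).
#' @examples
#' classify_scores(c(0.2, 0.5, 0.9), 0.5)  # 0 1 1
#' @export
classify_scores <- function(scores, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  if (is.data.frame(scores)) {
    scores$call <- as.integer(scores$score >= threshold)
    return(scores)
  }
  if (any(scores < 0 | scores > 1)) {
    stop("scores must be in [0, 1]", call. = FALSE)
  }
  as.integer(scores >= threshold)
}

#' Save / load a trained classifier
#'
#' The archive is a single versioned RDS file embedding the configuration,
#' weights and encoding-scheme tag, so a reloaded model reproduces
#' predictions exactly and can verify input provenance.
#'
#' @param model A `pf_cnn`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `pf_cnn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pf_cnn"))
  saveRDS(list(format = "poreformer_cnn", version = model$version,
               model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model archive ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "poreformer_cnn")) {
    stop("not a poreformer model archive: ", path, call. = FALSE)
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported model archive version: ", obj$version, call. = FALSE)
  }
  structure(obj$model, class = "pf_cnn")
}
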