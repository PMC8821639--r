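test_that("parameter count matches the hand-computed closed form", {
  cfg <- model_config(conv1_filters = 2L, conv1_kernel = 5L,
                      conv2_filters = 2L, conv2_kernel = 3L,
                      pool_size = 5L)
  m <- build_model(cfg, input_shape = c(50L, 5L))
  # conv1: (5*5+1)*2; positions 46 -> pool 9 -> conv2 7 -> pool 1
  # conv2: (3*2+1)*2; dense: (1*2+1)*1
  expect_equal(m$n_parameters, (5 * 5 + 1) * 2 + (3 * 2 + 1) * 2 + (1 * 2 + 1))
  expect_equal(m$layer_lengths,
               list(conv1 = 46L, pool1 = 9L, conv2 = 7L, pool2 = 1L))
  # default configuration at full scale: 25 filters spanning 100 x 33
  big <- build_model(model_config(), input_shape = c(2000L, 33L))
  expect_equal(dim(big$weights$W1), NULL)  # untrained
  expect_equal(big$n_parameters,
               (100 * 33 + 1) * 25 + (50 * 25 + 1) * 25 +
                 (((((2000 - 100 + 1) %/% 5) - 50 + 1) %/% 5) * 25 + 1))
})

test_that("kernels that do not fit the (post-pooling) length are rejected", {
  expect_error(build_model(model_config(conv1_kernel = 60L), c(50L, 5L)),
               "conv1 kernel")
  expect_error(build_model(model_config(conv1_kernel = 10L, pool_size = 5L,
                                        conv2_kernel = 50L), c(60L, 5L)),
               "conv2 kernel")
})

test_that("analytic gradients match finite differences on every layer", {
  cfg <- model_config(conv1_filters = 2L, conv1_kernel = 5L,
                      conv2_filters = 3L, conv2_kernel = 3L,
                      pool_size = 2L, dropout_rate = 0, seed = 3L)
  mod <- build_model(cfg, c(24L, 4L))
  ll <- mod$layer_lengths
  set.seed(99)
  x <- array(stats::rnorm(24 * 4 * 5), c(24L, 4L, 5L))
  y <- c(1, 0, 1, 1, 0)
  w <- poreformer:::init_weights(cfg, 4L, ll$pool2 * cfg$conv2_filters)
  fwd <- poreformer:::cnn_forward(w, cfg, ll, x, keep = TRUE)
  gr <- poreformer:::cnn_backward(w, cfg, ll, fwd, y, NULL)
  loss_at <- function(w) mean((poreformer:::cnn_forward(w, cfg, ll, x) - y)^2)
  eps <- 1e-6
  for (nm in names(gr)) {
    k <- min(8L, length(w[[nm]]))
    idx <- round(seq(1L, length(w[[nm]]), length.out = k))
    fd <- vapply(idx, function(i) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      (loss_at(wp) - loss_at(wm)) / (2 * eps)
    }, numeric(1))
    expect_equal(fd, as.vector(gr[[nm]])[idx], tolerance = 1e-5,
                 label = paste("finite-difference gradient for", nm))
  }
})

test_that("training learns a separable bump pattern to perfect accuracy", {
  fit <- fitted_toy()
  hist <- fit$history
  expect_equal(nrow(hist), fit$config$epochs)
  expect_equal(max(hist$train_accuracy), 1.0)
  expect_lt(min(hist$train_loss), 0.02)
})

test_that("training is bit-reproducible under a fixed seed", {
  toy <- toy_bump_tensors(seed = 5L)
  cfg <- toy_model_config(epochs = 4L, dropout_rate = 0.25)
  m1 <- train_model(build_model(cfg, c(40L, 2L)), toy$tensors)
  m2 <- train_model(build_model(cfg, c(40L, 2L)), toy$tensors)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
})

test_that("shuffled labels give chance-level performance", {
  toy <- toy_bump_tensors(seed = 5L)
  set.seed(13)
  null_tensors <- toy$tensors
  null_tensors$labels <- sample(null_tensors$labels)
  holdout <- toy_bump_tensors(seed = 6L)$tensors
  m <- train_model(build_model(toy_model_config(), c(40L, 2L)), null_tensors)
  preds <- predict(m, holdout)
  acc <- mean((preds$score >= 0.5) == holdout$labels)
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
})

test_that("predictions are deterministic, ordered, and inside [0, 1]", {
  fit <- fitted_toy()
  toy <- toy_bump_tensors(seed = 5L)
  p1 <- predict(fit, toy$tensors)
  p2 <- predict(fit, toy$tensors)
  expect_identical(p1, p2)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_equal(p1$id, toy$tensors$ids)
  # duplicated input gives identical scores
  dup <- toy$tensors[c(1L, 1L)]
  pd <- predict(fit, dup)
  expect_equal(pd$score[1], pd$score[2])
  # trained separable model separates at 0.5
  expect_true(all(p1$score[toy$tensors$labels == 1] > 0.5))
  expect_true(all(p1$score[toy$tensors$labels == 0] < 0.5))
})

test_that("score shifts little when the motif moves less than the pool size", {
  fit <- fitted_toy()
  set.seed(21)
  L <- 40L
  base <- array(stats::rnorm(L * 2L * 20L, sd = 0.3), c(L, 2L, 20L))
  base[, 1, ] <- 0
  shifted <- base
  for (i in 1:20) {
    at <- sample(L - 8L - 4L, 1L)
    base[at:(at + 7L), 1, i] <- 1
    shifted[(at + 3L):(at + 10L), 1, i] <- 1   # shift 3 < pool size 5
  }
  s0 <- predict(fit, as_tensors(base, rep(1, 20)))$score
  s1 <- predict(fit, as_tensors(shifted, rep(1, 20)))$score
  expect_lt(mean(abs(s1 - s0)), 0.1)
})

test_that("shape and scheme mismatches are rejected with informative errors", {
  fit <- fitted_toy()
  bad <- as_tensors(array(0, c(41L, 2L, 1L)), 1)
  expect_error(predict(fit, bad), "\\(41, 2\\).*\\(40, 2\\)")
  expect_error(predict(build_model(toy_model_config(), c(40L, 2L)),
                       toy_bump_tensors()$tensors), "untrained")
  # single-class training set
  toy <- toy_bump_tensors(seed = 5L)
  ones <- toy$tensors[toy$tensors$labels == 1]
  expect_error(train_model(build_model(toy_model_config(), c(40L, 2L)), ones),
               "single class")
})

test_that("classification thresholds scores as documented", {
  expect_equal(classify_scores(c(0.2, 0.5, 0.9), 0.5), c(0L, 1L, 1L))
  expect_equal(classify_scores(c(0.2, 0.5, 0.9), 0), c(1L, 1L, 1L))
  expect_equal(classify_scores(c(0.2, 0.5, 1), 1), c(0L, 0L, 1L))
  expect_error(classify_scores(0.5, 1.5), "threshold")
  d <- tibble::tibble(id = "a", score = 0.7)
  expect_equal(classify_scores(d)$call, 1L)
})

test_that("a saved model reloads to identical predictions", {
  fit <- fitted_toy()
  toy <- toy_bump_tensors(seed = 5L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(predict(back, toy$tensors)$score,
                   predict(fit, toy$tensors)$score)
  expect_identical(back$scheme, fit$scheme)
  # corrupted archive fails cleanly
  writeLines("not a model", path)
  expect_error(load_model(path), "model archive")
})
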