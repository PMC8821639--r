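# Shared fixtures. Heavy objects (the trained benchmark classifiers) are
# built once per test run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Raw tensor batch without going through sequences, for model unit tests.
as_tensors <- function(x, labels, scheme = NULL) {
  structure(list(x = x, ids = sprintf("t%03d", seq_len(dim(x)[3])),
                 labels = labels, family = rep(NA_character_, dim(x)[3]),
                 true_length = rep(dim(x)[1], dim(x)[3]),
                 scheme = scheme, pad_length = dim(x)[1],
                 channels = dim(x)[2]),
            class = "pf_tensors")
}

# Linearly separable toy set: positives carry an 8-wide block of ones on
# channel 1 at a random position; channel 2 is noise for both classes.
toy_bump_tensors <- function(n_per_class = 30L, L = 40L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(stats::rnorm(L * 2L * n, sd = 0.3), c(L, 2L, n))
  x[, 1, ] <- 0
  starts <- integer(n)
  for (i in seq_len(n_per_class)) {
    starts[i] <- sample(L - 8L + 1L, 1L)
    x[starts[i]:(starts[i] + 7L), 1, i] <- 1
  }
  list(tensors = as_tensors(x, c(rep(1, n_per_class), rep(0, n_per_class))),
       starts = starts)
}

toy_model_config <- function(epochs = 40L, dropout_rate = 0, ...) {
  model_config(conv1_filters = 4L, conv1_kernel = 5L, conv2_filters = 4L,
               conv2_kernel = 3L, pool_size = 5L,
               dropout_rate = dropout_rate, learning_rate = 5e-3,
               epochs = epochs, batch_size = 10L, seed = 7L, ...)
}

fitted_toy <- function() {
  memo("toy_fit", function() {
    toy <- toy_bump_tensors(seed = 5L)
    model <- build_model(toy_model_config(), input_shape = c(40L, 2L))
    train_model(model, toy$tensors)
  })
}

# The default synthetic benchmark with a trained combined-encoding model,
# shared by the acceptance suite.
fitted_benchmark <- function(signal = 1) {
  memo(paste0("bench_fit_", signal), function() {
    cfg <- synthetic_config(seed = 7L, signal_strength = signal)
    bench <- make_benchmark(cfg)
    ev <- run_benchmark(bench$dataset, benchmark_model_config(seed = 7L),
                        scheme = "combined", pad_length = 400L,
                        holdout = if (signal == 1) bench$holdout else NULL,
                        seed = 7L)
    list(bench = bench, eval = ev)
  })
}
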