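test_that("stratified splits obey the partition law for all seeds", {
  set.seed(83)
  d <- sequence_tbl(sprintf("s%03d", 1:100),
                    replicate(100, random_protein(60)),
                    label = rep(c("positive", "negative"), each = 50))
  for (seed in 1:5) {
    sp <- split_dataset(d, 0.8, seed = seed)
    expect_equal(nrow(sp$train), 80L)
    expect_equal(nrow(sp$test), 20L)
    expect_length(intersect(sp$train$id, sp$test$id), 0L)
    expect_setequal(c(sp$train$id, sp$test$id), d$id)
    # stratification: 40/10 per class
    expect_equal(as.integer(table(sp$train$label)), c(40L, 40L))
    expect_equal(as.integer(table(sp$test$label)), c(10L, 10L))
  }
  s1 <- split_dataset(d, 0.8, seed = 3)
  s2 <- split_dataset(d, 0.8, seed = 3)
  expect_identical(s1$train$id, s2$train$id)
  s3 <- split_dataset(d, 0.8, seed = 3, trial = 2)
  expect_false(identical(s1$train$id, s3$train$id))
})

test_that("degenerate splits are refused with advice", {
  d <- sequence_tbl(c("a", "b"), c("MKVLA", "GGALK"),
                    label = c("positive", "negative"))
  expect_error(split_dataset(d, 0.5), "larger dataset")
})

test_that("ROC curves are monotone with correct endpoints and trapezoid AUC", {
  r <- compute_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(roc_auc(r), 1.0)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  set.seed(89)
  for (k in 1:10) {
    n <- sample(10:60, 1)
    scores <- round(stats::runif(n), 2)  # force ties
    labels <- stats::rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- compute_roc(scores, labels)
    expect_true(all(diff(r$fpr) >= 0))
    expect_true(all(diff(r$tpr) >= 0))
    expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
    expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  }
  expect_error(compute_roc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the exhaustive Mann-Whitney statistic", {
  set.seed(97)
  for (k in 1:50) {
    n <- sample(4:200, 1)
    scores <- if (k %% 2) stats::runif(n) else round(stats::runif(n), 1)
    labels <- stats::rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(roc_auc(compute_roc(scores, labels)),
                 oracle_auc(scores, labels))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(101)
  scores <- stats::runif(80)
  labels <- stats::rbinom(80, 1, 0.5)
  expect_equal(roc_auc(compute_roc(scores, labels)),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("per-class ROC separates families and inverts the negative curve", {
  # idealised scorer: positives 1, negatives 0
  preds <- tibble::tibble(
    score = c(rep(1, 6), rep(0, 6)),
    label = c(rep(1, 6), rep(0, 6)),
    family = c(rep("alpha", 3), rep("beta", 3), rep(NA, 6)))
  curves <- per_class_roc(preds)
  expect_setequal(names(curves), c("alpha", "beta", "negative", "average"))
  for (cv in curves) expect_equal(roc_auc(cv), 1.0)
  # random scores give chance-level AUCs (fixed seed)
  set.seed(103)
  preds2 <- preds
  preds2$score <- stats::runif(12)
  curves2 <- per_class_roc(preds2)
  for (cv in curves2) {
    expect_gte(roc_auc(cv), 0.1)
    expect_lte(roc_auc(cv), 0.9)
  }
  expect_error(per_class_roc(preds[preds$label == 1, ]), "both positives")
})

test_that("holdout evaluation guards against train/holdout overlap", {
  fit <- fitted_toy()
  hold <- sequence_tbl(c("h1", "h2"), c("MKVLA", "GGALK"), label = "positive",
                       family = "novel")
  train <- sequence_tbl(c("h1", "t2"), c("MKVLA", "AAKKL"),
                        label = "positive")
  expect_error(holdout_family_eval(fit, hold, train), "protocol|present")
})

test_that("holdout detection counts respect the threshold", {
  # scores everything near zero: nothing detected
  toy <- toy_bump_tensors(seed = 5L)
  fit <- fitted_toy()
  neg_only <- toy$tensors[toy$tensors$labels == 0]
  preds <- classify_scores(predict(fit, neg_only), 0.5)
  expect_equal(sum(preds$call), 0L)
  expect_lte(sum(preds$call), nrow(preds))
})
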