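#' Stratified train/test split
#'
#' Randomised split of a sequence table (or any tibble with a `label`
#' column) into training and test partitions, stratified by label so both
#' classes appear on each side even at small n. Reproducible per
#' `(seed, trial)`.
#'
#' @param data A tibble with a `label` column.
#' @param train_fraction Fraction assigned to training (default 0.80).
#' @param seed Integer seed.
#' @param trial Trial index; different trials give different randomised
#'   splits under the same seed.
#' @return A list of class `pf_split` with tibbles `train` and `test`
#'   (disjoint, union = input).
#' @examples
#' d <- sequence_tbl(paste0("s", 1:10), strrep("MKVA", 15),
#'                   label = rep(c("positive", "negative"), 5))
#' sp <- split_dataset(d, seed = 7)
#' nrow(sp$train); nrow(sp$test)  # 8 and 2
#' @export
split_dataset <- function(data, train_fraction = 0.80, seed = 1L, trial = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, "label" %in% names(data))
  rng <- local_rng(seed + 7919L * (trial - 1L))
  on.exit(rng())
  idx_train <- integer(0)
  for (cls in unique(data$label)) {
    rows <- which(data$label == cls)
    if (length(rows) < 2L) {
      stop("class '", cls, "' has fewer than 2 records; ",
           "use a larger dataset", call. = FALSE)
    }
    k <- round(train_fraction * length(rows))
    if (k < 1L || k >= length(rows)) {
      stop("class '", cls, "' would be absent from one side of the split; ",
           "use a larger dataset", call. = FALSE)
    }
    idx_train <- c(idx_train, sample(rows, k))
  }
  idx_train <- sort(idx_train)
  structure(list(train = data[idx_train, , drop = FALSE],
                 test = data[-idx_train, , drop = FALSE]),
            class = "pf_split")
}

# Save/restore the global RNG state around seeded internals.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  }
}

#' ROC curve from scores and binary labels
#'
#' Sweeps every distinct score as a threshold (ties grouped into one
#' step), producing a curve of (false positive rate, true positive rate)
#' points from (0,0) to (1,1), with the area under it computed by the
#' trapezoidal rule. That area equals the Mann-Whitney statistic: the
#' probability that a random positive outscores a random negative, ties
#' counting half.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels aligned with `scores`.
#' @param class_label Optional tag stored on the curve (e.g. `"alpha"`).
#' @return A tibble of class `pf_roc` with columns `threshold`, `fpr`,
#'   `tpr` and attributes `auc` and `class_label`.
#' @examples
#' r <- compute_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' attr(r, "auc")  # 1
#' @export
compute_roc <- function(scores, labels, class_label = NA_character_) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L) {
    stop("labels must contain both classes (0 and 1)", call. = FALSE)
  }
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores into a single threshold step
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]
  fp <- cumsum(1 - l)[last]
  out <- tibble::tibble(threshold = c(Inf, s[last]),
                        fpr = c(0, fp / nn),
                        tpr = c(0, tp / np))
  auc <- sum(diff(out$fpr) * (utils::head(out$tpr, -1) + utils::tail(out$tpr, -1)) / 2)
  structure(out, auc = auc, class_label = class_label,
            class = c("pf_roc", class(out)))
}

#' Area under a ROC curve
#' @param roc A `pf_roc` object (or anything with an `auc` attribute).
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Per-class ROC curves for a multi-family test set
#'
#' For a binary pore-former scorer evaluated on a test set whose positives
#' carry family tags, computes one detection curve per positive family
#' (that family's records versus the negatives), a "negative" curve in
#' which the negative class is the detection target (scores inverted,
#' negatives versus all positives), and a macro-average curve (mean TPR
#' over the class curves on a fixed 101-point FPR grid).
#'
#' @param predictions A tibble with columns `score`, `label` (0/1) and
#'   `family` (NA for negatives), as returned by [predict.pf_cnn()].
#' @return A list of `pf_roc` objects named by class (families,
#'   `"negative"`, `"average"`). Classes with no records are omitted with
#'   a warning.
#' @export
per_class_roc <- function(predictions) {
  stopifnot(all(c("score", "label", "family") %in% names(predictions)))
  pos <- predictions$label == 1
  neg <- predictions$label == 0
  if (!any(pos) || !any(neg)) {
    stop("test set must contain both positives and negatives", call. = FALSE)
  }
  fams <- sort(unique(predictions$family[pos]))
  fams <- fams[!is.na(fams)]
  curves <- list()
  for (f in fams) {
    sel <- (pos & predictions$family == f) | neg
    curves[[f]] <- compute_roc(predictions$score[sel],
                               predictions$label[sel], class_label = f)
  }
  if (!length(curves)) warning("no family-tagged positives; family curves omitted")
  # negatives as the detection target: invert scores
  curves[["negative"]] <- compute_roc(1 - predictions$score,
                                      1 - predictions$label,
                                      class_label = "negative")
  grid <- seq(0, 1, length.out = 101L)
  mean_tpr <- rowMeans(vapply(curves, function(cv) {
    stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(101L)))
  avg <- tibble::tibble(threshold = NA_real_, fpr = grid, tpr = mean_tpr)
  auc <- sum(diff(grid) * (utils::head(mean_tpr, -1) + utils::tail(mean_tpr, -1)) / 2)
  curves[["average"]] <- structure(avg, auc = auc, class_label = "average",
                                   class = c("pf_roc", class(avg)))
  curves
}

#' Held-out family detection count
#'
#' Scores an entire protein family that was absent from training and
#' counts how many of its members are called pore formers at the decision
#' threshold. Refuses to run if any holdout id also appears in the
#' training data (a protocol violation), and can additionally screen the
#' holdout against the training positives by global identity.
#'
#' @param model A trained `pf_cnn`.
#' @param holdout A `pf_sequences` tibble (one family).
#' @param train_data The training sequence tibble, for the overlap guard.
#' @param threshold Decision threshold (default 0.5).
#' @param max_identity If non-`NULL`, also require every holdout sequence
#'   to be below this global identity to every training positive, else
#'   error.
#' @param ... Passed to [encode_sequences()] (e.g. `pad_length`).
#' @return A list: `detected`, `total`, `rate`, and `scores` (per-record
#'   tibble with `call` column).
#' @export
holdout_family_eval <- function(model, holdout, train_data, threshold = 0.5,
                                max_identity = NULL, ...) {
  holdout <- validate_sequences(holdout)
  overlap <- intersect(holdout$id, train_data$id)
  if (length(overlap)) {
    stop("holdout records also present in training data: ",
         paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(max_identity)) {
    tp <- train_data$sequence[train_data$label == "positive"]
    worst <- max_identity_to_set(holdout$sequence, tp)
    if (worst >= max_identity) {
      stop("holdout sequence within ", round(100 * max_identity),
           "% identity of a training positive (", round(100 * worst, 1),
           "%); protocol violation", call. = FALSE)
    }
  }
  tensors <- encode_sequences(holdout, scheme = model$scheme, ...)
  preds <- classify_scores(predict(model, tensors), threshold)
  list(detected = sum(preds$call), total = nrow(preds),
       rate = mean(preds$call), scores = preds)
}

#' Maximum pairwise identity between two sequence sets
#'
#' @param queries,subjects Character vectors of sequences.
#' @param config Alignment scoring, see [curation_config()].
#' @return The largest global identity over all query/subject pairs.
#' @export
max_identity_to_set <- function(queries, subjects,
                                config = curation_config()) {
  worst <- 0
  for (q in queries) {
    worst <- max(worst, max(identity_to_set(q, subjects, config)))
  }
  worst
}

#' Run the full evaluation benchmark
#'
#' For each trial: stratified 80:20 split, model training, test-set
#' accuracy and per-class ROC, and (optionally) held-out family scoring.
#' Aggregates metrics across trials.
#'
#' @param data A labelled `pf_sequences` tibble (positives family-tagged).
#' @param model_cfg A [model_config()].
#' @param scheme Encoding scheme.
#' @param pad_length Padded length for encoding.
#' @param holdout Optional holdout-family `pf_sequences` tibble.
#' @param train_fraction,n_trials,seed Split specification.
#' @param threshold Decision threshold for accuracy and holdout counts.
#' @param verbose Print progress.
#' @return An object of class `pf_eval`: list with `trials` (tibble of
#'   per-trial metrics), `history` (per-epoch metrics, all trials), `roc`
#'   (per-class curves of the last trial), `holdout` (per-trial detection
#'   tibble or NULL), and `models` (last trial's trained model).
#' @export
run_benchmark <- function(data, model_cfg = benchmark_model_config(),
                          scheme = "combined", pad_length = NULL,
                          holdout = NULL, train_fraction = 0.80,
                          n_trials = 1L, seed = 1L, threshold = 0.5,
                          verbose = FALSE) {
  data <- validate_sequences(data)
  if (is.null(pad_length)) {
    pad_length <- max(nchar(data$sequence),
                      if (!is.null(holdout)) nchar(holdout$sequence) else 0L)
  }
  trials <- vector("list", n_trials)
  hists <- vector("list", n_trials)
  hold <- vector("list", n_trials)
  roc_last <- NULL
  model_last <- NULL
  for (tr in seq_len(n_trials)) {
    sp <- split_dataset(data, train_fraction, seed = seed, trial = tr)
    tens_train <- encode_sequences(sp$train, scheme, pad_length)
    tens_test <- encode_sequences(sp$test, scheme, pad_length)
    cfg <- model_cfg
    cfg$seed <- model_cfg$seed + 104729L * (tr - 1L)
    model <- build_model(cfg, input_shape = c(pad_length,
                                              scheme_channels(scheme)))
    model <- train_model(model, tens_train, tens_test, verbose = verbose)
    preds <- predict(model, tens_test)
    acc <- mean((preds$score >= threshold) == preds$label)
    roc_all <- compute_roc(preds$score, preds$label, "all")
    roc_last <- per_class_roc(preds)
    model_last <- model
    hists[[tr]] <- dplyr::mutate(model$history, trial = tr)
    if (!is.null(holdout)) {
      hv <- holdout_family_eval(model, holdout, sp$train, threshold,
                                pad_length = pad_length)
      hold[[tr]] <- tibble::tibble(trial = tr,
                                   family = unique(holdout$family)[1L],
                                   detected = hv$detected, total = hv$total,
                                   rate = hv$rate)
    }
    trials[[tr]] <- tibble::tibble(trial = tr, test_accuracy = acc,
                                   test_auc = roc_auc(roc_all))
  }
  structure(list(trials = dplyr::bind_rows(trials),
                 history = dplyr::bind_rows(hists),
                 roc = roc_last,
                 holdout = if (is.null(holdout)) NULL else dplyr::bind_rows(hold),
                 model = model_last,
                 scheme = scheme, threshold = threshold, seed = seed),
            class = "pf_eval")
}

#' @export
print.pf_eval <- function(x, ...) {
  cat("<pf_eval> ", nrow(x$trials), " trial(s), scheme '", x$scheme, "'\n",
      sep = "")
  cat("  mean test accuracy: ", round(mean(x$trials$test_accuracy), 3),
      "; mean test AUC: ", round(mean(x$trials$test_auc), 3), "\n", sep = "")
  if (!is.null(x$holdout)) {
    cat("  holdout detection: ", sum(x$holdout$detected), "/",
        sum(x$holdout$total), "\n", sep = "")
  }
  invisible(x)
}
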