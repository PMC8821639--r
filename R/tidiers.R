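#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained classifier's training history
#'
#' @param x A trained `pf_cnn`.
#' @param ... Unused.
#' @return A long tibble: `epoch`, `set` (train/validation), `metric`
#'   (accuracy/loss), `value`.
#' @method tidy pf_cnn
#' @export
tidy.pf_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history", call. = FALSE)
  x$history |>
    tidyr::pivot_longer(-"epoch", names_to = "key", values_to = "value") |>
    tidyr::separate_wider_delim("key", "_", names = c("set", "metric")) |>
    dplyr::mutate(set = dplyr::recode(.data$set, val = "validation"))
}

#' One-row summary of a trained classifier
#' @param x A trained `pf_cnn`.
#' @param ... Unused.
#' @method glance pf_cnn
#' @export
glance.pf_cnn <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_parameters = x$n_parameters,
    epochs = x$config$epochs,
    scheme = x$scheme %||% NA_character_,
    train_loss = if (is.null(h)) NA_real_ else utils::tail(h$train_loss, 1),
    train_accuracy = if (is.null(h)) NA_real_ else utils::tail(h$train_accuracy, 1),
    val_loss = if (is.null(h)) NA_real_ else utils::tail(h$val_loss, 1),
    val_accuracy = if (is.null(h)) NA_real_ else utils::tail(h$val_accuracy, 1)
  )
}

#' Tidy a set of per-class ROC curves
#'
#' @param x A list of `pf_roc` curves (from [per_class_roc()]) or a
#'   single `pf_roc`.
#' @param ... Unused.
#' @return A tibble with `class`, `fpr`, `tpr`, `threshold`.
#' @method tidy pf_roc
#' @export
tidy.pf_roc <- function(x, ...) {
  tibble::tibble(class = attr(x, "class_label"), fpr = x$fpr, tpr = x$tpr,
                 threshold = x$threshold)
}

#' @rdname tidy.pf_roc
#' @export
tidy_roc_set <- function(x) {
  dplyr::bind_rows(lapply(x, tidy))
}

#' @rdname tidy.pf_roc
#' @method glance pf_roc
#' @export
glance.pf_roc <- function(x, ...) {
  tibble::tibble(class = attr(x, "class_label"), auc = roc_auc(x),
                 n_points = nrow(x))
}

#' Per-trial summary of an evaluation report
#' @param x A `pf_eval` from [run_benchmark()].
#' @param ... Unused.
#' @method tidy pf_eval
#' @export
tidy.pf_eval <- function(x, ...) x$trials

#' @rdname tidy.pf_eval
#' @method glance pf_eval
#' @export
glance.pf_eval <- function(x, ...) {
  tibble::tibble(
    n_trials = nrow(x$trials),
    mean_test_accuracy = mean(x$trials$test_accuracy),
    mean_test_auc = mean(x$trials$test_auc),
    holdout_rate = if (is.null(x$holdout)) NA_real_ else
      sum(x$holdout$detected) / sum(x$holdout$total)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
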