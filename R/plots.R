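#' Plot training history
#'
#' Accuracy and loss per epoch on the training and validation sets, one
#' panel per metric.
#'
#' @param object A trained `pf_cnn`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pf_cnn
#' @export
autoplot.pf_cnn <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot ROC curves
#'
#' @param object A list of `pf_roc` curves (from [per_class_roc()]).
#' @param ... Unused.
#' @return A ggplot with one curve per class, AUC in the legend.
#' @export
plot_roc <- function(object, ...) {
  if (inherits(object, "pf_roc")) object <- list(object)
  d <- tidy_roc_set(object)
  aucs <- dplyr::bind_rows(lapply(object, glance))
  d <- dplyr::left_join(d, aucs[, c("class", "auc")], by = "class")
  d$class <- sprintf("%s (AUC %.3f)", d$class, d$auc)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                  colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL, title = "ROC curves") +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @param object A `pf_eval` report.
#' @method autoplot pf_eval
#' @export
autoplot.pf_eval <- function(object, ...) {
  plot_roc(object$roc)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
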