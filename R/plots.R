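#' One-vs-rest ROC curves
#'
#' @param y_true True labels.
#' @param prob_matrix Samples x classes probability matrix with class-named
#'   columns.
#' @return A ggplot object: one ROC curve per class with AUC in the legend.
#' @export
plot_roc <- function(y_true, prob_matrix) {
  curves <- purrr::map_dfr(colnames(prob_matrix), function(cls) {
    pos <- as.character(y_true) == cls
    rc <- roc_points(prob_matrix[, cls], pos)
    dplyr::mutate(rc$points,
                  class = sprintf("%s (AUC %.2f)", cls, rc$auc))
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL, title = "One-vs-rest ROC") +
    ggplot2::theme_minimal()
}

#' One-vs-rest precision-recall curves
#'
#' Dashed horizontal lines mark the prevalence baseline of each class.
#'
#' @inheritParams plot_roc
#' @return A ggplot object.
#' @export
plot_pr <- function(y_true, prob_matrix) {
  parts <- lapply(colnames(prob_matrix), function(cls) {
    pos <- as.character(y_true) == cls
    pr <- pr_points(prob_matrix[, cls], pos)
    label <- sprintf("%s (AP %.2f)", cls, pr$average_precision)
    list(points = dplyr::mutate(pr$points, class = label),
         baseline = tibble::tibble(class = label, baseline = pr$baseline))
  })
  curves <- dplyr::bind_rows(lapply(parts, `[[`, "points"))
  baselines <- dplyr::bind_rows(lapply(parts, `[[`, "baseline"))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$recall, y = .data$precision,
                                       colour = .data$class)) +
    ggplot2::geom_step(linewidth = 0.7, direction = "vh") +
    ggplot2::geom_hline(data = baselines,
                        ggplot2::aes(yintercept = .data$baseline,
                                     colour = .data$class),
                        linetype = "dashed", alpha = 0.5) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = NULL,
                  title = "Precision-recall") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(x, ...) {
  df <- tibble::as_tibble(as.table(x$confusion), .name_repair = "minimal")
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(x$confusion))) +
    ggplot2::labs(x = "Predicted class", y = "True class",
                  title = sprintf("Confusion matrix (accuracy %.2f)", x$accuracy)) +
    ggplot2::theme_minimal()
}

#' Training-history curves
#'
#' @param x A `mutsubtype_fit`.
#' @param ... Unused.
#' @return A ggplot object: train/validation loss per epoch, best epoch
#'   marked.
#' @export
autoplot.mutsubtype_fit <- function(x, ...) {
  df <- x$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss"), names_to = "series",
                        values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = x$best_epoch, linetype = "dotted") +
    ggplot2::labs(x = "Epoch", y = "Cross-entropy loss", colour = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
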