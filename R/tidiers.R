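#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted classifier
#'
#' Returns the per-epoch training history (one row per epoch).
#'
#' @param x A `mutsubtype_fit`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `train_loss`, `val_loss`, `lr`.
#' @export
tidy.mutsubtype_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted classifier
#'
#' @param x A `mutsubtype_fit`.
#' @param ... Unused.
#' @return A one-row tibble: branches, dimensions, epochs trained,
#'   best epoch and its validation loss, early-stop flag.
#' @export
glance.mutsubtype_fit <- function(x, ...) {
  tibble::tibble(
    branches = paste(x$model_config$branches, collapse = "+"),
    n_features = x$model_config$n_features,
    n_classes = x$model_config$n_classes,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = min(x$history$val_loss),
    stopped_early = x$stopped_early
  )
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The per-class metric tibble (sensitivity, specificity, precision,
#'   F1, OvR AUC, average precision, degeneracy flag).
#' @export
tidy.evaluation_report <- function(x, ...) {
  x$per_class
}

#' One-row summary of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A one-row tibble: accuracy, macro precision/recall/F1, macro OvR
#'   AUC, n.
#' @export
glance.evaluation_report <- function(x, ...) {
  dplyr::bind_cols(glance_report(x), tibble::tibble(n = x$n))
}

#' Tidy a bootstrap result
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return The per-metric summary tibble (mean, ci_low, ci_high, n_missing).
#' @export
tidy.bootstrap_result <- function(x, ...) {
  x$summary
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-fold metric tibble.
#' @export
tidy.cv_result <- function(x, ...) {
  x$per_fold
}

#' One-row-per-metric summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The mean/sd-across-folds tibble.
#' @export
glance.cv_result <- function(x, ...) {
  x$summary
}
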