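#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in `class_names` order.
#'
#' @param y_true,y_pred Label vectors of equal length; every label must be in
#'   `class_names`.
#' @param class_names Ordered class names; defaults to the sorted union of
#'   observed labels.
#' @return Integer C x C matrix with dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred,
                             class_names = sort(unique(c(as.character(y_true),
                                                         as.character(y_pred))))) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have the same length.",
          class = "mutsubtype_shape_error")
  }
  unknown <- setdiff(unique(c(y_true, y_pred)), class_names)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown label(s): %s", paste(unknown, collapse = ", ")),
          class = "mutsubtype_domain_error")
  }
  tab <- table(factor(y_true, levels = class_names),
               factor(y_pred, levels = class_names))
  cm <- matrix(as.integer(tab), nrow = length(class_names),
               dimnames = list(true = class_names, predicted = class_names))
  cm
}

#' Per-class and macro metrics from a confusion matrix
#'
#' One-vs-rest reduction per class: sensitivity (recall) TP/(TP+FN),
#' specificity TN/(TN+FP), precision TP/(TP+FP), and F1. Zero-denominator
#' cases are defined as 0 and flagged in the `degenerate` column so
#' macro-averages stay defined on small folds. Accuracy is trace/total;
#' macro values are unweighted class means (specificity is reported per
#' class but, following the conventional metric set, not macro-aggregated).
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @return A list with `per_class` tibble (class, sensitivity, specificity,
#'   precision, f1, degenerate), `accuracy`, and `macro` tibble (precision,
#'   recall, f1).
#' @export
per_class_metrics <- function(cm) {
  total <- sum(cm)
  if (total < 1) abort("Confusion matrix is empty.", class = "mutsubtype_parameter_error")
  classes <- rownames(cm)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * prec * sens, prec + sens)
  per_class <- tibble::tibble(
    class = classes, sensitivity = unname(sens), specificity = unname(spec),
    precision = unname(prec), f1 = unname(f1),
    degenerate = unname((tp + fn) == 0 | (tp + fp) == 0)
  )
  list(
    per_class = per_class,
    accuracy = sum(tp) / total,
    macro = tibble::tibble(precision = mean(prec), recall = mean(sens),
                           f1 = mean(f1))
  )
}

#' ROC curve points and AUC
#'
#' Sweeps thresholds over the unique scores in descending order (ties
#' grouped) and returns (FPR, TPR) points with the trapezoidal AUC, which
#' equals the normalized Mann-Whitney U statistic (ties counted 1/2).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positives Binary vector (1/TRUE = positive) aligned to `scores`.
#' @return A list: `points` tibble (threshold, fpr, tpr) including the (0,0)
#'   anchor, and `auc`.
#' @export
roc_points <- function(scores, positives) {
  positives <- as.integer(as.logical(positives))
  if (length(scores) != length(positives)) {
    abort("`scores` and `positives` must have the same length.",
          class = "mutsubtype_shape_error")
  }
  n_pos <- sum(positives)
  n_neg <- length(positives) - n_pos
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC requires at least one positive and one negative.",
          class = "mutsubtype_undefined_metric_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positives[ord]
  grp_last <- cumsum(rle(s)$lengths)     # last index of each tied group
  tp <- cumsum(p)[grp_last]
  fp <- (seq_along(p) - cumsum(p))[grp_last]
  pts <- tibble::tibble(
    threshold = c(Inf, s[grp_last]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

#' Precision-recall curve points and average precision
#'
#' Average precision is the step-wise sum `sum_n (R_n - R_{n-1}) P_n` over
#' descending score thresholds (ties grouped). The prevalence baseline is
#' reported alongside.
#'
#' @inheritParams roc_points
#' @return A list: `points` tibble (threshold, recall, precision),
#'   `average_precision`, `baseline` (positive prevalence).
#' @export
pr_points <- function(scores, positives) {
  positives <- as.integer(as.logical(positives))
  if (length(scores) != length(positives)) {
    abort("`scores` and `positives` must have the same length.",
          class = "mutsubtype_shape_error")
  }
  n_pos <- sum(positives)
  if (n_pos == 0) {
    abort("PR requires at least one positive.",
          class = "mutsubtype_undefined_metric_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positives[ord]
  grp_last <- cumsum(rle(s)$lengths)
  tp <- cumsum(p)[grp_last]
  npred <- grp_last
  recall <- tp / n_pos
  precision <- tp / npred
  ap <- sum(diff(c(0, recall)) * precision)
  list(
    points = tibble::tibble(threshold = s[grp_last], recall = recall,
                            precision = precision),
    average_precision = ap,
    baseline = n_pos / length(positives)
  )
}

#' One-vs-one AUC for a class pair
#'
#' Restricts to samples of the two classes; by default the score for the
#' first class is its probability renormalized over the pair. Reversing the
#' pair flips both the score and the positive class, so the AUC is invariant
#' to the pair order (it measures the pairwise separability).
#'
#' @param prob_matrix Samples x classes probability matrix with class-named
#'   columns.
#' @param y_true True labels.
#' @param pair Character vector of two class names (first = positive).
#' @param renormalize If `FALSE`, use the raw first-class probability as the
#'   score.
#' @return AUC scalar.
#' @export
ovo_auc <- function(prob_matrix, y_true, pair, renormalize = TRUE) {
  y_true <- as.character(y_true)
  keep <- y_true %in% pair
  if (!all(pair %in% y_true)) {
    abort("Both classes of `pair` must be present in `y_true`.",
          class = "mutsubtype_undefined_metric_error")
  }
  sub <- prob_matrix[keep, pair, drop = FALSE]
  scores <- if (renormalize) {
    sub[, 1] / pmax(rowSums(sub), 1e-15)
  } else {
    sub[, 1]
  }
  roc_points(scores, y_true[keep] == pair[1])$auc
}

#' Full evaluation report from probabilities
#'
#' Hard predictions are the row-wise argmax. The report carries per-class
#' metrics, accuracy, macro averages, one-vs-rest AUC and average precision
#' per class, all six one-vs-one AUCs, and the macro OvR AUC (unweighted
#' mean of the per-class OvR AUCs).
#'
#' @param y_true True labels.
#' @param prob_matrix Samples x classes probability matrix; column names are
#'   the class names.
#' @return An `evaluation_report` list.
#' @export
evaluate_predictions <- function(y_true, prob_matrix) {
  class_names <- colnames(prob_matrix)
  if (is.null(class_names)) {
    abort("`prob_matrix` must have class-named columns.",
          class = "mutsubtype_shape_error")
  }
  y_true <- factor(as.character(y_true), levels = class_names)
  y_pred <- factor(class_names[max.col(prob_matrix, ties.method = "first")],
                   levels = class_names)
  cm <- confusion_matrix(y_true, y_pred, class_names)
  base <- per_class_metrics(cm)

  auc_ovr <- vapply(class_names, function(cls) {
    pos <- y_true == cls
    if (!any(pos) || all(pos)) return(NA_real_)
    roc_points(prob_matrix[, cls], pos)$auc
  }, numeric(1))
  ap <- vapply(class_names, function(cls) {
    pos <- y_true == cls
    if (!any(pos)) return(NA_real_)
    pr_points(prob_matrix[, cls], pos)$average_precision
  }, numeric(1))
  pairs <- utils::combn(class_names, 2, simplify = FALSE)
  present <- class_names[class_names %in% y_true]
  auc_ovo <- purrr::map_dfr(pairs, function(pr) {
    val <- if (all(pr %in% present)) ovo_auc(prob_matrix, y_true, pr) else NA_real_
    tibble::tibble(class_a = pr[1], class_b = pr[2], auc = val)
  })

  structure(
    list(
      confusion = cm,
      per_class = dplyr::mutate(base$per_class,
                                auc_ovr = unname(auc_ovr),
                                average_precision = unname(ap)),
      accuracy = base$accuracy,
      macro = dplyr::mutate(base$macro,
                            auc_ovr = mean(auc_ovr, na.rm = TRUE)),
      auc_ovo = auc_ovo,
      n = length(y_true)
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d samples: accuracy %.3f, macro-F1 %.3f, macro OvR AUC %.3f\n",
              x$n, x$accuracy, x$macro$f1, x$macro$auc_ovr))
  print(x$per_class)
  invisible(x)
}

# one-row tibble of the headline metrics of a report
glance_report <- function(report) {
  tibble::tibble(
    accuracy = report$accuracy,
    macro_precision = report$macro$precision,
    macro_recall = report$macro$recall,
    macro_f1 = report$macro$f1,
    macro_auc_ovr = report$macro$auc_ovr
  )
}

#' Percentile bootstrap confidence intervals on test-set metrics
#'
#' Resamples the evaluated samples with replacement `B` times (the model is
#' fixed; only the index set is resampled), recomputing accuracy, macro
#' precision/recall/F1 and macro OvR AUC per replicate. Replicates where a
#' metric is undefined (a class missing from the resample) are recorded as
#' missing and excluded, with the count reported. Intervals are the 2.5th
#' and 97.5th percentiles (linear-interpolation empirical quantiles).
#'
#' @param y_true True labels.
#' @param prob_matrix Fixed samples x classes probability matrix.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; resampling is bit-reproducible.
#' @param conf_level Confidence level, default 0.95.
#' @return A `bootstrap_result` list: `replicates` tibble (B rows),
#'   `summary` tibble (metric, mean, ci_low, ci_high, n_missing), `B`,
#'   `seed`.
#' @export
bootstrap_ci <- function(y_true, prob_matrix, B = 1000, seed = 1L,
                         conf_level = 0.95) {
  if (B < 1) abort("`B` must be >= 1.", class = "mutsubtype_parameter_error")
  y_true <- as.character(y_true)
  n <- length(y_true)
  class_names <- colnames(prob_matrix)
  y_pred <- class_names[max.col(prob_matrix, ties.method = "first")]

  one_rep <- function(idx) {
    yt <- y_true[idx]
    cm <- confusion_matrix(yt, y_pred[idx], class_names)
    base <- per_class_metrics(cm)
    aucs <- vapply(class_names, function(cls) {
      pos <- yt == cls
      if (!any(pos) || all(pos)) return(NA_real_)
      roc_points(prob_matrix[idx, cls], pos)$auc
    }, numeric(1))
    macro_auc <- if (anyNA(aucs)) NA_real_ else mean(aucs)
    tibble::tibble(
      accuracy = base$accuracy,
      macro_precision = base$macro$precision,
      macro_recall = base$macro$recall,
      macro_f1 = base$macro$f1,
      macro_auc_ovr = macro_auc
    )
  }

  reps <- with_seed(substream_seed(seed, "bootstrap"), {
    dplyr::bind_rows(lapply(seq_len(B), function(b) {
      one_rep(sample.int(n, n, replace = TRUE))
    }))
  })
  alpha <- (1 - conf_level) / 2
  summary <- reps |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      ci_low = quantile(.data$value, alpha, na.rm = TRUE, names = FALSE),
      ci_high = quantile(.data$value, 1 - alpha, na.rm = TRUE, names = FALSE),
      n_missing = sum(is.na(.data$value)),
      .groups = "drop"
    )
  structure(
    list(replicates = reps, summary = summary, B = as.integer(B),
         seed = as.integer(seed), conf_level = conf_level),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Percentile bootstrap, B = %d (seed %d)\n", x$B, x$seed))
  print(x$summary)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(
    list(
      n = report$n,
      accuracy = report$accuracy,
      macro = report$macro,
      per_class = report$per_class,
      auc_ovo = report$auc_ovo,
      confusion = list(classes = rownames(report$confusion),
                       counts = unname(apply(report$confusion, 1, as.list)))
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
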