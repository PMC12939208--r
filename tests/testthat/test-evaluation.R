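test_that("confusion matrix counts true/predicted pairs", {
  cm <- confusion_matrix(c("A", "B", "A"), c("A", "B", "A"), c("A", "B"))
  expect_equal(unname(diag(cm)), c(2L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)

  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2))

  withr::local_seed(1)
  yt <- sample(LETTERS[1:3], 40, replace = TRUE)
  yp <- sample(LETTERS[1:3], 40, replace = TRUE)
  cm <- confusion_matrix(yt, yp, LETTERS[1:3])
  expect_equal(unname(rowSums(cm)), unname(as.integer(table(factor(yt, levels = LETTERS[1:3])))))
  expect_equal(sum(cm), 40L)
  expect_error(confusion_matrix("A", "Z", c("A", "B")),
               class = "mutsubtype_domain_error")
})

test_that("per-class metrics follow the one-vs-rest formulas", {
  cm <- confusion_matrix(c("A", "B"), c("A", "B"), c("A", "B"))
  m <- per_class_metrics(cm)
  expect_true(all(m$per_class$sensitivity == 1, m$per_class$precision == 1,
                  m$per_class$f1 == 1))
  expect_equal(m$accuracy, 1)

  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  m <- per_class_metrics(cm)
  pc <- m$per_class
  expect_equal(pc$sensitivity[pc$class == "A"], 0.5)
  expect_equal(pc$precision[pc$class == "A"], 1.0)
  expect_equal(pc$f1[pc$class == "A"], 2 / 3)
  expect_equal(pc$sensitivity[pc$class == "B"], 1.0)
  expect_equal(pc$precision[pc$class == "B"], 0.5)
  expect_equal(pc$f1[pc$class == "B"], 2 / 3)
  expect_equal(m$accuracy, 2 / 3)
  expect_equal(pc$specificity[pc$class == "A"], 1.0)
  expect_equal(pc$specificity[pc$class == "B"], 0.5)
  expect_equal(m$macro$f1, 2 / 3)

  # class absent from truth and predictions: metrics 0, flagged
  cm3 <- confusion_matrix(c("A", "B"), c("A", "B"), c("A", "B", "C"))
  m3 <- per_class_metrics(cm3)
  expect_equal(m3$per_class$precision[m3$per_class$class == "C"], 0)
  expect_true(m3$per_class$degenerate[m3$per_class$class == "C"])
})

test_that("ROC points and AUC agree with the concordance oracle", {
  perfect <- roc_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1.0)

  withr::local_seed(2)
  null_auc <- roc_points(runif(4000), rbinom(4000, 1, 0.3))$auc
  expect_equal(null_auc, 0.5, tolerance = 0.05)

  scores <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)
  pos <- c(1, 1, 0, 1, 0, 0)
  rp <- roc_points(scores, pos)
  expect_equal(rp$auc, auc_concordance_oracle(scores, pos), tolerance = 1e-12)

  # tie grouping and curve anchors
  expect_equal(rp$points$fpr[1], 0)
  expect_equal(rp$points$tpr[nrow(rp$points)], 1)
  expect_error(roc_points(c(0.1, 0.2), c(1, 1)),
               class = "mutsubtype_undefined_metric_error")

  withr::local_seed(3)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    p <- rbinom(n, 1, 0.5)
    if (sum(p) == 0 || sum(p) == n) next
    expect_equal(roc_points(s, p)$auc, auc_concordance_oracle(s, p),
                 tolerance = 1e-12)
  }
})

test_that("ROC AUC matches an established implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(4)
  s <- runif(60)
  p <- rbinom(60, 1, 0.4)
  ours <- roc_points(s, p)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(p, s, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("PR points and average precision follow the step-sum definition", {
  expect_equal(pr_points(c(0.9, 0.8, 0.2), c(1, 1, 0))$average_precision, 1.0)

  # uninformative constant scores: AP equals prevalence
  expect_equal(pr_points(rep(0.5, 10), c(rep(1, 3), rep(0, 7)))$average_precision,
               0.3)
  expect_equal(pr_points(rep(0.5, 10), c(rep(1, 3), rep(0, 7)))$baseline, 0.3)

  scores <- c(0.95, 0.8, 0.7, 0.6, 0.3, 0.2)
  pos <- c(1, 0, 1, 1, 0, 0)
  pr <- pr_points(scores, pos)
  expect_equal(pr$average_precision, ap_oracle(scores, pos), tolerance = 1e-12)
  expect_error(pr_points(c(0.2, 0.4), c(0, 0)),
               class = "mutsubtype_undefined_metric_error")
})

test_that("one-vs-one AUC restricts to the pair and is order-invariant", {
  probs <- matrix(c(0.8, 0.7, 0.2, 0.1,
                    0.1, 0.2, 0.7, 0.8,
                    0.1, 0.1, 0.1, 0.1), 4, 3,
                  dimnames = list(NULL, c("A", "B", "C")))
  y <- c("A", "A", "B", "B")
  expect_equal(ovo_auc(probs, y, c("A", "B")), 1.0)
  expect_equal(ovo_auc(probs, y, c("B", "A")), 1.0)

  # flipping the pair flips both the score and the positive class, so the
  # pairwise separability is unchanged
  withr::local_seed(5)
  probs <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  probs <- probs / rowSums(probs)
  y <- sample(c("A", "B", "C"), 20, replace = TRUE)
  a_b <- ovo_auc(probs, y, c("A", "B"))
  expect_equal(ovo_auc(probs, y, c("B", "A")), a_b, tolerance = 1e-12)
  # oracle on the renormalized pair scores
  keep <- y %in% c("A", "B")
  sc <- probs[keep, "A"] / (probs[keep, "A"] + probs[keep, "B"])
  expect_equal(a_b, auc_concordance_oracle(sc, as.integer(y[keep] == "A")),
               tolerance = 1e-12)
  expect_error(ovo_auc(probs, rep("A", 20), c("A", "B")),
               class = "mutsubtype_undefined_metric_error")
})

test_that("evaluation report macro values recompute from raw labels", {
  withr::local_seed(6)
  for (rep in 1:20) {
    n <- 60
    y <- sample(LETTERS[1:4], n, replace = TRUE)
    probs <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, LETTERS[1:4]))
    probs <- probs / rowSums(probs)
    rep_out <- evaluate_predictions(y, probs)
    y_pred <- LETTERS[1:4][max.col(probs, ties.method = "first")]
    # independent recomputation of macro-F1 from scratch
    f1s <- vapply(LETTERS[1:4], function(cls) {
      tp <- sum(y == cls & y_pred == cls)
      fp <- sum(y != cls & y_pred == cls)
      fn <- sum(y == cls & y_pred != cls)
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }, numeric(1))
    expect_equal(rep_out$macro$f1, mean(f1s), tolerance = 1e-12)
    expect_equal(rep_out$accuracy, mean(y == y_pred), tolerance = 1e-12)
    # macro OvR AUC is the unweighted mean of per-class AUCs
    expect_equal(rep_out$macro$auc_ovr,
                 mean(rep_out$per_class$auc_ovr, na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap CIs use percentile quantiles and are reproducible", {
  probs <- matrix(c(rep(c(0.9, 0.1), 5), rep(c(0.1, 0.9), 5)), 10, 2,
                  byrow = TRUE, dimnames = list(NULL, c("A", "B")))
  y <- rep(c("A", "B"), each = 5)
  bs <- bootstrap_ci(y, probs, B = 50, seed = 3)
  acc <- bs$summary[bs$summary$metric == "accuracy", ]
  expect_equal(acc$ci_low, 1.0)
  expect_equal(acc$ci_high, 1.0)

  b1 <- bootstrap_ci(y, probs, B = 1, seed = 4)
  acc1 <- b1$summary[b1$summary$metric == "accuracy", ]
  expect_equal(acc1$ci_low, acc1$ci_high)
  expect_equal(acc1$mean, b1$replicates$accuracy[1])

  expect_identical(bootstrap_ci(y, probs, B = 25, seed = 5)$replicates,
                   bootstrap_ci(y, probs, B = 25, seed = 5)$replicates)

  # percentile convention: linear interpolation at h = (n-1)p + 1
  v <- c(10, 20, 30, 40, 50)
  expect_equal(quantile(v, 0.025, names = FALSE), 11)  # h = 1.1
  expect_equal(quantile(v, 0.975, names = FALSE), 49)  # h = 4.9
})

test_that("tidiers and plots expose report internals", {
  withr::local_seed(7)
  y <- sample(c("A", "B"), 30, replace = TRUE)
  probs <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("A", "B")))
  probs <- probs / rowSums(probs)
  rep_out <- evaluate_predictions(y, probs)
  expect_s3_class(tidy(rep_out), "tbl_df")
  expect_equal(nrow(glance(rep_out)), 1)
  expect_s3_class(autoplot(rep_out), "ggplot")
  expect_s3_class(plot_roc(y, probs), "ggplot")
  expect_s3_class(plot_pr(y, probs), "ggplot")
})
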