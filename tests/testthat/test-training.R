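test_that("inverse-frequency weights rebalance sampling", {
  w <- inverse_frequency_weights(c("A", "A", "A", "B"))
  expect_equal(w, c(1 / 3, 1 / 3, 1 / 3, 1))
  expect_equal(inverse_frequency_weights(rep(c("A", "B"), 5)), rep(1 / 5, 10))
  expect_error(inverse_frequency_weights(character(0)),
               class = "mutsubtype_parameter_error")

  # empirical class frequencies of 1e5 weighted draws are uniform (3 SE)
  withr::local_seed(21)
  labels <- rep(c("A", "B", "C"), times = c(600, 300, 100))
  w <- inverse_frequency_weights(labels)
  draws <- sample(labels, 1e5, replace = TRUE, prob = w)
  freq <- table(draws) / 1e5
  se <- sqrt((1 / 3) * (2 / 3) / 1e5)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("stratified folds partition the data with balanced class counts", {
  fold <- make_stratified_folds(rep(c("A", "B"), each = 5), k = 5, seed = 1)
  for (f in 1:5) {
    expect_equal(sum(fold == f & rep(c("A", "B"), each = 5) == "A"), 1)
    expect_equal(sum(fold == f & rep(c("A", "B"), each = 5) == "B"), 1)
  }

  lab <- c(rep("A", 4), rep("B", 2))
  fold <- make_stratified_folds(lab, k = 2, seed = 2)
  for (f in 1:2) {
    expect_equal(sum(fold == f & lab == "A"), 2)
    expect_equal(sum(fold == f & lab == "B"), 1)
  }

  withr::local_seed(3)
  lab <- sample(c("A", "B", "C"), 83, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  for (k in c(3, 5)) {
    fold <- make_stratified_folds(lab, k = k, seed = 4)
    expect_setequal(unique(fold), seq_len(k))
    expect_equal(length(fold), 83)        # partition: every index exactly once
    for (cls in unique(lab)) {
      counts <- table(factor(fold[lab == cls], levels = seq_len(k)))
      expect_lte(diff(range(counts)), 1)  # within one sample of proportional
    }
  }
  expect_identical(make_stratified_folds(lab, 5, seed = 9),
                   make_stratified_folds(lab, 5, seed = 9))
  expect_error(make_stratified_folds(c("A", "B"), k = 3),
               class = "mutsubtype_parameter_error")
})

test_that("training solves a linearly separable problem with the wide branch", {
  withr::local_seed(31)
  n <- 120
  X <- cbind(f1 = rbinom(n, 1, 0.5), f2 = rbinom(n, 1, 0.5))
  y <- factor(ifelse(X[, "f1"] == 1, "pos", "neg"))
  fit <- fit_classifier(X, y,
                        train_config(seed = 5, max_epochs = 300),
                        model_config(n_features = 2, n_classes = 2,
                                     branches = "wide"))
  expect_equal(mean(predict(fit, X) == y), 1.0)
})

test_that("training history, early stopping and determinism behave", {
  withr::local_seed(32)
  n <- 80
  X <- matrix(rbinom(n * 5, 1, 0.4), n, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  y <- factor(sample(c("A", "B"), n, replace = TRUE))

  fit1 <- fit_classifier(X, y, train_config(seed = 6, max_epochs = 1))
  expect_equal(nrow(fit1$history), 1)
  expect_false(fit1$stopped_early)

  cfg <- train_config(seed = 7, max_epochs = 80)
  fit_a <- fit_classifier(X, y, cfg)
  fit_b <- fit_classifier(X, y, cfg)
  expect_identical(fit_a$history, fit_b$history)
  expect_identical(fit_a$params, fit_b$params)

  # the retained parameters correspond to the minimal validation loss
  best <- fit_a$history$val_loss[fit_a$best_epoch]
  later <- fit_a$history$val_loss[fit_a$history$epoch > fit_a$best_epoch]
  if (length(later) > 0) {
    expect_true(all(best <= later + cfg$early_stop_min_delta))
  }

  expect_error(fit_classifier(X, factor(rep("A", n))),
               class = "mutsubtype_parameter_error")
})

test_that("cross-validation scores every sample exactly once and aggregates", {
  cohort <- generate_cohort(small_planted_config(seed = 41, n_samples = 300))
  fs <- select_pathway_representatives(cohort$matrix, cohort$labels,
                                       cohort$pathways, 0.005)
  X <- cohort$matrix[, fs$gene]
  cv <- cross_validate(X, cohort$labels, k = 5, fast_train_config(seed = 8))
  expect_length(cv$fold_reports, 5)
  expect_equal(sort(unique(cv$fold_of_sample)), 1:5)
  expect_equal(sum(vapply(cv$fold_reports, `[[`, numeric(1), "n")),
               nrow(X))
  # aggregate mean equals the arithmetic mean of the per-fold values
  acc_mean <- cv$summary$mean[cv$summary$metric == "accuracy"]
  expect_equal(acc_mean, mean(cv$per_fold$accuracy), tolerance = 1e-12)
  # strong planted signal is recovered
  expect_gte(acc_mean, 0.8)
})

test_that("feature selection sees only training-partition rows", {
  cohort <- generate_cohort(small_planted_config(seed = 51, n_samples = 300))
  seed <- 13
  train_mask <- train_test_split(cohort$labels, 0.7, seed)

  # poison a background gene so it perfectly encodes the label on TEST rows
  poisoned <- cohort$matrix
  target_gene <- setdiff(colnames(poisoned), cohort$truth$gene)[2]
  poisoned[!train_mask, target_gene] <-
    as.integer(cohort$labels[!train_mask] == levels(cohort$labels)[1])

  res_clean <- run_pipeline(cohort$matrix, cohort$labels, cohort$pathways,
                            seed = seed, config = fast_train_config(seed))
  res_poison <- run_pipeline(poisoned, cohort$labels, cohort$pathways,
                             seed = seed, config = fast_train_config(seed))
  # identical selections: the test-partition poison was never consulted
  expect_identical(res_clean$features$gene, res_poison$features$gene)

  # and the selection equals an explicit training-only recomputation
  manual <- select_pathway_representatives(
    cohort$matrix[train_mask, , drop = FALSE],
    cohort$labels[train_mask], cohort$pathways, 0.005
  )
  expect_identical(res_clean$features$gene, manual$gene)
})

test_that("run_pipeline reports generalization on the held-out split", {
  cohort <- generate_cohort(small_planted_config(seed = 61))
  res <- run_pipeline(cohort$matrix, cohort$labels, cohort$pathways, seed = 17,
                      config = fast_train_config(17))
  expect_s3_class(res$report, "evaluation_report")
  expect_equal(res$report$n, sum(!res$split))
  expect_gte(res$report$accuracy, 0.8)  # strong signal generalizes
})
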