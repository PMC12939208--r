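#' Stratified train/test split
#'
#' @param labels Categorical vector.
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` = training sample.
#' @export
train_test_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  !stratified_holdout(as.character(labels), 1 - train_fraction,
                      substream_seed(seed, "split"))
}

#' End-to-end pipeline on a prepared matrix
#'
#' Splits the cohort 70/30 (stratified), selects pathway representatives on
#' the training partition only, trains the classifier on the selected
#' features, and evaluates on the held-out test set.
#'
#' @param matrix Binary samples x genes matrix.
#' @param labels Labels aligned to the matrix rows.
#' @param pathways Named list of gene sets.
#' @param threshold Recurrence threshold for feature selection.
#' @param train_fraction Training fraction of the stratified split.
#' @param seed Master seed (fans out to split/selection/training streams).
#' @param config A [train_config()] (its seed is overridden from `seed`).
#' @param model_cfg Optional [model_config()] template; `n_features` and
#'   `n_classes` are set from the data. Its `branches`/`fm_mode` choices are
#'   honored (used by ablation).
#' @return A `pipeline_result` list: `fit`, `features` (feature set),
#'   `report` ([evaluate_predictions()] on the test set), `split` (logical
#'   training mask), `seed`.
#' @export
run_pipeline <- function(matrix, labels, pathways, threshold = 0.005,
                         train_fraction = 0.7, seed = 1L,
                         config = train_config(), model_cfg = NULL) {
  labels <- droplevels(as.factor(labels))
  train_mask <- train_test_split(labels, train_fraction, seed)
  features <- select_pathway_representatives(
    matrix[train_mask, , drop = FALSE], labels[train_mask], pathways, threshold
  )
  if (nrow(features) == 0) {
    abort("Feature selection produced an empty set; cannot train.",
          class = "mutsubtype_parameter_error")
  }
  X <- matrix[, features$gene, drop = FALSE]
  cfg <- config
  cfg$seed <- substream_seed(seed, "train")
  mc <- if (is.null(model_cfg)) {
    model_config(n_features = nrow(features), n_classes = nlevels(labels))
  } else {
    model_config(n_features = nrow(features), n_classes = nlevels(labels),
                 embedding_dim = model_cfg$embedding_dim,
                 hidden_sizes = model_cfg$hidden_sizes,
                 dropout_rate = model_cfg$dropout_rate,
                 fm_mode = model_cfg$fm_mode, branches = model_cfg$branches)
  }
  fit <- fit_classifier(X[train_mask, , drop = FALSE], labels[train_mask],
                        cfg, mc)
  probs <- predict(fit, X[!train_mask, , drop = FALSE], type = "prob")
  report <- evaluate_predictions(labels[!train_mask], probs)
  structure(
    list(fit = fit, features = features, report = report, split = train_mask,
         seed = seed),
    class = "pipeline_result"
  )
}

#' Branch-ablation comparison
#'
#' Runs the pipeline with branch subsets `{wide}`, `{fm}`, `{deep}`,
#' `{wide, deep}` and `{wide, fm, deep}` on identical splits, selections and
#' seeds, and tabulates test-set metrics per variant.
#'
#' @inheritParams run_pipeline
#' @param variants List of branch subsets to compare.
#' @return A list: `table` (tibble of variant metrics), `results` (named
#'   list of `pipeline_result`s).
#' @export
run_ablation <- function(matrix, labels, pathways, threshold = 0.005,
                         train_fraction = 0.7, seed = 1L,
                         config = train_config(),
                         variants = list("wide", "fm", "deep",
                                         c("wide", "deep"),
                                         c("wide", "fm", "deep"))) {
  results <- list()
  rows <- list()
  for (br in variants) {
    nm <- paste(br, collapse = "+")
    mc <- model_config(n_features = 1, n_classes = 2, branches = br)
    res <- run_pipeline(matrix, labels, pathways, threshold, train_fraction,
                        seed, config, model_cfg = mc)
    results[[nm]] <- res
    rows[[nm]] <- dplyr::bind_cols(tibble::tibble(variant = nm),
                                   glance_report(res$report))
  }
  list(table = dplyr::bind_rows(rows), results = results)
}

# ---- command-layer (thin compositions used by the CLI) --------------------

write_manifest <- function(out_dir, command, inputs, seed, extra = list()) {
  manifest <- c(
    list(command = command, inputs = inputs, seed = seed,
         package_version = as.character(utils::packageVersion("mutsubtype")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Pipeline commands
#'
#' Thin file-in/file-out compositions of the package's functions, used by
#' the `mutsubtype` command-line entry point (`inst/cli/mutsubtype`). Each
#' command writes its outputs plus a JSON manifest (inputs, seed, package
#' version) into `out_dir` and logs progress to `stderr`.
#'
#' @param maf,gmt,labels,matrix Paths to input files (MAF, GMT, a two-column
#'   `sample_id`/`label` TSV, a matrix TSV from `cmd_build_matrix`).
#' @param out_dir Output directory (created if missing).
#' @param capture_size_mb Capture size for TMB (Mb).
#' @param threshold Recurrence threshold.
#' @param train_fraction Training fraction.
#' @param seed Master seed.
#' @param B Bootstrap replicate count.
#' @param config_file Optional YAML/JSON file overriding [train_config()]
#'   fields.
#' @param preset_n_samples,preset_seed Synthetic preset controls.
#' @name pipeline-commands
NULL

msg <- function(...) message(sprintf(...))

read_labels_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stats::setNames(as.character(df[[2]]), df[[1]])
}

load_train_config <- function(config_file = NULL, seed = 1L) {
  overrides <- if (!is.null(config_file)) {
    if (grepl("\\.ya?ml$", config_file)) yaml::read_yaml(config_file)
    else jsonlite::fromJSON(config_file)
  } else {
    list()
  }
  overrides$seed <- substream_seed(seed, "train")
  do.call(train_config, overrides)
}

#' @rdname pipeline-commands
#' @export
cmd_build_matrix <- function(maf, out_dir, capture_size_mb = 50) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- read_maf(maf)
  msg("Read %d MAF records", nrow(tbl))
  kept <- filter_nonsynonymous(tbl)
  msg("Retained %d non-synonymous records", nrow(kept))
  if (nrow(kept) == 0) warn("No non-synonymous records; matrix is empty.")
  mat <- build_binary_matrix(kept)
  msg("Matrix: %d samples x %d genes", nrow(mat), ncol(mat))
  write_matrix_tsv(mat, file.path(out_dir, "matrix.tsv"))
  write_cohort_summary(summarize_cohort(kept, capture_size_mb),
                       file.path(out_dir, "cohort_summary.json"))
  write_manifest(out_dir, "build_matrix", list(maf = maf), NA,
                 list(capture_size_mb = capture_size_mb))
  invisible(mat)
}

#' @rdname pipeline-commands
#' @export
cmd_select <- function(matrix, gmt, labels, out_dir, threshold = 0.005,
                       train_fraction = 0.7, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat <- read_matrix_tsv(matrix)
  pathways <- read_gmt(gmt)
  lab <- read_labels_tsv(labels)
  if (!all(rownames(mat) %in% names(lab))) {
    abort("Labels file does not cover all matrix samples.",
          class = "mutsubtype_consistency_error")
  }
  y <- lab[rownames(mat)]
  train_mask <- train_test_split(y, train_fraction, seed)
  fs <- select_pathway_representatives(mat[train_mask, , drop = FALSE],
                                       y[train_mask], pathways, threshold)
  msg("Selected %d representative genes from %d pathways",
      nrow(fs), length(pathways))
  write_feature_set(fs, file.path(out_dir, "features.tsv"))
  # leakage audit trail: threshold, split seed and the exact training samples
  jsonlite::write_json(
    list(threshold = threshold, train_fraction = train_fraction, seed = seed,
         training_samples = rownames(mat)[train_mask]),
    file.path(out_dir, "selection_audit.json"), auto_unbox = TRUE, digits = NA
  )
  write_manifest(out_dir, "select",
                 list(matrix = matrix, gmt = gmt, labels = labels), seed,
                 list(threshold = threshold))
  invisible(fs)
}

#' @rdname pipeline-commands
#' @export
cmd_train <- function(matrix, gmt, labels, out_dir, threshold = 0.005,
                      train_fraction = 0.7, seed = 1L, config_file = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat <- read_matrix_tsv(matrix)
  pathways <- read_gmt(gmt)
  y <- read_labels_tsv(labels)[rownames(mat)]
  cfg <- load_train_config(config_file, seed)
  res <- run_pipeline(mat, y, pathways, threshold, train_fraction, seed, cfg)
  msg("Trained %d epochs; test accuracy %.3f, macro-F1 %.3f",
      nrow(res$fit$history), res$report$accuracy, res$report$macro$f1)
  save_checkpoint(res$fit$params, res$fit$model_config,
                  file.path(out_dir, "checkpoint.txt"))
  readr::write_tsv(res$fit$history, file.path(out_dir, "history.tsv"),
                   progress = FALSE)
  write_feature_set(res$features, file.path(out_dir, "features.tsv"))
  write_evaluation_report(res$report, file.path(out_dir, "test_report.json"))
  readr::write_tsv(
    tibble::tibble(sample_id = rownames(mat),
                   partition = ifelse(res$split, "train", "test")),
    file.path(out_dir, "split.tsv"), progress = FALSE
  )
  write_manifest(out_dir, "train",
                 list(matrix = matrix, gmt = gmt, labels = labels), seed,
                 list(threshold = threshold, train_fraction = train_fraction))
  invisible(res)
}

#' @rdname pipeline-commands
#' @param k Number of cross-validation folds.
#' @export
cmd_crossval <- function(matrix, gmt, labels, out_dir, threshold = 0.005,
                         k = 5, seed = 1L, config_file = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat <- read_matrix_tsv(matrix)
  pathways <- read_gmt(gmt)
  y <- droplevels(as.factor(read_labels_tsv(labels)[rownames(mat)]))
  cfg <- load_train_config(config_file, seed)
  fold <- make_stratified_folds(as.character(y), k = k, seed = cfg$seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    # selection confined to this fold's training partition
    fs <- select_pathway_representatives(mat[tr, , drop = FALSE], y[tr],
                                         pathways, threshold)
    X <- mat[, fs$gene, drop = FALSE]
    fold_cfg <- cfg
    fold_cfg$seed <- substream_seed(cfg$seed, paste0("fold", f))
    fit <- fit_classifier(X[tr, , drop = FALSE], y[tr], fold_cfg)
    probs <- predict(fit, X[!tr, , drop = FALSE], type = "prob")
    reports[[f]] <- evaluate_predictions(y[!tr], probs)
    msg("Fold %d: accuracy %.3f, macro-F1 %.3f", f,
        reports[[f]]$accuracy, reports[[f]]$macro$f1)
  }
  per_fold <- dplyr::bind_rows(lapply(seq_len(k), function(f) {
    dplyr::bind_cols(tibble::tibble(fold = f), glance_report(reports[[f]]))
  }))
  readr::write_tsv(per_fold, file.path(out_dir, "cv_metrics.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(sample_id = rownames(mat), fold = fold),
                   file.path(out_dir, "folds.tsv"), progress = FALSE)
  write_manifest(out_dir, "crossval",
                 list(matrix = matrix, gmt = gmt, labels = labels), seed,
                 list(threshold = threshold, k = k))
  invisible(list(per_fold = per_fold, reports = reports, fold = fold))
}

#' @rdname pipeline-commands
#' @param checkpoint Checkpoint file from `cmd_train`.
#' @param features Feature-set TSV from `cmd_train`/`cmd_select`.
#' @param split Split TSV from `cmd_train` (evaluates the `test` rows).
#' @export
cmd_evaluate <- function(matrix, checkpoint, features, labels, split, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat <- read_matrix_tsv(matrix)
  ck <- load_checkpoint(checkpoint)
  fs <- readr::read_tsv(features, show_col_types = FALSE, progress = FALSE)
  y <- read_labels_tsv(labels)[rownames(mat)]
  sp <- readr::read_tsv(split, show_col_types = FALSE, progress = FALSE)
  test_ids <- sp$sample_id[sp$partition == "test"]
  X <- mat[test_ids, fs$gene, drop = FALSE]
  pred <- forward(X, ck$params, ck$config, training_mode = FALSE)
  classes <- sort(unique(as.character(y)))
  probs <- pred$probabilities
  colnames(probs) <- classes
  report <- evaluate_predictions(y[test_ids], probs)
  msg("Test accuracy %.3f, macro-F1 %.3f", report$accuracy, report$macro$f1)
  write_evaluation_report(report, file.path(out_dir, "evaluation.json"))
  write_manifest(out_dir, "evaluate",
                 list(matrix = matrix, checkpoint = checkpoint), NA)
  invisible(report)
}

#' @rdname pipeline-commands
#' @export
cmd_bootstrap <- function(matrix, checkpoint, features, labels, split, out_dir,
                          B = 1000, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat <- read_matrix_tsv(matrix)
  ck <- load_checkpoint(checkpoint)
  fs <- readr::read_tsv(features, show_col_types = FALSE, progress = FALSE)
  y <- read_labels_tsv(labels)[rownames(mat)]
  sp <- readr::read_tsv(split, show_col_types = FALSE, progress = FALSE)
  test_ids <- sp$sample_id[sp$partition == "test"]
  X <- mat[test_ids, fs$gene, drop = FALSE]
  pred <- forward(X, ck$params, ck$config, training_mode = FALSE)
  probs <- pred$probabilities
  colnames(probs) <- sort(unique(as.character(y)))
  bs <- bootstrap_ci(y[test_ids], probs, B = B, seed = seed)
  jsonlite::write_json(
    list(B = bs$B, seed = bs$seed, summary = bs$summary,
         replicates = bs$replicates),
    file.path(out_dir, "bootstrap.json"), auto_unbox = TRUE, digits = NA
  )
  write_manifest(out_dir, "bootstrap",
                 list(matrix = matrix, checkpoint = checkpoint), seed,
                 list(B = B))
  invisible(bs)
}

#' @rdname pipeline-commands
#' @export
cmd_ablate <- function(matrix, gmt, labels, out_dir, threshold = 0.005,
                       train_fraction = 0.7, seed = 1L, config_file = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat <- read_matrix_tsv(matrix)
  pathways <- read_gmt(gmt)
  y <- read_labels_tsv(labels)[rownames(mat)]
  cfg <- load_train_config(config_file, seed)
  ab <- run_ablation(mat, y, pathways, threshold, train_fraction, seed, cfg)
  readr::write_tsv(ab$table, file.path(out_dir, "ablation.tsv"), progress = FALSE)
  write_manifest(out_dir, "ablate",
                 list(matrix = matrix, gmt = gmt, labels = labels), seed,
                 list(threshold = threshold))
  invisible(ab)
}

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(out_dir, preset_n_samples = 900, preset_seed = 1L,
                         silent_rate = 0.1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(tcga_like_config(seed = preset_seed,
                                             n_samples = preset_n_samples))
  write_fixture_maf(cohort, file.path(out_dir, "cohort.maf"),
                    silent_rate = silent_rate, seed = preset_seed)
  write_fixture_gmt(cohort, file.path(out_dir, "pathways.gmt"))
  readr::write_tsv(
    tibble::tibble(sample_id = rownames(cohort$matrix),
                   label = as.character(cohort$labels)),
    file.path(out_dir, "labels.tsv"), progress = FALSE
  )
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "simulate", list(), preset_seed,
                 list(n_samples = preset_n_samples))
  msg("Simulated cohort: %d samples x %d genes", nrow(cohort$matrix),
      ncol(cohort$matrix))
  invisible(cohort)
}

# ---- command-line dispatcher ----------------------------------------------

parse_cli_args <- function(args) {
  opts <- list()
  positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(command = positional[1], opts = opts)
}

#' Command-line entry point
#'
#' Dispatches the `mutsubtype` subcommands (`build-matrix`, `select`,
#' `train`, `crossval`, `evaluate`, `bootstrap`, `ablate`, `simulate`) onto
#' the `cmd_*` functions. Invoked by `inst/cli/mutsubtype`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mutsubtype <command> [--option value ...]",
    "commands: build-matrix select train crossval evaluate bootstrap ablate simulate",
    sep = "\n")
  parsed <- parse_cli_args(args)
  if (is.na(parsed$command) || length(parsed$command) == 0) {
    message(usage)
    return(invisible(1L))
  }
  o <- parsed$opts
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)
  int <- function(x, default) if (is.null(x)) default else as.integer(x)
  chr <- function(x, default = NULL) if (is.null(x)) default else x
  status <- tryCatch({
    switch(
      parsed$command,
      "build-matrix" = cmd_build_matrix(o$maf, chr(o$out, "."),
                                        num(o$capture_size_mb, 50)),
      "select" = cmd_select(o$matrix, o$gmt, o$labels, chr(o$out, "."),
                            num(o$threshold, 0.005),
                            num(o$train_fraction, 0.7), int(o$seed, 1L)),
      "train" = cmd_train(o$matrix, o$gmt, o$labels, chr(o$out, "."),
                          num(o$threshold, 0.005), num(o$train_fraction, 0.7),
                          int(o$seed, 1L), chr(o$config)),
      "crossval" = cmd_crossval(o$matrix, o$gmt, o$labels, chr(o$out, "."),
                                num(o$threshold, 0.005), int(o$k, 5L),
                                int(o$seed, 1L), chr(o$config)),
      "evaluate" = cmd_evaluate(o$matrix, o$checkpoint, o$features, o$labels,
                                o$split, chr(o$out, ".")),
      "bootstrap" = cmd_bootstrap(o$matrix, o$checkpoint, o$features,
                                  o$labels, o$split, chr(o$out, "."),
                                  int(o$B, 1000L), int(o$seed, 1L)),
      "ablate" = cmd_ablate(o$matrix, o$gmt, o$labels, chr(o$out, "."),
                            num(o$threshold, 0.005), num(o$train_fraction, 0.7),
                            int(o$seed, 1L), chr(o$config)),
      "simulate" = cmd_simulate(chr(o$out, "."), int(o$n_samples, 900L),
                                int(o$seed, 1L), num(o$silent_rate, 0.1)),
      {
        message(usage)
        return(invisible(1L))
      }
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
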