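#' Read a GMT gene-set collection
#'
#' Parses the standard MSigDB GMT dialect: one gene set per line, tab
#' separated, fields `name`, `description`, then one or more member genes.
#' The description is discarded and duplicate genes within a line collapsed.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (pathway name -> member genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GMT file not found: %s", path), class = "mutsubtype_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.", bad[1]),
          class = "mutsubtype_format_error")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) {
    abort("GMT file contains duplicate pathway names.",
          class = "mutsubtype_format_error")
  }
  sets
}

#' Write a pathway collection as GMT
#'
#' @param pathways Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], "na", unique(pathways[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter genes by mutation recurrence
#'
#' Retains genes mutated in at least `threshold` of samples (boundary
#' inclusive: genes *below* the threshold are removed), in matrix column
#' order.
#'
#' @param matrix Binary samples x genes matrix.
#' @param threshold Recurrence fraction in (0, 1). Default 0.005 (0.5%).
#' @return Character vector of retained gene symbols.
#' @export
recurrence_filter <- function(matrix, threshold = 0.005) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.",
          class = "mutsubtype_parameter_error")
  }
  if (length(matrix) == 0 || nrow(matrix) == 0) return(character(0))
  freq <- colMeans(matrix)
  colnames(matrix)[freq >= threshold]
}

#' Mutual information between a binary feature and a categorical label
#'
#' Plug-in (maximum-likelihood) estimate of
#' \eqn{I(X;Y) = \sum_y \sum_x p(x,y) \log \frac{p(x,y)}{p(x)\,p(y)}}
#' with empirical cell probabilities; zero-count cells contribute 0 (the
#' \eqn{x \log x \to 0} limit) and no pseudocounts are added. Natural-log
#' units (nats) by default.
#'
#' @param x Binary vector (gene mutation status).
#' @param y Categorical vector (subtype labels), same length as `x`.
#' @param log_base `"nats"` (natural log) or `"bits"` (log2).
#' @return Non-negative scalar.
#' @export
mutual_information <- function(x, y, log_base = c("nats", "bits")) {
  log_base <- match.arg(log_base)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.", class = "mutsubtype_shape_error")
  }
  if (length(x) == 0) {
    abort("`x` and `y` must have length >= 1.", class = "mutsubtype_shape_error")
  }
  joint <- table(x, y)
  n <- sum(joint)
  pxy <- joint / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  terms <- pxy * log(pxy / outer(px, py))
  mi <- sum(terms[is.finite(terms)])
  if (log_base == "bits") mi <- mi / log(2)
  max(mi, 0)
}

# Vectorized MI of every column of a binary matrix against labels y (nats).
# Same plug-in estimator as mutual_information(), computed from the 2 x C
# joint counts of each gene simultaneously.
mi_profile <- function(matrix, y) {
  y <- as.factor(y)
  n <- nrow(matrix)
  ind <- stats::model.matrix(~ y - 1)          # n x C class indicator
  n1 <- crossprod(matrix, ind)                 # genes x C counts with x = 1
  ny <- matrix(colSums(ind), nrow = ncol(matrix), ncol = ncol(ind), byrow = TRUE)
  n0 <- ny - n1
  m1 <- colSums(matrix)                        # per-gene count of x = 1
  m0 <- n - m1
  term <- function(cell, margin_x) {
    p <- cell / n
    l <- log((cell * n) / (margin_x * ny))
    out <- p * l
    out[cell == 0] <- 0
    out
  }
  mi <- rowSums(term(n1, m1)) + rowSums(term(n0, m0))
  mi <- pmax(mi, 0)
  names(mi) <- colnames(matrix)
  mi
}

#' Select one representative gene per pathway by mutual information
#'
#' Within each pathway, member genes present in the (training) matrix and
#' passing the recurrence filter compete; the gene with the highest mutual
#' information with the labels wins (ties broken by higher mutation
#' frequency, then lexicographically smaller symbol). Pathways with no
#' surviving member are skipped. Representatives are pooled and deduplicated;
#' a gene chosen by several pathways carries all of them as provenance.
#'
#' Feature selection must see only training samples: pass the training
#' partition of the matrix, never the full cohort.
#'
#' @param matrix Binary samples x genes matrix (training partition).
#' @param labels Categorical labels aligned to the matrix rows.
#' @param pathways Named list of gene sets (from [read_gmt()]).
#' @param threshold Recurrence threshold passed to [recurrence_filter()].
#' @return A `feature_set`: tibble with columns `gene`, `mi`, `frequency`,
#'   `pathways` (list-column of pathway names represented), plus attributes
#'   `threshold` and `status`.
#' @export
select_pathway_representatives <- function(matrix, labels, pathways,
                                           threshold = 0.005) {
  if (length(labels) != nrow(matrix)) {
    abort("`labels` must align with the matrix rows.",
          class = "mutsubtype_shape_error")
  }
  kept <- recurrence_filter(matrix, threshold)
  mi_all <- if (length(kept) > 0) {
    mi_profile(matrix[, kept, drop = FALSE], labels)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  freq_all <- if (length(kept) > 0) colMeans(matrix[, kept, drop = FALSE]) else numeric(0)

  reps <- character(0)
  provenance <- list()
  for (pw in names(pathways)) {
    members <- intersect(pathways[[pw]], kept)
    if (length(members) == 0) next
    mi_m <- mi_all[members]
    fr_m <- freq_all[members]
    ord <- order(-mi_m, -fr_m, members)
    winner <- members[ord[1]]
    if (winner %in% reps) {
      provenance[[winner]] <- c(provenance[[winner]], pw)
    } else {
      reps <- c(reps, winner)
      provenance[[winner]] <- pw
    }
  }
  status <- if (length(reps) == 0) {
    warn("No pathway yielded a representative gene; feature set is empty.")
    "empty"
  } else {
    "ok"
  }
  out <- tibble::tibble(
    gene = reps,
    mi = unname(mi_all[reps]),
    frequency = unname(freq_all[reps]),
    pathways = unname(provenance[reps])
  )
  structure(out, class = c("feature_set", class(out)),
            threshold = threshold, status = status)
}

#' Compare feature sets selected at two recurrence thresholds
#'
#' Quantifies selection stability: Jaccard similarity, inclusion rate of the
#' stricter set within the looser one, and the Spearman rank correlation of
#' the mutual-information rankings over the top `rank_depth` genes of the
#' stricter set (genes absent from the looser set are excluded and their
#' count reported).
#'
#' @param set_strict Feature set from the stricter (higher) threshold.
#' @param set_loose Feature set from the looser (lower) threshold.
#' @param rank_depth Number of top-MI genes of the stricter set to rank
#'   (>= 2, <= number of genes in `set_strict`).
#' @return A one-row tibble: `jaccard`, `inclusion_rate`, `spearman_rho`,
#'   `n_ranked`, `n_excluded`.
#' @export
stability_analysis <- function(set_strict, set_loose, rank_depth = nrow(set_strict)) {
  if (!is.numeric(rank_depth) || rank_depth < 2) {
    abort("`rank_depth` must be >= 2.", class = "mutsubtype_parameter_error")
  }
  if (rank_depth > nrow(set_strict)) {
    abort("`rank_depth` cannot exceed the size of the stricter set.",
          class = "mutsubtype_parameter_error")
  }
  a <- set_strict$gene
  b <- set_loose$gene
  inter <- intersect(a, b)
  uni <- union(a, b)
  jaccard <- if (length(uni) == 0) 1 else length(inter) / length(uni)
  inclusion <- if (length(a) == 0) 1 else length(inter) / length(a)

  top <- set_strict$gene[order(-set_strict$mi)][seq_len(rank_depth)]
  shared <- top[top %in% b]
  n_excluded <- length(top) - length(shared)
  spearman_rho <- if (length(shared) >= 2) {
    mi_s <- set_strict$mi[match(shared, set_strict$gene)]
    mi_l <- set_loose$mi[match(shared, set_loose$gene)]
    suppressWarnings(cor(mi_s, mi_l, method = "spearman"))
  } else {
    NA_real_
  }
  tibble::tibble(
    jaccard = jaccard, inclusion_rate = inclusion,
    spearman_rho = spearman_rho,
    n_ranked = length(shared), n_excluded = n_excluded
  )
}

#' Write a feature set as TSV
#'
#' Columns `gene`, `mi`, `frequency`, `pathways` (semicolon-joined).
#'
#' @param feature_set A `feature_set` tibble.
#' @param path Output path.
#' @export
write_feature_set <- function(feature_set, path) {
  flat <- feature_set |>
    dplyr::mutate(pathways = vapply(.data$pathways, paste, character(1),
                                    collapse = ";"))
  readr::write_tsv(tibble::as_tibble(flat), path, progress = FALSE)
  invisible(path)
}
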