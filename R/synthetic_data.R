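#' Default per-class rate matrix for informative genes
#'
#' Builds a two-level Bernoulli rate code: each informative ("marker") gene
#' is mutated at `base + gap` in the classes it marks and at `base`
#' elsewhere. Marker genes are dedicated to single classes; the most
#' prevalent class receives none and is identified by marker absence,
#' mirroring how the most common tumor subtypes are the ones defined largely
#' by the *absence* of the distinctive alterations enriched in rarer
#' subtypes. The remaining classes share the markers equally, remainders
#' going to the rarest classes.
#'
#' @param proportions Class proportions (used to pick the marker-poor
#'   baseline class and to order remainder allocation).
#' @param n_informative Number of informative genes.
#' @param gap Within-gene rate difference between marked and unmarked
#'   classes, default 0.4.
#' @param base Rate in unmarked classes; defaults to the geometric mean of
#'   `background_range` (the median background rate).
#' @param background_range Background-rate range used for the `base` default.
#' @return Matrix of dim C x n_informative with rates in \[0, 1\].
#' @export
informative_rate_matrix <- function(proportions, n_informative, gap = 0.4,
                                    base = NULL,
                                    background_range = c(0.001, 0.02)) {
  C <- length(proportions)
  if (is.null(base)) base <- sqrt(prod(background_range))
  stopifnot(gap > 0, base >= 0, base + gap <= 1, n_informative >= 1, C >= 2)
  baseline_class <- which.max(proportions)
  marker_classes <- setdiff(seq_len(C), baseline_class)
  # equal share per marker class; remainders to the rarest classes
  share <- rep(n_informative %/% length(marker_classes), length(marker_classes))
  rem <- n_informative %% length(marker_classes)
  if (rem > 0) {
    rare_order <- marker_classes[order(proportions[marker_classes])]
    share[match(rare_order[seq_len(rem)], marker_classes)] <-
      share[match(rare_order[seq_len(rem)], marker_classes)] + 1L
  }
  rates <- matrix(base, C, n_informative)
  g <- 1L
  for (i in seq_along(marker_classes)) {
    if (share[i] == 0) next
    rates[marker_classes[i], g:(g + share[i] - 1L)] <- base + gap
    g <- g + share[i]
  }
  rates
}

#' Synthetic cohort configuration
#'
#' Describes a cohort with the statistical structure sparse somatic-mutation
#' data exhibits: a binary samples x genes matrix at ~1% density whose
#' background per-gene mutation rates are drawn log-uniformly (long-tailed
#' recurrence), a minority of informative genes whose Bernoulli rates depend
#' on the class, imbalanced classes, and a pathway collection in which every
#' informative gene sits in exactly one pathway among noise genes.
#'
#' @param n_samples Cohort size.
#' @param class_proportions Vector summing to 1; one entry per class.
#' @param class_names Optional class names (default `Class1..C`).
#' @param n_genes Total number of genes.
#' @param n_pathways Number of pathways (must satisfy
#'   `n_pathways * genes_per_pathway <= n_genes` and
#'   `n_informative <= n_pathways`).
#' @param genes_per_pathway Genes per pathway.
#' @param n_informative Number of class-informative genes.
#' @param background_rate_range `(low, high)` for the log-uniform background
#'   gene mutation rates; `background_mode = "fixed"` instead uses the
#'   midpoint for every gene (for analytic checks).
#' @param informative_rates Optional C x n_informative rate matrix; default
#'   [informative_rate_matrix()] with `rate_gap`.
#' @param rate_gap Rate gap handed to [informative_rate_matrix()] when
#'   `informative_rates` is not supplied.
#' @param background_mode `"loguniform"` (default) or `"fixed"`.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 900,
                             class_proportions = c(0.47, 0.21, 0.21, 0.11),
                             class_names = NULL,
                             n_genes = 2000, n_pathways = 200,
                             genes_per_pathway = 8, n_informative = 10,
                             background_rate_range = c(0.001, 0.02),
                             informative_rates = NULL, rate_gap = 0.4,
                             background_mode = c("loguniform", "fixed"),
                             seed = 1L) {
  background_mode <- match.arg(background_mode)
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort("`class_proportions` must sum to 1.", class = "mutsubtype_parameter_error")
  }
  if (n_informative > n_genes) {
    abort("`n_informative` cannot exceed `n_genes`.",
          class = "mutsubtype_parameter_error")
  }
  if (n_informative > n_pathways) {
    abort("`n_informative` cannot exceed `n_pathways` (one pathway each).",
          class = "mutsubtype_parameter_error")
  }
  if (n_pathways * genes_per_pathway > n_genes) {
    abort("`n_pathways * genes_per_pathway` cannot exceed `n_genes`.",
          class = "mutsubtype_parameter_error")
  }
  C <- length(class_proportions)
  if (is.null(class_names)) class_names <- paste0("Class", seq_len(C))
  if (is.null(informative_rates)) {
    informative_rates <- informative_rate_matrix(
      class_proportions, n_informative, gap = rate_gap,
      background_range = background_rate_range
    )
  }
  stopifnot(nrow(informative_rates) == C, ncol(informative_rates) == n_informative,
            all(informative_rates >= 0 & informative_rates <= 1))
  structure(
    list(n_samples = as.integer(n_samples),
         class_proportions = class_proportions, class_names = class_names,
         n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
         genes_per_pathway = as.integer(genes_per_pathway),
         n_informative = as.integer(n_informative),
         background_rate_range = background_rate_range,
         informative_rates = informative_rates,
         background_mode = background_mode, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' The TCGA-like cohort preset
#'
#' Approximates the class imbalance of the four major PAM50 breast cancer
#' subtypes (Luminal A / Luminal B / Basal-like / HER2-enriched at roughly
#' 0.47 / 0.21 / 0.21 / 0.11) at n = 900 with 2000 genes, 200 pathways of 8
#' genes and 10 informative genes. Proportions are approximate by design;
#' exact cohort counts are cohort-specific.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
tcga_like_config <- function(seed = 1L, ...) {
  args <- modifyList(
    list(n_samples = 900, class_proportions = c(0.47, 0.21, 0.21, 0.11),
         class_names = c("LumA", "LumB", "Basal", "Her2"),
         n_genes = 2000, n_pathways = 200, genes_per_pathway = 8,
         n_informative = 10, seed = seed),
    list(...)
  )
  do.call(synthetic_config, args)
}

#' Generate a synthetic mutation cohort
#'
#' Class sizes are apportioned by largest remainder and the sample order
#' shuffled; background gene g is mutated i.i.d. Bernoulli(r_g) with r_g
#' log-uniform in `background_rate_range` (or fixed); informative gene j is
#' mutated Bernoulli(`informative_rates[class(sample), j]`). Pathway p holds
#' `genes_per_pathway` consecutive genes and pathway i (i <= n_informative)
#' carries informative gene i as its first member. Deterministic given the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort` list: `matrix` (binary, samples x genes),
#'   `labels` (factor), `pathways` (named list), `truth` (tibble: gene,
#'   pathway, one rate column per class), `config`.
#' @export
generate_cohort <- function(config) {
  with_seed(substream_seed(config$seed, "cohort"), {
    n <- config$n_samples
    C <- length(config$class_proportions)
    sizes <- largest_remainder(n, config$class_proportions)
    labels <- factor(rep(config$class_names, sizes), levels = config$class_names)
    labels <- labels[sample.int(n)]

    genes <- sprintf("G%05d", seq_len(config$n_genes))
    sample_ids <- sprintf("S%04d", seq_len(n))

    # informative gene i is the first member of pathway i
    informative_idx <- (seq_len(config$n_informative) - 1L) *
      config$genes_per_pathway + 1L
    background_idx <- setdiff(seq_len(config$n_genes), informative_idx)

    rates_bg <- switch(
      config$background_mode,
      loguniform = exp(runif(length(background_idx),
                             log(config$background_rate_range[1]),
                             log(config$background_rate_range[2]))),
      fixed = rep(mean(config$background_rate_range), length(background_idx))
    )

    mat <- matrix(0L, n, config$n_genes, dimnames = list(sample_ids, genes))
    mat[, background_idx] <- rbinom(n * length(background_idx), 1,
                                    rep(rates_bg, each = n))
    cls <- as.integer(labels)
    for (j in seq_len(config$n_informative)) {
      mat[, informative_idx[j]] <-
        rbinom(n, 1, config$informative_rates[cls, j])
    }

    pathways <- lapply(seq_len(config$n_pathways), function(p) {
      genes[((p - 1L) * config$genes_per_pathway + 1L):(p * config$genes_per_pathway)]
    })
    names(pathways) <- sprintf("PW%04d", seq_len(config$n_pathways))

    truth <- tibble::tibble(
      gene = genes[informative_idx],
      pathway = names(pathways)[seq_len(config$n_informative)]
    )
    rate_cols <- as.data.frame(t(config$informative_rates))
    names(rate_cols) <- paste0("rate_", config$class_names)
    truth <- dplyr::bind_cols(truth, tibble::as_tibble(rate_cols))

    structure(
      list(matrix = mat, labels = labels, pathways = pathways, truth = truth,
           config = config),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d samples x %d genes (density %.4f), %d classes, %d informative genes\n",
    nrow(x$matrix), ncol(x$matrix), mean(x$matrix), nlevels(x$labels),
    nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic cohort as a MAF fixture
#'
#' Emits one MAF row per mutated (sample, gene) cell, traversing genes in
#' matrix column order, with `Variant_Classification` drawn from the
#' non-synonymous set. Optionally sprinkles additional synonymous rows
#' (classes `Silent`/`3'UTR`) at random cells to exercise the
#' non-synonymous filter: filtering and rebuilding the matrix (with the
#' cohort's sample list) reproduces `cohort$matrix` on its mutated genes.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output path.
#' @param silent_rate Number of synonymous rows to add, as a fraction of the
#'   non-synonymous row count.
#' @param seed Seed for variant-class assignment.
#' @return `path`, invisibly.
#' @export
write_fixture_maf <- function(cohort, path, silent_rate = 0, seed = 1L) {
  mat <- cohort$matrix
  hits <- which(mat == 1L, arr.ind = TRUE)
  hits <- hits[order(hits[, "col"], hits[, "row"]), , drop = FALSE]
  with_seed(substream_seed(seed, "maf"), {
    rows <- tibble::tibble(
      Hugo_Symbol = colnames(mat)[hits[, "col"]],
      Tumor_Sample_Barcode = rownames(mat)[hits[, "row"]],
      Variant_Classification = sample(nonsynonymous_classes(), nrow(hits),
                                      replace = TRUE,
                                      prob = c(0.65, 0.08, 0.01, 0.07, 0.05,
                                               0.03, 0.02, 0.07, 0.02))
    )
    n_silent <- round(silent_rate * nrow(rows))
    if (n_silent > 0) {
      silent <- tibble::tibble(
        Hugo_Symbol = sample(colnames(mat), n_silent, replace = TRUE),
        Tumor_Sample_Barcode = sample(rownames(mat), n_silent, replace = TRUE),
        Variant_Classification = sample(c("Silent", "3'UTR"), n_silent,
                                        replace = TRUE)
      )
      rows <- dplyr::bind_rows(rows, silent)
    }
  })
  lines <- c(
    "#version 2.4",
    paste(names(rows), collapse = "\t"),
    do.call(paste, c(as.list(rows), sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a cohort's pathway collection as a GMT fixture
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output path.
#' @export
write_fixture_gmt <- function(cohort, path) {
  write_gmt(cohort$pathways, path)
}
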