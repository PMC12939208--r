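#' Variant classes treated as non-synonymous
#'
#' The default set of MAF `Variant_Classification` values regarded as
#' protein-altering. Matches the convention used by common MAF-processing
#' tools: missense, nonsense, nonstop, frameshift and in-frame indels,
#' splice-site and translation-start-site changes. Silent, UTR, intronic and
#' flanking classes are excluded.
#'
#' @return Character vector of variant-class names.
#' @export
#' @examples
#' nonsynonymous_classes()
nonsynonymous_classes <- function() {
  c(
    "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site"
  )
}

#' Read a MAF mutation table
#'
#' Reads a tab-separated Mutation Annotation Format file. Comment lines
#' beginning with `#` (including the leading `#version` block) are skipped.
#' Row order is preserved and all columns are kept; downstream functions use
#' `Hugo_Symbol`, `Tumor_Sample_Barcode` and `Variant_Classification`.
#'
#' @param path Path to a MAF (TSV) file.
#' @param required_columns Columns that must be present (case-sensitive).
#' @return A tibble with one row per mutation record.
#' @export
read_maf <- function(path,
                     required_columns = c("Hugo_Symbol", "Tumor_Sample_Barcode",
                                          "Variant_Classification")) {
  if (!file.exists(path)) {
    abort(sprintf("MAF file not found: %s", path), class = "mutsubtype_io_error")
  }
  tbl <- tryCatch(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE, col_types = readr::cols(.default = "c")),
    error = function(e) {
      abort(sprintf("Failed to parse MAF file %s: %s", path, conditionMessage(e)),
            class = "mutsubtype_format_error")
    }
  )
  if (nrow(tbl) == 0 && ncol(tbl) == 0) {
    abort(sprintf("MAF file is empty: %s", path), class = "mutsubtype_format_error")
  }
  missing_cols <- setdiff(required_columns, names(tbl))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("MAF file %s is missing required column(s): %s",
              path, paste(missing_cols, collapse = ", ")),
      class = "mutsubtype_format_error"
    )
  }
  tbl
}

#' Keep only non-synonymous mutation records
#'
#' Retains records whose `Variant_Classification` is in `classes`, preserving
#' relative order. Idempotent; an empty result is legal.
#'
#' @param table A mutation tibble (from [read_maf()]).
#' @param classes Character vector of variant classes to keep.
#' @return Filtered tibble.
#' @export
filter_nonsynonymous <- function(table, classes = nonsynonymous_classes()) {
  if (length(classes) == 0) {
    abort("`classes` must be non-empty.", class = "mutsubtype_parameter_error")
  }
  dplyr::filter(table, .data$Variant_Classification %in% classes)
}

#' Build a binary gene-by-sample mutation matrix
#'
#' Collapses a (filtered) mutation table to a samples x genes indicator
#' matrix: entry (s, g) is 1 when sample s carries at least one retained
#' mutation in gene g. Multiplicity is collapsed to 1. Gene order is
#' first-appearance order; sample order follows `all_samples` when given
#' (samples absent from the table become all-zero rows), else
#' first-appearance order.
#'
#' @param table A mutation tibble, already filtered to the variant classes of
#'   interest (not re-checked here).
#' @param all_samples Optional character vector of sample identifiers; must be
#'   a superset of the samples present in `table`.
#' @return Integer matrix with `rownames` = samples, `colnames` = genes.
#' @export
build_binary_matrix <- function(table, all_samples = NULL) {
  samples_in_table <- unique(table$Tumor_Sample_Barcode)
  if (is.null(all_samples)) {
    samples <- samples_in_table
  } else {
    missing_samples <- setdiff(samples_in_table, all_samples)
    if (length(missing_samples) > 0) {
      abort(
        sprintf("`all_samples` is missing sample(s) present in the table: %s",
                paste(head(missing_samples, 5), collapse = ", ")),
        class = "mutsubtype_consistency_error"
      )
    }
    if (anyDuplicated(all_samples)) {
      abort("`all_samples` contains duplicates.", class = "mutsubtype_consistency_error")
    }
    samples <- all_samples
  }
  genes <- unique(table$Hugo_Symbol)
  mat <- matrix(0L, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  if (nrow(table) > 0) {
    idx <- cbind(match(table$Tumor_Sample_Barcode, samples),
                 match(table$Hugo_Symbol, genes))
    mat[idx] <- 1L
  }
  mat
}

#' Summarize per-sample mutation burden and variant classes
#'
#' Computes per-sample variant counts, tumor mutational burden
#' (count / capture size in Mb) and cohort-level variant-class tallies over
#' the retained records.
#'
#' @param table A mutation tibble.
#' @param capture_size_mb Sequenced territory in megabases (> 0). The default
#'   of 50 Mb approximates a whole-exome capture.
#' @return A `cohort_summary` list with tibbles `per_sample`
#'   (`sample_id`, `n_variants`, `tmb`) and `variant_classes`
#'   (`variant_class`, `n`), plus `capture_size_mb`.
#' @export
summarize_cohort <- function(table, capture_size_mb = 50) {
  if (!is.numeric(capture_size_mb) || length(capture_size_mb) != 1 ||
      capture_size_mb <= 0) {
    abort("`capture_size_mb` must be a single positive number.",
          class = "mutsubtype_parameter_error")
  }
  per_sample <- table |>
    dplyr::count(.data$Tumor_Sample_Barcode, name = "n_variants") |>
    dplyr::rename(sample_id = "Tumor_Sample_Barcode") |>
    dplyr::mutate(tmb = .data$n_variants / capture_size_mb)
  variant_classes <- table |>
    dplyr::count(.data$Variant_Classification, name = "n") |>
    dplyr::rename(variant_class = "Variant_Classification") |>
    dplyr::arrange(dplyr::desc(.data$n))
  structure(
    list(per_sample = per_sample, variant_classes = variant_classes,
         capture_size_mb = capture_size_mb),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d samples, %d retained variants\n",
              nrow(x$per_sample), sum(x$per_sample$n_variants)))
  if (nrow(x$per_sample) > 0) {
    cat(sprintf("Median TMB: %.3f mut/Mb (capture %.1f Mb)\n",
                median(x$per_sample$tmb), x$capture_size_mb))
  }
  invisible(x)
}

#' Write / read a binary mutation matrix as TSV
#'
#' First column `sample_id`, remaining columns one per gene.
#'
#' @param matrix Integer samples x genes matrix.
#' @param path Output path.
#' @return `path`, invisibly (writer); the matrix (reader).
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- tibble::as_tibble(matrix, rownames = "sample_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df[[1]]
  mat
}

#' Write a cohort summary as JSON
#'
#' @param summary A `cohort_summary` object.
#' @param path Output path.
#' @export
write_cohort_summary <- function(summary, path) {
  jsonlite::write_json(
    list(
      capture_size_mb = summary$capture_size_mb,
      per_sample = summary$per_sample,
      variant_classes = summary$variant_classes
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
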