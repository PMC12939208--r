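# Shared fixtures and independent oracles, all built in code.

# --- tiny MAF builders -----------------------------------------------------

write_tiny_maf <- function(rows, path) {
  con <- file(path, "w")
  writeLines("#version 2.4", con)
  writeLines(paste("Hugo_Symbol", "Tumor_Sample_Barcode",
                   "Variant_Classification", sep = "\t"), con)
  for (r in rows) writeLines(paste(r, collapse = "\t"), con)
  close(con)
  path
}

maf_row <- function(gene, sample, class = "Missense_Mutation") {
  c(gene, sample, class)
}

# a 12-record / 3-sample MAF fixture
fixture_maf_12 <- function(path) {
  genes <- c("TP53", "PIK3CA", "GATA3", "MAP3K1")
  rows <- list()
  k <- 1
  for (s in c("S1", "S2", "S3")) {
    for (g in genes) {
      rows[[k]] <- maf_row(g, s)
      k <- k + 1
    }
  }
  write_tiny_maf(rows, path)
}

# mutation tibble with known class mix: 13 non-synonymous, 7 synonymous
fixture_table_20 <- function() {
  classes <- c(rep("Missense_Mutation", 8), rep("Frame_Shift_Del", 3),
               rep("Splice_Site", 2), rep("Silent", 4), rep("3'UTR", 3))
  tibble::tibble(
    Hugo_Symbol = paste0("G", seq_along(classes)),
    Tumor_Sample_Barcode = rep(c("S1", "S2"), length.out = length(classes)),
    Variant_Classification = classes
  )
}

random_mutation_table <- function(n, n_samples = 4, n_genes = 6) {
  tibble::tibble(
    Hugo_Symbol = sample(paste0("G", seq_len(n_genes)), n, replace = TRUE),
    Tumor_Sample_Barcode = sample(paste0("S", seq_len(n_samples)), n, replace = TRUE),
    Variant_Classification = "Missense_Mutation"
  )
}

# --- independent oracles ---------------------------------------------------

# direct evaluation of the mutual-information double sum
mi_oracle <- function(x, y) {
  s <- 0
  for (xv in unique(x)) {
    for (yv in unique(y)) {
      pxy <- mean(x == xv & y == yv)
      if (pxy > 0) s <- s + pxy * log(pxy / (mean(x == xv) * mean(y == yv)))
    }
  }
  s
}

# brute-force pairwise factorization-machine sum
fm_oracle <- function(x, V) {
  total <- 0
  N <- length(x)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (j > i) total <- total + sum(V[i, ] * V[j, ]) * x[i] * x[j]
    }
  }
  total
}

# naive layer-by-layer MLP over the pooled embedding (no dropout)
deep_oracle <- function(x, params) {
  e <- numeric(ncol(params$V))
  for (i in seq_along(x)) e <- e + x[i] * params$V[i, ]
  h <- e
  L <- length(params$mlp)
  for (l in seq_len(L)) {
    W <- params$mlp[[l]]$W
    b <- params$mlp[[l]]$b
    a <- numeric(nrow(W))
    for (r in seq_len(nrow(W))) a[r] <- sum(W[r, ] * h) + b[r]
    h <- if (l < L) pmax(a, 0) else a
  }
  h
}

# AUC as the fraction of concordant positive/negative pairs (ties count 1/2)
auc_concordance_oracle <- function(scores, positives) {
  pos <- which(positives == 1)
  neg <- which(positives == 0)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# exhaustive threshold-sweep average precision
ap_oracle <- function(scores, positives) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(positives)
  prev_recall <- 0
  ap <- 0
  for (t in thresholds) {
    pred <- scores >= t
    tp <- sum(pred & positives == 1)
    precision <- tp / sum(pred)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# small planted cohort for pipeline-level tests
small_planted_config <- function(seed, n_samples = 400, gap = 0.6) {
  synthetic_config(
    n_samples = n_samples, class_proportions = c(0.4, 0.3, 0.3),
    class_names = c("C1", "C2", "C3"), n_genes = 300, n_pathways = 30,
    genes_per_pathway = 8, n_informative = 6, rate_gap = gap, seed = seed
  )
}

fast_train_config <- function(seed = 1L, ...) {
  train_config(max_epochs = 60, seed = seed, ...)
}
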