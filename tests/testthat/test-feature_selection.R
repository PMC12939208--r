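test_that("read_gmt parses sets, collapses duplicates and flags bad lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("P1\tdesc\tA\tB", path)
  expect_equal(read_gmt(path), list(P1 = c("A", "B")))

  writeLines("P1\tdesc\tA\tB\tA", path)
  expect_equal(read_gmt(path)$P1, c("A", "B"))

  writeLines(c("P1\tdesc\tA", "P2\tonlydesc"), path)
  expect_error(read_gmt(path), "line 2", class = "mutsubtype_format_error")

  # 5 pathways x 3 genes with one gene shared by three sets: union = 13
  sets <- list(P1 = c("A", "B", "C"), P2 = c("D", "E", "F"),
               P3 = c("G", "H", "A"), P4 = c("J", "K", "L"),
               P5 = c("A", "M", "N"))
  write_gmt(sets, path)
  parsed <- read_gmt(path)
  expect_equal(length(parsed), 5)
  expect_equal(length(unique(unlist(parsed))), 13)
  expect_equal(parsed, sets)
})

test_that("recurrence_filter keeps genes at or above the threshold", {
  n <- 200
  m <- cbind(
    at_thresh = c(1L, rep(0L, n - 1)),          # 1/200 = 0.005 exactly
    never = rep(0L, n)
  )
  expect_equal(recurrence_filter(m, 0.005), "at_thresh")
  expect_equal(recurrence_filter(m, 0.0051), character(0))

  n <- 1000
  m <- sapply(c(1, 4, 20, 300), function(k) c(rep(1L, k), rep(0L, n - k)))
  colnames(m) <- c("f001", "f004", "f020", "f300")
  expect_equal(recurrence_filter(m, 0.005), c("f020", "f300"))
  expect_error(recurrence_filter(m, 0), class = "mutsubtype_parameter_error")
  expect_error(recurrence_filter(m, 1), class = "mutsubtype_parameter_error")
})

test_that("mutual_information matches the direct double-sum evaluation", {
  # constant x carries no information
  expect_equal(mutual_information(rep(1, 10), rep(c("A", "B"), 5)), 0)

  # x the indicator of a balanced binary y: exactly log 2 nats = 1 bit
  y <- rep(c("A", "B"), each = 8)
  x <- as.integer(y == "A")
  expect_equal(mutual_information(x, y), log(2))
  expect_equal(mutual_information(x, y, log_base = "bits"), 1)

  # joint counts (x=1,A)=3, (x=0,A)=1, (x=1,B)=1, (x=0,B)=3 over n = 8
  x <- c(1, 1, 1, 0, 1, 0, 0, 0)
  y <- rep(c("A", "B"), each = 4)
  expected <- 0.75 * log(1.5) + 0.25 * log(0.5)  # closed form of the sum
  expect_equal(mutual_information(x, y), expected, tolerance = 1e-12)
  expect_equal(mutual_information(x, y), mi_oracle(x, y), tolerance = 1e-12)

  expect_error(mutual_information(c(0, 1), c("A")), class = "mutsubtype_shape_error")
})

test_that("MI is non-negative, bounded by min entropy and label-invariant", {
  withr::local_seed(7)
  entropy <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- sample(LETTERS[1:4], n, replace = TRUE)
    mi <- mutual_information(x, y)
    expect_equal(mi, mi_oracle(x, y), tolerance = 1e-12)
    expect_gte(mi, 0)
    expect_lte(mi, min(entropy(x), entropy(y)) + 1e-12)
    # invariant to relabeling of y
    relab <- setNames(sample(letters[1:4]), LETTERS[1:4])
    expect_equal(mutual_information(x, relab[y]), mi)
  }
})

test_that("permuting labels drives MI towards the permutation null", {
  withr::local_seed(11)
  n <- 2000
  y <- sample(c("A", "B", "C", "D"), n, replace = TRUE)
  x <- rbinom(n, 1, ifelse(y == "A", 0.5, 0.1))
  mi_obs <- mutual_information(x, y)
  null_mi <- replicate(50, mutual_information(x, sample(y)))
  expect_lt(mean(null_mi), quantile(null_mi, 0.95) + 1e-12)
  expect_lt(mean(null_mi), mi_obs / 10)  # permuted labels lose the signal
})

test_that("vectorized per-gene MI agrees with the scalar implementation", {
  withr::local_seed(3)
  X <- matrix(rbinom(50 * 8, 1, 0.3), 50, 8,
              dimnames = list(NULL, paste0("g", 1:8)))
  y <- sample(c("A", "B", "C"), 50, replace = TRUE)
  vec <- mutsubtype:::mi_profile(X, y)
  for (g in colnames(X)) {
    expect_equal(vec[[g]], mutual_information(X[, g], y), tolerance = 1e-12)
  }
})

test_that("pathway representatives are argmax-MI with documented tie-breaks", {
  withr::local_seed(5)
  n <- 100
  y <- rep(c("A", "B"), each = 50)
  informative <- as.integer(y == "A")
  weak <- rbinom(n, 1, 0.3)
  m <- cbind(SIG = informative, NOISE = weak, TIE1 = weak, COMMON = rbinom(n, 1, 0.5))
  pathways <- list(P1 = c("SIG", "NOISE"), P2 = c("SIG", "COMMON"),
                   P3 = c("TIE1", "NOISE"))
  fs <- select_pathway_representatives(m, y, pathways, threshold = 0.01)
  # P1 and P2 both pick the informative gene; provenance records both
  expect_equal(sum(fs$gene == "SIG"), 1)
  expect_setequal(fs$pathways[fs$gene == "SIG"][[1]], c("P1", "P2"))
  # identical columns tie on MI and frequency -> lexicographically smaller wins
  expect_equal(fs$gene[fs$gene %in% c("NOISE", "TIE1")], "NOISE")
  # deterministic under repetition
  expect_identical(fs, select_pathway_representatives(m, y, pathways, 0.01))
})

test_that("selection skips empty pathways and warns when nothing survives", {
  m <- matrix(c(1L, 0L, 0L, 0L), 4, 1, dimnames = list(NULL, "RARE"))
  y <- c("A", "A", "B", "B")
  expect_warning(
    fs <- select_pathway_representatives(m, y, list(P = "ABSENT"), 0.01),
    "empty"
  )
  expect_equal(nrow(fs), 0)
  expect_equal(attr(fs, "status"), "empty")
})

test_that("planted informative genes win their pathways at strong effect sizes", {
  recovered <- sapply(1:3, function(s) {
    cohort <- generate_cohort(small_planted_config(seed = s))
    fs <- select_pathway_representatives(cohort$matrix, cohort$labels,
                                         cohort$pathways, 0.005)
    mean(cohort$truth$gene %in% fs$gene)
  })
  expect_gte(mean(recovered), 0.9)
})

test_that("stability metrics follow the set arithmetic", {
  fs <- function(genes, mi) {
    tibble::tibble(gene = genes, mi = mi, frequency = rep(0.1, length(genes)),
                   pathways = as.list(genes))
  }
  a <- fs(c("g1", "g2", "g3", "g4"), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(stability_analysis(a, a)$jaccard, 1)
  expect_equal(stability_analysis(a, a)$inclusion_rate, 1)
  expect_equal(stability_analysis(a, a)$spearman_rho, 1)

  b <- fs(c("h1", "h2"), c(0.5, 0.1))
  res <- stability_analysis(a, b)
  expect_equal(res$jaccard, 0)
  expect_equal(res$inclusion_rate, 0)

  # strict set nested in loose set
  loose <- fs(paste0("g", 1:8), c(0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1))
  strict <- fs(paste0("g", 1:4), c(0.8, 0.7, 0.6, 0.5))
  res <- stability_analysis(strict, loose)
  expect_equal(res$jaccard, 0.5)
  expect_equal(res$inclusion_rate, 1.0)
  expect_equal(res$spearman_rho, 1.0)
  expect_lte(res$jaccard, res$inclusion_rate)
  expect_error(stability_analysis(strict, loose, rank_depth = 1),
               class = "mutsubtype_parameter_error")
})

test_that("genes that keep winning their pathway survive threshold loosening", {
  cohort <- generate_cohort(small_planted_config(seed = 9))
  fs_strict <- select_pathway_representatives(cohort$matrix, cohort$labels,
                                              cohort$pathways, 0.01)
  fs_loose <- select_pathway_representatives(cohort$matrix, cohort$labels,
                                             cohort$pathways, 0.0025)
  freq <- colMeans(cohort$matrix)
  mi <- mutsubtype:::mi_profile(cohort$matrix, cohort$labels)
  for (i in seq_len(nrow(fs_strict))) {
    g <- fs_strict$gene[i]
    still_wins <- all(vapply(fs_strict$pathways[[i]], function(pw) {
      members <- intersect(cohort$pathways[[pw]],
                           names(freq)[freq >= 0.0025])
      ord <- order(-mi[members], -freq[members], members)
      members[ord[1]] == g
    }, logical(1)))
    if (still_wins) expect_true(g %in% fs_loose$gene)
  }
})
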