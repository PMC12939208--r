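#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom stats rbinom runif rnorm quantile cor predict median
#' @importFrom utils head modifyList
NULL

# Deterministic sub-seed derivation: one user-facing seed fans out into named
# streams (split / init / sampler / dropout / bootstrap / ...) so pipeline
# stages can be re-run independently yet reproducibly.  Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) %% 2147480000 + h * 7919) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

softmax_rows <- function(logits) {
  shifted <- logits - apply(logits, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}

assert_binary_matrix <- function(x, arg = "x") {
  if (!is.matrix(x)) abort(sprintf("`%s` must be a matrix.", arg), class = "mutsubtype_shape_error")
  if (!all(x == 0 | x == 1)) {
    abort(sprintf("`%s` must contain only 0/1 entries.", arg), class = "mutsubtype_domain_error")
  }
  invisible(x)
}

# largest-remainder apportionment of n into round(n * p) with sum exactly n
largest_remainder <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}
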