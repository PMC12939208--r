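#' Model configuration for the three-branch classifier
#'
#' The classifier combines a linear (wide) branch, a factorization-machine
#' branch over latent feature embeddings, and a deep branch applying an MLP
#' to the sum-pooled embedding. Class logits are the sum of the enabled
#' branches, normalized by softmax.
#'
#' The literal factorization-machine output is a scalar; a scalar added to
#' every class logit is annihilated by softmax, so the default `fm_mode`
#' `"per_class"` projects the K-dimensional interaction vector to C class
#' logits with a learned linear map. `"scalar"` keeps the literal (inert)
#' form.
#'
#' @param n_features Number of binary input features (N).
#' @param n_classes Number of classes (C), default 4.
#' @param embedding_dim Latent dimension K of the feature embeddings, default 4.
#' @param hidden_sizes Hidden layer widths of the deep branch, default c(64, 32).
#' @param dropout_rate Dropout probability in the deep branch, default 0.5.
#' @param fm_mode `"per_class"` or `"scalar"`.
#' @param branches Subset of `c("wide", "fm", "deep")`; disabled branches
#'   contribute zero logits (used for ablation variants).
#' @return A `model_config` list.
#' @export
model_config <- function(n_features, n_classes = 4, embedding_dim = 4,
                         hidden_sizes = c(64, 32), dropout_rate = 0.5,
                         fm_mode = c("per_class", "scalar"),
                         branches = c("wide", "fm", "deep")) {
  fm_mode <- match.arg(fm_mode)
  stopifnot(n_features >= 1, n_classes >= 2, embedding_dim >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  branches <- match.arg(branches, c("wide", "fm", "deep"), several.ok = TRUE)
  if (length(branches) == 0) {
    abort("`branches` must be non-empty.", class = "mutsubtype_parameter_error")
  }
  structure(
    list(n_features = as.integer(n_features), n_classes = as.integer(n_classes),
         embedding_dim = as.integer(embedding_dim),
         hidden_sizes = as.integer(hidden_sizes),
         dropout_rate = dropout_rate, fm_mode = fm_mode, branches = branches),
    class = "model_config"
  )
}

#' Initialize model parameters
#'
#' Embeddings and the FM projection start from small-scale normals
#' (sd = 0.01); dense-layer weights use fan-in-scaled uniform initialization;
#' all biases start at zero.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for reproducible initialization.
#' @return A `model_params` list: `W_linear` (C x N), `b` (C),
#'   `V` (N x K), `fm_projection` (C x K), `mlp` (list of `W`/`b` layers).
#' @export
init_params <- function(config, seed = 1L) {
  with_seed(seed, {
    N <- config$n_features; C <- config$n_classes; K <- config$embedding_dim
    fan_unif <- function(nout, nin) {
      r <- 1 / sqrt(nin)
      matrix(runif(nout * nin, -r, r), nout, nin)
    }
    sizes <- c(K, config$hidden_sizes, C)
    mlp <- lapply(seq_len(length(sizes) - 1L), function(l) {
      list(W = fan_unif(sizes[l + 1L], sizes[l]), b = numeric(sizes[l + 1L]))
    })
    structure(
      list(
        W_linear = matrix(rnorm(C * N, sd = 0.01), C, N),
        b = numeric(C),
        V = matrix(rnorm(N * K, sd = 0.01), N, K),
        fm_projection = matrix(rnorm(C * K, sd = 0.01), C, K),
        mlp = mlp
      ),
      class = "model_params"
    )
  })
}

#' Linear (wide) branch logits
#'
#' Affine map `W_linear x + b` capturing marginal single-gene effects.
#'
#' @param x Binary feature vector of length N.
#' @param params A `model_params` list.
#' @return Numeric vector of C logits.
#' @export
forward_linear <- function(x, params) {
  if (length(x) != ncol(params$W_linear)) {
    abort("`x` length does not match the number of features.",
          class = "mutsubtype_shape_error")
  }
  as.vector(params$W_linear %*% x + params$b)
}

#' Factorization-machine interaction vector
#'
#' Component k equals `0.5 * ((sum_i x_i v_ik)^2 - sum_i x_i v_ik^2)` (for
#' binary x, `x_i^2 = x_i`), the O(NK) sum-of-squares form; summing over k
#' recovers the pairwise form `sum_i sum_{j>i} <v_i, v_j> x_i x_j`.
#'
#' @param x Binary feature vector of length N.
#' @param V N x K embedding matrix.
#' @return Numeric vector of length K.
#' @export
fm_interaction_vector <- function(x, V) {
  if (length(x) != nrow(V)) {
    abort("`x` length does not match the embedding matrix.",
          class = "mutsubtype_shape_error")
  }
  s <- as.vector(crossprod(V, x))
  q <- as.vector(crossprod(V^2, x))
  0.5 * (s^2 - q)
}

#' Factorization-machine branch logits
#'
#' In `per_class` mode the interaction vector is projected to C logits; in
#' `scalar` mode the literal scalar interaction sum is broadcast to all
#' classes (and is therefore inert under softmax).
#'
#' @param x Binary feature vector.
#' @param params A `model_params` list.
#' @param config A [model_config()].
#' @return Numeric vector of C logits.
#' @export
forward_fm <- function(x, params, config) {
  f <- fm_interaction_vector(x, params$V)
  if (config$fm_mode == "per_class") {
    as.vector(params$fm_projection %*% f)
  } else {
    rep(sum(f), config$n_classes)
  }
}

#' Deep branch logits
#'
#' Sum-pools the active feature embeddings into `e = sum_i x_i v_i` (length
#' K) and passes it through an MLP: dense + ReLU + dropout per hidden layer,
#' then a dense C-unit head with no activation. Dropout is active only in
#' training mode.
#'
#' @param x Binary feature vector.
#' @param params A `model_params` list.
#' @param config A [model_config()].
#' @param training_mode Logical; enables dropout.
#' @return Numeric vector of C logits.
#' @export
forward_deep <- function(x, params, config, training_mode = FALSE) {
  if (length(x) != nrow(params$V)) {
    abort("`x` length does not match the embedding matrix.",
          class = "mutsubtype_shape_error")
  }
  h <- matrix(as.vector(crossprod(params$V, x)), nrow = 1)
  out <- deep_forward_batch(h, params, config, training_mode = training_mode)
  as.vector(out$y)
}

# Batch deep branch: E is B x K pooled embeddings. Returns logits and the
# per-layer caches needed for backpropagation. Inverted dropout (scaling by
# 1/(1-p) at train time) keeps inference a plain forward pass.
deep_forward_batch <- function(E, params, config, training_mode = FALSE) {
  L <- length(params$mlp)
  h <- E
  cache <- vector("list", L)
  p <- config$dropout_rate
  for (l in seq_len(L)) {
    layer <- params$mlp[[l]]
    a <- h %*% t(layer$W) + matrix(layer$b, nrow(h), length(layer$b), byrow = TRUE)
    if (l < L) {
      r <- a * (a > 0)
      if (training_mode && p > 0) {
        mask <- matrix(rbinom(length(r), 1, 1 - p), nrow(r), ncol(r)) / (1 - p)
        h_out <- r * mask
      } else {
        mask <- NULL
        h_out <- r
      }
      cache[[l]] <- list(input = h, a = a, mask = mask)
      h <- h_out
    } else {
      cache[[l]] <- list(input = h, a = a, mask = NULL)
      h <- a
    }
  }
  list(y = h, cache = cache)
}

# Full batch forward pass with caches for training. X is B x N binary.
forward_batch <- function(X, params, config, training_mode = FALSE) {
  B <- nrow(X); C <- config$n_classes
  logits <- matrix(0, B, C)
  cache <- list()
  if ("wide" %in% config$branches) {
    logits <- logits + X %*% t(params$W_linear) +
      matrix(params$b, B, C, byrow = TRUE)
  }
  need_embed <- any(c("fm", "deep") %in% config$branches)
  if (need_embed) {
    S <- X %*% params$V                       # B x K pooled embeddings
    cache$S <- S
  }
  if ("fm" %in% config$branches) {
    Q <- X %*% (params$V^2)
    F_int <- 0.5 * (S^2 - Q)
    cache$F_int <- F_int
    if (config$fm_mode == "per_class") {
      logits <- logits + F_int %*% t(params$fm_projection)
    } else {
      logits <- logits + matrix(rowSums(F_int), B, C)
    }
  }
  if ("deep" %in% config$branches) {
    deep <- deep_forward_batch(S, params, config, training_mode = training_mode)
    logits <- logits + deep$y
    cache$deep <- deep$cache
  }
  list(logits = logits, cache = cache)
}

#' Forward pass over a batch of samples
#'
#' @param x_batch Binary matrix (B x N) or a single length-N vector.
#' @param params A `model_params` list.
#' @param config A [model_config()].
#' @param training_mode Logical; enables dropout in the deep branch.
#' @return A `prediction_batch` list: `logits` (B x C), `probabilities`
#'   (B x C, rows summing to 1), `predicted_class` (integer vector of column
#'   indices).
#' @export
forward <- function(x_batch, params, config, training_mode = FALSE) {
  if (is.vector(x_batch)) x_batch <- matrix(x_batch, nrow = 1)
  assert_binary_matrix(x_batch, "x_batch")
  if (ncol(x_batch) != config$n_features) {
    abort("`x_batch` width does not match `config$n_features`.",
          class = "mutsubtype_shape_error")
  }
  fp <- forward_batch(x_batch, params, config, training_mode = training_mode)
  probs <- softmax_rows(fp$logits)
  structure(
    list(logits = fp$logits, probabilities = probs,
         predicted_class = max.col(probs, ties.method = "first")),
    class = "prediction_batch"
  )
}

#' Save / load model parameters as a portable text checkpoint
#'
#' Single-file format: a JSON header line holding the model configuration and
#' parameter shapes, followed by one `%.17g`-formatted line per parameter
#' block. Full decimal precision makes reloaded inference bit-identical.
#'
#' @param params A `model_params` list.
#' @param config The matching [model_config()].
#' @param path Checkpoint path.
#' @return `path` invisibly (save); a list `params`, `config` (load).
#' @export
save_checkpoint <- function(params, config, path) {
  flat <- flatten_params(params)
  header <- jsonlite::toJSON(
    list(format = "mutsubtype-checkpoint-1",
         config = unclass(config),
         blocks = lapply(flat, function(m) dim(as.matrix(m)))),
    auto_unbox = TRUE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  for (m in flat) {
    writeLines(paste(sprintf("%.17g", as.numeric(m)), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$format, "mutsubtype-checkpoint-1")) {
    abort("Unrecognized checkpoint format.", class = "mutsubtype_format_error")
  }
  cfg <- header$config
  config <- model_config(
    n_features = cfg$n_features, n_classes = cfg$n_classes,
    embedding_dim = cfg$embedding_dim, hidden_sizes = cfg$hidden_sizes,
    dropout_rate = cfg$dropout_rate, fm_mode = cfg$fm_mode,
    branches = cfg$branches
  )
  values <- lapply(lines[-1], function(l) as.numeric(strsplit(l, " ", fixed = TRUE)[[1]]))
  shaped <- mapply(function(v, d) matrix(v, d[1], d[2]), values, header$blocks,
                   SIMPLIFY = FALSE)
  names(shaped) <- names(header$blocks)
  params <- unflatten_params(shaped, config)
  list(params = params, config = config)
}

# canonical ordering of parameter blocks for checkpoints and the optimizer
flatten_params <- function(params) {
  out <- list(W_linear = params$W_linear, b = matrix(params$b, ncol = 1),
              V = params$V, fm_projection = params$fm_projection)
  for (l in seq_along(params$mlp)) {
    out[[paste0("mlp", l, "_W")]] <- params$mlp[[l]]$W
    out[[paste0("mlp", l, "_b")]] <- matrix(params$mlp[[l]]$b, ncol = 1)
  }
  out
}

unflatten_params <- function(blocks, config) {
  n_layers <- (length(blocks) - 4L) / 2L
  mlp <- lapply(seq_len(n_layers), function(l) {
    list(W = blocks[[paste0("mlp", l, "_W")]],
         b = as.vector(blocks[[paste0("mlp", l, "_b")]]))
  })
  structure(
    list(W_linear = blocks$W_linear, b = as.vector(blocks$b), V = blocks$V,
         fm_projection = blocks$fm_projection, mlp = mlp),
    class = "model_params"
  )
}
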