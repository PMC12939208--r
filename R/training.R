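#' Training configuration
#'
#' Defaults follow the training recipe the classifier was designed around:
#' Adam (beta1 = 0.9, beta2 = 0.999) at an initial learning rate of 1e-3,
#' halved when the validation loss fails to improve for 10 epochs; early
#' stopping after 10 non-improving epochs (improvement means a drop of more
#' than `early_stop_min_delta`); L2 weight decay of 1e-3 on the linear and
#' dense weights only (not embeddings, not biases); batch size 64 for at
#' most 300 epochs; class imbalance handled purely by inverse-frequency
#' weighted sampling of mini-batches, with an unweighted cross-entropy loss.
#'
#' @param lr Initial learning rate.
#' @param adam_betas Adam momentum parameters (beta1, beta2).
#' @param weight_decay L2 coefficient for linear/dense/projection weights.
#' @param lr_decay_factor Multiplicative learning-rate decay on plateau.
#' @param lr_patience Epochs without improvement before decaying the rate.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param early_stop_min_delta Minimum validation-loss drop that counts as
#'   improvement.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of epochs.
#' @param val_fraction Stratified fraction of the training data carved out as
#'   the internal validation set.
#' @param sampler `"weighted"` (inverse class-frequency, the default recipe)
#'   or `"uniform"` mini-batch sampling; the uniform mode exists for
#'   controlled comparisons of the rebalancing strategy.
#' @param seed Integer seed; all randomness (initialization, sampling,
#'   dropout, splits) derives from it through named sub-streams.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-3, adam_betas = c(0.9, 0.999),
                         weight_decay = 1e-3, lr_decay_factor = 0.5,
                         lr_patience = 10, early_stop_patience = 10,
                         early_stop_min_delta = 1e-3, batch_size = 64,
                         max_epochs = 300, val_fraction = 0.1,
                         sampler = c("weighted", "uniform"), seed = 1L) {
  sampler <- match.arg(sampler)
  stopifnot(lr > 0, length(adam_betas) == 2, all(adam_betas > 0 & adam_betas < 1),
            weight_decay >= 0, lr_decay_factor > 0, lr_decay_factor < 1,
            lr_patience >= 1, early_stop_patience >= 1,
            early_stop_min_delta >= 0, batch_size >= 1, max_epochs >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(
    list(lr = lr, adam_betas = adam_betas, weight_decay = weight_decay,
         lr_decay_factor = lr_decay_factor, lr_patience = lr_patience,
         early_stop_patience = early_stop_patience,
         early_stop_min_delta = early_stop_min_delta,
         batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
         val_fraction = val_fraction, sampler = sampler,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Inverse class-frequency sampling weights
#'
#' Weight of sample i is `1 / count(class(i))` so that sampling with
#' replacement proportional to the weights draws each class with equal
#' expected frequency.
#'
#' @param labels Categorical vector.
#' @return Numeric weight vector aligned to `labels`.
#' @export
inverse_frequency_weights <- function(labels) {
  if (length(labels) == 0) {
    abort("`labels` must be non-empty.", class = "mutsubtype_parameter_error")
  }
  counts <- table(labels)
  as.numeric(1 / counts[as.character(labels)])
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently (deterministic given `seed`) and deals
#' its samples round-robin across folds, so per-fold class counts are within
#' one sample of proportionality and the folds partition the index set.
#'
#' @param labels Categorical vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k) aligned to `labels`.
#' @export
make_stratified_folds <- function(labels, k = 5, seed = 1L) {
  n <- length(labels)
  if (k > n) abort("`k` cannot exceed the number of samples.",
                   class = "mutsubtype_parameter_error")
  if (k < 2) abort("`k` must be at least 2.", class = "mutsubtype_parameter_error")
  counts <- table(labels)
  if (any(counts < k)) {
    warn(sprintf("Some classes have fewer than %d samples; folds are best-effort.", k))
  }
  fold <- integer(n)
  with_seed(substream_seed(seed, "folds"), {
    offset <- 0L
    for (cls in names(counts)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      # rotate the starting fold across classes so fold sizes stay balanced
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

# stratified holdout: TRUE = validation membership
stratified_holdout <- function(labels, fraction, seed) {
  n <- length(labels)
  val <- logical(n)
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      n_val <- max(1L, round(length(idx) * fraction))
      n_val <- min(n_val, length(idx) - 1L)  # keep at least one for training
      val[sample(idx, n_val)] <- TRUE
    }
  })
  val
}

# ---- loss and gradients ---------------------------------------------------

# mean multiclass cross-entropy; T_onehot is B x C
ce_loss <- function(probs, T_onehot) {
  -mean(log(pmax(rowSums(probs * T_onehot), 1e-12)))
}

# Backpropagation through the batch forward pass. Returns gradients in the
# same structure as `params` plus the scalar loss. Derivation notes:
#   dY = (P - T)/B for softmax + mean cross-entropy;
#   wide:  dW = dY' X, db = colSums(dY);
#   FM:    F = 0.5 (S^2 - Q), S = X V, Q = X V^2
#          per-class: dF = dY P_fm;  dP_fm = dY' F
#          dV += X'(dF * S) - V * (X' dF);
#   deep:  standard MLP backprop down to the pooled embedding E = S,
#          then dV += X' dE.
backprop_batch <- function(X, T_onehot, params, config, training_mode = TRUE) {
  fp <- forward_batch(X, params, config, training_mode = training_mode)
  probs <- softmax_rows(fp$logits)
  loss <- ce_loss(probs, T_onehot)
  B <- nrow(X)
  dY <- (probs - T_onehot) / B

  g <- list(W_linear = NULL, b = NULL, V = NULL, fm_projection = NULL, mlp = NULL)
  K <- config$embedding_dim
  dV <- matrix(0, nrow(params$V), K)

  if ("wide" %in% config$branches) {
    g$W_linear <- crossprod(dY, X)
    g$b <- colSums(dY)
  }
  if ("fm" %in% config$branches) {
    S <- fp$cache$S
    F_int <- fp$cache$F_int
    if (config$fm_mode == "per_class") {
      dF <- dY %*% params$fm_projection
      g$fm_projection <- crossprod(dY, F_int)
    } else {
      dF <- matrix(rowSums(dY), B, K)
    }
    dV <- dV + crossprod(X, dF * S) - params$V * crossprod(X, dF)
  }
  if ("deep" %in% config$branches) {
    cache <- fp$cache$deep
    L <- length(cache)
    p <- config$dropout_rate
    g$mlp <- vector("list", L)
    delta <- dY                      # gradient wrt layer output
    for (l in rev(seq_len(L))) {
      layer_cache <- cache[[l]]
      if (l < L) {
        if (!is.null(layer_cache$mask)) delta <- delta * layer_cache$mask
        delta <- delta * (layer_cache$a > 0)
      }
      g$mlp[[l]] <- list(W = crossprod(delta, layer_cache$input),
                         b = colSums(delta))
      delta <- delta %*% params$mlp[[l]]$W
    }
    dV <- dV + crossprod(X, delta)   # delta is now dE (B x K)
  }
  if (any(c("fm", "deep") %in% config$branches)) g$V <- dV
  list(grads = g, loss = loss)
}

# ---- Adam optimizer over the flattened parameter list ---------------------

adam_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

# blocks subject to weight decay: linear weights, dense weights, FM projection
decayed_blocks <- function(block_names) {
  block_names[block_names == "W_linear" | block_names == "fm_projection" |
                grepl("^mlp[0-9]+_W$", block_names)]
}

adam_step <- function(params, grads, state, lr, betas, weight_decay, eps = 1e-8) {
  flat_p <- flatten_params(params)
  flat_g <- flatten_params(structure(fill_missing_grads(grads, params),
                                     class = "model_params"))
  decay_set <- decayed_blocks(names(flat_p))
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  for (nm in names(flat_p)) {
    gmat <- flat_g[[nm]]
    if (weight_decay > 0 && nm %in% decay_set) {
      gmat <- gmat + weight_decay * flat_p[[nm]]
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gmat
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gmat^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    flat_p[[nm]] <- flat_p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = unflatten_params_like(flat_p, params), state = state)
}

# zero gradients for branches disabled in the config
fill_missing_grads <- function(grads, params) {
  g <- grads
  if (is.null(g$W_linear)) { g$W_linear <- params$W_linear * 0; g$b <- params$b * 0 }
  if (is.null(g$V)) g$V <- params$V * 0
  if (is.null(g$fm_projection)) g$fm_projection <- params$fm_projection * 0
  if (is.null(g$mlp)) {
    g$mlp <- lapply(params$mlp, function(l) list(W = l$W * 0, b = l$b * 0))
  }
  g
}

unflatten_params_like <- function(blocks, template) {
  mlp <- lapply(seq_along(template$mlp), function(l) {
    list(W = blocks[[paste0("mlp", l, "_W")]],
         b = as.vector(blocks[[paste0("mlp", l, "_b")]]))
  })
  structure(
    list(W_linear = blocks$W_linear, b = as.vector(blocks$b), V = blocks$V,
         fm_projection = blocks$fm_projection, mlp = mlp),
    class = "model_params"
  )
}

# ---- training loop --------------------------------------------------------

#' Train the three-branch classifier
#'
#' Mini-batches are drawn with replacement proportional to inverse
#' class-frequency weights (one epoch = `ceiling(n / batch_size)` batches);
#' the loss is plain (unweighted) cross-entropy. A stratified
#' `val_fraction` carve-out of the training data drives plateau learning-rate
#' decay and early stopping (independent patience counters; the scheduler is
#' checked before the stopper each epoch), and the parameters with the best
#' validation loss are returned.
#'
#' @param x Binary samples x features matrix (training partition).
#' @param y Categorical labels aligned to the rows of `x`.
#' @param config A [train_config()].
#' @param model_cfg A [model_config()]; defaults to one sized to `x` with all
#'   branches enabled.
#' @return A `mutsubtype_fit` object: best `params`, `model_config`,
#'   `train_config`, `class_names`, `feature_names`, `history` tibble
#'   (epoch, train_loss, val_loss, lr), `best_epoch`, `stopped_early`.
#' @export
fit_classifier <- function(x, y, config = train_config(),
                           model_cfg = NULL) {
  assert_binary_matrix(x, "x")
  y <- as.factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) {
    abort("Training data must contain at least two classes.",
          class = "mutsubtype_parameter_error")
  }
  if (length(y) != nrow(x)) {
    abort("`y` must align with the rows of `x`.", class = "mutsubtype_shape_error")
  }
  if (is.null(model_cfg)) model_cfg <- model_config(n_features = ncol(x),
                                                    n_classes = nlevels(y))
  if (model_cfg$n_features != ncol(x) || model_cfg$n_classes != nlevels(y)) {
    abort("`model_cfg` does not match the data dimensions.",
          class = "mutsubtype_shape_error")
  }

  val_mask <- stratified_holdout(as.character(y),
                                 config$val_fraction,
                                 substream_seed(config$seed, "valsplit"))
  X_tr <- x[!val_mask, , drop = FALSE]
  y_tr <- y[!val_mask]
  X_val <- x[val_mask, , drop = FALSE]
  y_val <- y[val_mask]
  C <- nlevels(y)
  T_tr <- diag(C)[as.integer(y_tr), , drop = FALSE]
  T_val <- diag(C)[as.integer(y_val), , drop = FALSE]

  params <- init_params(model_cfg, substream_seed(config$seed, "init"))
  state <- adam_init(params)
  w <- if (identical(config$sampler, "uniform")) {
    rep(1, length(y_tr))
  } else {
    inverse_frequency_weights(as.character(y_tr))
  }

  n <- nrow(X_tr)
  batches_per_epoch <- ceiling(n / config$batch_size)
  lr <- config$lr
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  lr_wait <- 0L
  stop_wait <- 0L
  stopped_early <- FALSE
  history <- vector("list", config$max_epochs)

  sampler_seed <- substream_seed(config$seed, "sampler")
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(sampler_seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  for (epoch in seq_len(config$max_epochs)) {
    epoch_loss <- 0
    for (b in seq_len(batches_per_epoch)) {
      idx <- sample.int(n, config$batch_size, replace = TRUE, prob = w)
      bp <- backprop_batch(X_tr[idx, , drop = FALSE],
                           T_tr[idx, , drop = FALSE],
                           params, model_cfg, training_mode = TRUE)
      upd <- adam_step(params, bp$grads, state, lr, config$adam_betas,
                       config$weight_decay)
      params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + bp$loss
    }
    train_loss <- epoch_loss / batches_per_epoch
    val_probs <- softmax_rows(forward_batch(X_val, params, model_cfg,
                                            training_mode = FALSE)$logits)
    val_loss <- ce_loss(val_probs, T_val)
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                       val_loss = val_loss, lr = lr)

    improved <- val_loss < best_val - config$early_stop_min_delta
    if (improved) {
      best_val <- val_loss
      best_params <- params
      best_epoch <- epoch
      lr_wait <- 0L
      stop_wait <- 0L
    } else {
      lr_wait <- lr_wait + 1L
      stop_wait <- stop_wait + 1L
      if (lr_wait >= config$lr_patience) {
        lr <- lr * config$lr_decay_factor
        lr_wait <- 0L
      }
      if (stop_wait >= config$early_stop_patience) {
        stopped_early <- TRUE
        history <- history[seq_len(epoch)]
        break
      }
    }
  }

  structure(
    list(params = best_params, model_config = model_cfg, train_config = config,
         class_names = levels(y), feature_names = colnames(x),
         history = dplyr::bind_rows(history), best_epoch = best_epoch,
         stopped_early = stopped_early),
    class = "mutsubtype_fit"
  )
}

#' @export
print.mutsubtype_fit <- function(x, ...) {
  cat(sprintf(
    "Three-branch classifier (%s): %d features -> %d classes\n",
    paste(x$model_config$branches, collapse = "+"),
    x$model_config$n_features, x$model_config$n_classes))
  cat(sprintf("Trained %d epochs (best epoch %d%s)\n",
              nrow(x$history), x$best_epoch,
              if (x$stopped_early) ", early-stopped" else ""))
  invisible(x)
}

#' Predict from a fitted classifier
#'
#' @param object A `mutsubtype_fit`.
#' @param newdata Binary samples x features matrix with the same columns the
#'   model was trained on.
#' @param type `"class"` for hard labels, `"prob"` for the class-probability
#'   matrix.
#' @param ... Unused.
#' @return Factor of predicted classes, or a numeric matrix of probabilities
#'   with one column per class.
#' @export
predict.mutsubtype_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  pred <- forward(newdata, object$params, object$model_config,
                  training_mode = FALSE)
  if (type == "prob") {
    colnames(pred$probabilities) <- object$class_names
    return(pred$probabilities)
  }
  factor(object$class_names[pred$predicted_class], levels = object$class_names)
}

#' Stratified k-fold cross-validation of the full classifier
#'
#' For each fold the model is trained on the remaining folds (with its own
#' internal validation carve-out) and evaluated on the held-out fold, so
#' every sample is scored exactly once.
#'
#' @param x Binary samples x features matrix.
#' @param y Categorical labels.
#' @param k Number of folds.
#' @param config A [train_config()]; per-fold seeds derive from its seed.
#' @param model_cfg Optional [model_config()].
#' @return A `cv_result` list: `fold_reports` (one [evaluate_predictions()]
#'   report per fold), `fold_of_sample`, `summary` tibble of per-metric mean
#'   and sd across folds.
#' @export
cross_validate <- function(x, y, k = 5, config = train_config(),
                           model_cfg = NULL) {
  y <- droplevels(as.factor(y))
  fold <- make_stratified_folds(as.character(y), k = k, seed = config$seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fold_cfg <- config
    fold_cfg$seed <- substream_seed(config$seed, paste0("fold", f))
    fit <- fit_classifier(x[tr, , drop = FALSE], y[tr], fold_cfg, model_cfg)
    probs <- predict(fit, x[!tr, , drop = FALSE], type = "prob")
    reports[[f]] <- evaluate_predictions(y[!tr], probs)
  }
  metrics <- dplyr::bind_rows(
    lapply(seq_len(k), function(f) {
      g <- glance_report(reports[[f]])
      g$fold <- f
      g
    })
  )
  summary <- metrics |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(
    list(fold_reports = reports, fold_of_sample = fold, summary = summary,
         per_fold = metrics),
    class = "cv_result"
  )
}
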