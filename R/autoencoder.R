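# A three-hidden-layer penalized autoencoder trained on the stacked omics
# matrix. Hidden layers use tanh with (inverted) dropout; the output layer
# is sigmoid so that the cross-entropy ("logloss") objective is defined on
# inputs scaled to [0,1]. The objective adds an elementwise L1 penalty on
# the weight matrices (alpha_w, per-model l1 override), an optional L2
# weight penalty (per-model l2 override) and a squared-activation penalty
# (alpha_a) averaged over the mini-batch. Optimized by mini-batch gradient
# descent with adaptive moments (Adam); everything is seeded.

#' Autoencoder configuration
#'
#' @param bottleneck width of the middle hidden layer (the deep-feature
#'   count). The canonical grid is 50, 100, 150, 200, 250, 300, 400, 500.
#' @param hidden_sizes integer triple `(encoder, bottleneck, decoder)`;
#'   default `c(500, bottleneck, 500)`.
#' @param epochs training epochs (default 10).
#' @param hidden_dropout dropout rate on the hidden layers in `[0, 1)`
#'   (default 0.5), applied during training only.
#' @param alpha_w global L1 weight-penalty coefficient (default 0.001).
#' @param alpha_a squared-activation penalty coefficient (default 1e-4),
#'   averaged over the mini-batch.
#' @param l1_override,l2_override optional per-model weight-penalty
#'   coefficients: `l1_override` replaces `alpha_w`, `l2_override` adds a
#'   squared (L2) weight penalty.
#' @param learning_rate,batch_size Adam step size and mini-batch size.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @param model_id optional label used in grid reports.
#' @return A list of class `ae_config`.
#' @export
ae_config <- function(bottleneck = 150,
                      hidden_sizes = c(500, bottleneck, 500),
                      epochs = 10, hidden_dropout = 0.5,
                      alpha_w = 0.001, alpha_a = 1e-4,
                      l1_override = NULL, l2_override = NULL,
                      learning_rate = 1e-3, batch_size = 32,
                      seed = 1, model_id = NULL) {
  if (length(hidden_sizes) != 3 || any(hidden_sizes < 1))
    stopf("`hidden_sizes` must be a positive integer triple")
  if (hidden_dropout < 0 || hidden_dropout >= 1)
    stopf("`hidden_dropout` must lie in [0, 1)")
  if (any(c(alpha_w, alpha_a, l1_override, l2_override) < 0))
    stopf("penalty coefficients must be non-negative")
  if (epochs < 0) stopf("`epochs` must be non-negative")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 epochs = as.integer(epochs),
                 hidden_dropout = hidden_dropout,
                 activation = "TanhWithDropout",
                 alpha_w = alpha_w, alpha_a = alpha_a,
                 l1_override = l1_override, l2_override = l2_override,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 model_id = model_id),
            class = "ae_config")
}

# Effective weight-penalty coefficients for a config.
ae_penalties <- function(config) {
  list(l1 = if (is.null(config$l1_override)) config$alpha_w else config$l1_override,
       l2 = if (is.null(config$l2_override)) 0 else config$l2_override,
       aa = config$alpha_a)
}

#' The canonical eight-model bottleneck grid
#'
#' Eight configurations with bottleneck widths 50, 100, 150, 200, 250, 300,
#' 400, 500 and the matching per-model l1/l2 weight-penalty overrides
#' (model_3, the usual winner, uses l1 = 0.001, l2 = 0).
#'
#' @param epochs,seed shared settings applied to every config.
#' @return List of eight [ae_config()] objects named `model_1` ... `model_8`.
#' @export
default_ae_grid <- function(epochs = 10, seed = 1) {
  widths <- c(50, 100, 150, 200, 250, 300, 400, 500)
  l1s <- c(0.001, 1e-5, 0.001, 0.1, 0.1, 0.01, 1e-5, 0)
  l2s <- c(1e-5, 0.1, 0, 1e-4, 0, 0, 0.001, 0)
  grid <- lapply(seq_along(widths), function(i)
    ae_config(bottleneck = widths[i], epochs = epochs,
              l1_override = l1s[i], l2_override = l2s[i],
              seed = sub_seed(seed, paste0("ae_model_", i)),
              model_id = sprintf("model_%d", i)))
  names(grid) <- sprintf("model_%d", seq_along(widths))
  grid
}

#' Initialize the autoencoder
#'
#' Builds the four weight matrices (input -> encoder -> bottleneck ->
#' decoder -> output) with a seeded symmetric uniform scheme scaled by
#' fan-in/fan-out (Glorot) and zero biases.
#'
#' @param input_dim number of input features (>= 1).
#' @param config an [ae_config()].
#' @return A list of class `ae_model`: `W`, `b`, `config`, `input_dim`,
#'   `history` (empty).
#' @export
init_autoencoder <- function(input_dim, config = ae_config()) {
  if (!is_count(input_dim) || input_dim < 1)
    stopf("`input_dim` must be a positive integer")
  h <- config$hidden_sizes
  if (h[2] >= input_dim)
    warnf("bottleneck (%d) is not smaller than the input (%d); over-complete model",
          h[2], input_dim)
  dims <- c(input_dim, h, input_dim)
  W <- vector("list", 4); b <- vector("list", 4)
  with_seed(config$seed, {
    for (i in 1:4) {
      lim <- sqrt(6 / (dims[i] + dims[i + 1]))
      W[[i]] <- matrix(runif(dims[i] * dims[i + 1], -lim, lim),
                       nrow = dims[i])
      b[[i]] <- numeric(dims[i + 1])
    }
  })
  structure(list(W = W, b = b, config = config, input_dim = input_dim,
                 history = numeric(0)),
            class = "ae_model")
}

#' @export
print.ae_model <- function(x, ...) {
  cat(sprintf("<ae_model%s> %d -> [%s] -> %d, %s; %d/%d epochs trained\n",
              if (is.null(x$config$model_id)) ""
              else paste0(" ", x$config$model_id),
              x$input_dim, paste(x$config$hidden_sizes, collapse = ", "),
              x$input_dim, x$config$activation,
              length(x$history), x$config$epochs))
  invisible(x)
}

stack_values <- function(X) {
  v <- if (inherits(X, "omics_stack")) X$values else X
  if (!is.matrix(v)) stopf("expected an omics_stack or numeric matrix")
  v
}

check_unit_range <- function(v) {
  if (min(v) < 0 || max(v) > 1)
    stopf("autoencoder inputs must lie in [0, 1]; run minmax_scale first")
  v
}

# Forward pass. `masks` (list of 3 or NULL) are inverted-dropout masks
# already scaled by 1/(1-p); activations A1..A3 are post-dropout, H1..H3 the
# raw tanh outputs.
ae_forward <- function(model, V, masks = NULL) {
  A <- V; H <- vector("list", 3); Ad <- vector("list", 3)
  for (i in 1:3) {
    Z <- A %*% model$W[[i]]
    Z <- sweep(Z, 2, model$b[[i]], "+")
    H[[i]] <- tanh(Z)
    A <- if (is.null(masks)) H[[i]] else H[[i]] * masks[[i]]
    Ad[[i]] <- A
  }
  Z4 <- sweep(A %*% model$W[[4]], 2, model$b[[4]], "+")
  Xhat <- 1 / (1 + exp(-Z4))
  list(H = H, A = Ad, Xhat = Xhat)
}

ae_eps <- 1e-7

# Total objective on a value matrix: mean-over-samples summed cross-entropy
# + L1/L2 weight penalties + batch-averaged squared-activation penalty over
# all four layer activations.
ae_objective <- function(model, V, fw) {
  pen <- ae_penalties(model$config)
  xh <- pmin(pmax(fw$Xhat, ae_eps), 1 - ae_eps)
  ll <- -sum(V * log(xh) + (1 - V) * log(1 - xh)) / nrow(V)
  wpen <- sum(vapply(model$W, function(w)
    pen$l1 * sum(abs(w)) + pen$l2 * sum(w * w), numeric(1)))
  act <- (sum(fw$A[[1]]^2) + sum(fw$A[[2]]^2) + sum(fw$A[[3]]^2) +
            sum(fw$Xhat^2)) / nrow(V)
  ll + wpen + pen$aa * act
}

#' Penalized autoencoder objective
#'
#' Mean per-sample cross-entropy between input and reconstruction
#' (reconstructions clipped to `[1e-7, 1 - 1e-7]` before the log), plus the
#' L1 (and optional L2) weight penalties and the squared-activation penalty
#' averaged over samples. Dropout is disabled.
#'
#' @param model an [init_autoencoder()] model (trained or not).
#' @param X an `omics_stack` or numeric matrix with values in `[0, 1]`.
#' @return Non-negative scalar loss.
#' @export
ae_loss <- function(model, X) {
  V <- check_unit_range(stack_values(X))
  if (ncol(V) != model$input_dim) stopf("input width %d != model input_dim %d",
                                        ncol(V), model$input_dim)
  ae_objective(model, V, ae_forward(model, V))
}

#' Train the autoencoder
#'
#' Mini-batch Adam on the penalized cross-entropy objective for
#' `config$epochs` epochs, with inverted dropout (rate
#' `config$hidden_dropout`) on the three hidden layers during training only.
#' The mean per-batch objective of each epoch is appended to `history`.
#' The compiled training loop draws all randomness (shuffling, dropout
#' masks) from R's RNG, so training is deterministic under the config seed.
#'
#' @inheritParams ae_loss
#' @return The trained `ae_model`.
#' @export
train_autoencoder <- function(model, X) {
  V <- check_unit_range(stack_values(X))
  cfg <- model$config
  if (ncol(V) != model$input_dim) stopf("input width %d != model input_dim %d",
                                        ncol(V), model$input_dim)
  if (cfg$epochs == 0) return(model)
  pen <- ae_penalties(cfg)
  res <- with_seed(sub_seed(cfg$seed, "train"),
    cpp_train_ae(model$W, model$b, V, cfg$epochs, cfg$hidden_dropout,
                 pen$l1, pen$l2, pen$aa, cfg$learning_rate, cfg$batch_size))
  model$W <- res$W
  model$b <- res$b
  model$history <- c(model$history, res$history)
  model
}

#' Extract bottleneck deep features
#'
#' Forward pass (dropout disabled) up to the middle hidden layer; each
#' bottleneck activation is one "deep feature".
#'
#' @inheritParams ae_loss
#' @return Numeric matrix samples x bottleneck, feature columns named
#'   `DF1`, `DF2`, ...
#' @export
encode <- function(model, X) {
  V <- stack_values(X)
  if (ncol(V) != model$input_dim) stopf("input width %d != model input_dim %d",
                                        ncol(V), model$input_dim)
  fw <- ae_forward(model, V)
  F <- fw$H[[2]]
  dimnames(F) <- list(rownames(V), sprintf("DF%d", seq_len(ncol(F))))
  F
}

#' Reconstruct inputs through the full autoencoder
#'
#' @inheritParams ae_loss
#' @return Numeric matrix of reconstructions in (0, 1), same shape as `X`.
#' @export
reconstruct <- function(model, X) {
  V <- stack_values(X)
  if (ncol(V) != model$input_dim) stopf("input width %d != model input_dim %d",
                                        ncol(V), model$input_dim)
  xh <- ae_forward(model, V)$Xhat
  dimnames(xh) <- dimnames(V)
  xh
}

#' Root-mean-square reconstruction error
#'
#' @inheritParams ae_loss
#' @return `sqrt(mean((X - reconstruction)^2))` over all matrix entries.
#' @export
reconstruction_rmse <- function(model, X) {
  V <- stack_values(X)
  sqrt(mean((V - reconstruct(model, V))^2))
}

#' Train one autoencoder per grid configuration
#'
#' Trains every config in `grid` on the stack and reports the model-grid
#' table (one row per model: hidden sizes, epochs, activation, dropout
#' ratios, l1, l2, model id, reconstruction rmse). The `deep_features` and
#' `mean c-index/SD` columns are left `NA` here and filled by the downstream
#' screening/cross-validation stages.
#'
#' @param X an `omics_stack` (values in `[0, 1]`).
#' @param grid list of [ae_config()]; default [default_ae_grid()].
#' @return List with `models` (trained `ae_model`s), `features` (per-model
#'   deep-feature matrices) and `report` (the grid table).
#' @export
run_model_grid <- function(X, grid = default_ae_grid()) {
  if (length(grid) == 0) stopf("empty model grid")
  V <- check_unit_range(stack_values(X))
  models <- vector("list", length(grid))
  features <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  ids <- names(grid)
  if (is.null(ids)) ids <- sprintf("model_%d", seq_along(grid))
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    if (is.null(cfg$model_id)) cfg$model_id <- ids[i]
    model <- train_autoencoder(init_autoencoder(ncol(V), cfg), V)
    pen <- ae_penalties(cfg)
    models[[i]] <- model
    features[[i]] <- encode(model, V)
    rows[[i]] <- data.frame(
      ae_models = cfg$model_id,
      hidden = sprintf("[%s]", paste(cfg$hidden_sizes, collapse = ", ")),
      epochs = cfg$epochs,
      activation = cfg$activation,
      hidden_dropout_ratios = sprintf("[%s]",
        paste(rep(format(cfg$hidden_dropout), 3), collapse = ", ")),
      l1 = pen$l1, l2 = pen$l2,
      model_ids = cfg$model_id,
      rmse = reconstruction_rmse(model, V),
      deep_features = NA_integer_,
      check.names = FALSE,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  report[["mean c-index/SD"]] <- NA_character_
  names(models) <- names(features) <- ids
  list(models = models, features = features, report = report)
}
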