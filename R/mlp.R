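# Dense feed-forward regressor of recombination efficiency from one-hot
# sequence features. Two ReLU hidden layers by default, linear output,
# mean-squared-error loss, Adam updates, inverted dropout, early stopping on
# validation MSE with best-weight restore. Written as plain matrix algebra:
# the networks here are small (tens of units, thousands of rows) and train
# in seconds on one core.

#' Model configuration
#'
#' @param hidden Integer vector of hidden layer widths.
#' @param dropout Dropout rate applied to hidden activations during
#'   training, in `[0,1)`.
#' @param max_epochs Maximum training epochs.
#' @param patience Early stopping patience (epochs without validation MSE
#'   improvement); the best-validation weights are restored.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling weight initialization, batch
#'   shuffling, and dropout masks.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(64, 32), dropout = 0.2, max_epochs = 100,
                       patience = 10, batch_size = 64, learning_rate = 1e-3,
                       seed = 1) {
  stopifnot(dropout >= 0, dropout < 1, max_epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "mlp_config")
}

init_weights <- function(sizes) {
  # He-uniform initialization per layer
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    fan_in <- sizes[l]
    lim <- sqrt(6 / fan_in)
    W[[l]] <- matrix(runif(fan_in * sizes[l + 1], -lim, lim),
                     fan_in, sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

forward_mlp <- function(params, x, dropout = 0, train = FALSE) {
  nl <- length(params$W)
  a <- x
  acts <- vector("list", nl)
  masks <- vector("list", nl)
  for (l in seq_len(nl)) {
    z <- a %*% params$W[[l]]
    z <- sweep(z, 2, params$b[[l]], "+")
    if (l < nl) {
      a <- pmax(z, 0)
      if (train && dropout > 0) {
        m <- matrix(rbinom(length(a), 1, 1 - dropout), nrow(a), ncol(a))
        a <- a * m / (1 - dropout)
        masks[[l]] <- m
      }
    } else {
      a <- z
    }
    acts[[l]] <- a
  }
  list(out = a[, 1], acts = acts, masks = masks)
}

backward_mlp <- function(params, x, fw, grad_out, dropout = 0) {
  nl <- length(params$W)
  gW <- vector("list", nl); gb <- vector("list", nl)
  delta <- matrix(grad_out, ncol = 1)
  for (l in rev(seq_len(nl))) {
    a_prev <- if (l == 1) x else fw$acts[[l - 1]]
    gW[[l]] <- crossprod(a_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(params$W[[l]])
      act <- fw$acts[[l - 1]]
      delta <- delta * (act > 0)
      if (dropout > 0 && !is.null(fw$masks[[l - 1]])) {
        delta <- delta * fw$masks[[l - 1]] / (1 - dropout)
      }
    }
  }
  list(gW = gW, gb = gb)
}

#' Train the dense efficiency regressor
#'
#' @param x Training one-hot matrix (rows: variants, columns: binary
#'   features).
#' @param y Training targets in `[0,1]`.
#' @param xval,yval Validation set monitored for early stopping.
#' @param config An [mlp_config()].
#' @return Object of class `rss_mlp` with elements `params`, `config`,
#'   `feature_names`, `history` (per-epoch train/validation MSE) and
#'   `best_epoch`.
#' @export
mlp_train <- function(x, y, xval, yval, config = mlp_config()) {
  if (nrow(x) == 0 || nrow(xval) == 0) stop("empty training/validation set")
  if (!identical(colnames(x), colnames(xval))) {
    stop("train and validation feature columns differ")
  }
  if (length(y) != nrow(x) || length(yval) != nrow(xval)) {
    stop("target length mismatch")
  }
  x <- as.matrix(x) * 1.0
  xval <- as.matrix(xval) * 1.0
  set.seed(config$seed)
  sizes <- c(ncol(x), config$hidden, 1L)
  params <- init_weights(sizes)
  nl <- length(params$W)
  mW <- lapply(params$W, function(w) w * 0); vW <- mW
  mb <- lapply(params$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  n <- nrow(x)
  best_val <- Inf; best_params <- params; best_epoch <- 0L; wait <- 0L
  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- x[idx, , drop = FALSE]
      fw <- forward_mlp(params, xb, config$dropout, train = TRUE)
      err <- fw$out - y[idx]
      if (any(!is.finite(err))) {
        stop("NaN loss at epoch ", epoch)
      }
      grad_out <- 2 * err / length(idx)
      gr <- backward_mlp(params, xb, fw, grad_out, config$dropout)
      step <- step + 1
      lr_t <- config$learning_rate *
        sqrt(1 - beta2^step) / (1 - beta1^step)
      for (l in seq_len(nl)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gr$gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gr$gW[[l]]^2
        params$W[[l]] <- params$W[[l]] - lr_t * mW[[l]] / (sqrt(vW[[l]]) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gr$gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gr$gb[[l]]^2
        params$b[[l]] <- params$b[[l]] - lr_t * mb[[l]] / (sqrt(vb[[l]]) + eps)
      }
    }
    train_mse <- mean((forward_mlp(params, x)$out - y)^2)
    val_mse <- mean((forward_mlp(params, xval)$out - yval)^2)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_mse = train_mse,
                                         val_mse = val_mse))
    if (val_mse < best_val - 1e-12) {
      best_val <- val_mse; best_params <- params
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(params = best_params, config = config,
                 feature_names = colnames(x), history = history,
                 best_epoch = best_epoch, best_val_mse = best_val),
            class = "rss_mlp")
}

#' Predict recombination efficiency for encoded variants
#'
#' @param object A trained `rss_mlp`.
#' @param newdata One-hot matrix with exactly the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions (not clipped to `[0,1]`).
#' @export
predict.rss_mlp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata) * 1.0
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$feature_names)) {
    missing <- setdiff(object$feature_names, colnames(newdata))
    extra <- setdiff(colnames(newdata), object$feature_names)
    if (length(missing) + length(extra) > 0 ||
        !identical(colnames(newdata), object$feature_names)) {
      stop("feature mismatch; missing: ",
           paste(missing, collapse = ","), "; extra: ",
           paste(extra, collapse = ","))
    }
  }
  forward_mlp(object$params, newdata)$out
}

#' Regression performance metrics
#'
#' FVAF (fraction of variance accounted for) is `1 - MSE/Var(obs)` with the
#' population variance, so the mean predictor scores exactly 0 and a
#' perfect predictor 1. Spearman uses average ranks for ties.
#'
#' @param pred Predictions.
#' @param obs Observed targets.
#' @return List with `fvaf`, `spearman_rho`, `rmse`, `n`.
#' @export
evaluate_predictions <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(obs) < 2) stop("need at least 2 observations")
  v <- mean((obs - mean(obs))^2)
  if (v == 0) stop("zero variance in observations: FVAF undefined")
  mse <- mean((pred - obs)^2)
  list(fvaf = 1 - mse / v,
       spearman_rho = suppressWarnings(cor(pred, obs, method = "spearman")),
       rmse = sqrt(mse),
       n = length(obs))
}

#' Cross-validate model configurations over stratified rotations
#'
#' Trains one model per rotation for each configuration and summarizes
#' train/validation FVAF and MSE; configurations are compared on mean
#' validation FVAF.
#'
#' @param configs A single [mlp_config()] or list of them.
#' @param rot Result of [stratified_rotations()].
#' @param x One-hot matrix of the complete dataset.
#' @param y Normalized targets.
#' @param n_rotations Optionally restrict to the first few rotations.
#' @return data.frame with one row per (config, rotation) plus attribute
#'   `summary` (per-config means/sds).
#' @export
cross_validate <- function(configs, rot, x, y, n_rotations = NULL) {
  if (inherits(configs, "mlp_config")) configs <- list(configs)
  use <- seq_along(rot$rotations)
  if (!is.null(n_rotations)) use <- use[seq_len(n_rotations)]
  rows <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (r in use) {
      ro <- rot$rotations[[r]]
      fit <- mlp_train(x[ro$train, , drop = FALSE], y[ro$train],
                       x[ro$validation, , drop = FALSE], y[ro$validation],
                       cfg)
      mtr <- evaluate_predictions(
        predict(fit, x[ro$train, , drop = FALSE]), y[ro$train])
      mva <- evaluate_predictions(
        predict(fit, x[ro$validation, , drop = FALSE]), y[ro$validation])
      rows[[length(rows) + 1]] <- data.frame(
        config = ci, rotation = r,
        train_fvaf = mtr$fvaf, train_mse = mtr$rmse^2,
        val_fvaf = mva$fvaf, val_mse = mva$rmse^2)
    }
  }
  res <- do.call(rbind, rows)
  summ <- aggregate(res[c("train_fvaf", "train_mse", "val_fvaf", "val_mse")],
                    by = list(config = res$config),
                    FUN = function(v) c(mean = mean(v), sd = sd(v)))
  attr(res, "summary") <- summ
  res
}

#' Residuals versus replicate-to-replicate variability
#'
#' Compares the model's residual error on the training measurement with the
#' standard deviation of the measured efficiency across experimental
#' replicates, per variant.
#'
#' @param pred Model predictions for every variant.
#' @param replicate_targets Matrix of normalized targets, one column per
#'   replicate (>= 2), rows aligned with `pred`. The first column is the
#'   training replicate.
#' @return List with per-variant `residual`, `abs_residual`, `replicate_sd`,
#'   and `rho_sd_residual`, `rho_sd_abs_residual` Spearman correlations.
#' @export
residual_analysis <- function(pred, replicate_targets) {
  replicate_targets <- as.matrix(replicate_targets)
  if (ncol(replicate_targets) < 2) stop("need at least 2 replicates")
  if (nrow(replicate_targets) != length(pred)) stop("row mismatch")
  resid <- pred - replicate_targets[, 1]
  sds <- apply(replicate_targets, 1, sd)
  list(residual = resid,
       abs_residual = abs(resid),
       replicate_sd = sds,
       rho_sd_residual =
         suppressWarnings(cor(sds, resid, method = "spearman")),
       rho_sd_abs_residual =
         suppressWarnings(cor(sds, abs(resid), method = "spearman")))
}

#' Save/load a trained model as JSON
#'
#' Persists weights, configuration, feature names and training history in a
#' single portable JSON file.
#'
#' @param model A trained `rss_mlp`.
#' @param path File path.
#' @export
save_mlp <- function(model, path) {
  payload <- list(
    feature_names = model$feature_names,
    config = unclass(model$config),
    best_epoch = model$best_epoch,
    W_dims = lapply(model$params$W, dim),
    W_data = lapply(model$params$W, as.vector),
    b = model$params$b,
    history = model$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  nl <- length(p$b)
  W <- lapply(seq_len(nl), function(l) {
    d <- as.integer(unlist(p$W_dims[[l]]))
    matrix(as.numeric(unlist(p$W_data[[l]])), d[1], d[2])
  })
  b <- lapply(seq_len(nl), function(l) as.numeric(unlist(p$b[[l]])))
  cfg_in <- lapply(p$config, unlist)
  cfg <- do.call(mlp_config, cfg_in[c(
    "hidden", "dropout", "max_epochs", "patience", "batch_size",
    "learning_rate", "seed")])
  structure(list(params = list(W = W, b = b), config = cfg,
                 feature_names = as.character(unlist(p$feature_names)),
                 history = p$history,
                 best_epoch = as.integer(p$best_epoch)),
            class = "rss_mlp")
}
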