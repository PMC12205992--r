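# Permutation Shapley attribution. For each sample x, background row b and
# feature permutation pi, features are switched one at a time from the
# background value to the sample value in pi's order; the change in the
# model output at each switch is that feature's marginal contribution. The
# attribution is the average over background rows and permutations.
# Because the walk telescopes from f(b) to f(x), per-row additivity
#   sum_j phi_j + mean_b f(b) = f(x)
# holds exactly for any number of permutations.

#' Permutation Shapley attributions of a prediction model
#'
#' @param model A trained `rss_mlp`, or any function mapping a feature
#'   matrix to a numeric prediction vector.
#' @param x Samples to explain (matrix, columns = binary features).
#' @param background Background feature matrix defining the reference
#'   distribution; defaults to `x` itself. A seeded subsample of at most
#'   `max_background` rows is used.
#' @param n_perm Number of feature permutations per background row; each is
#'   also traversed in reverse (antithetic pairing).
#' @param max_background Cap on background rows.
#' @param seed Integer seed for permutations and background subsampling.
#' @return List of class `rss_shap`: `values` (samples x features
#'   attribution matrix), `base` (mean model prediction over the
#'   background), `pred` (model predictions of `x`), `n_perm`, `seed`.
#' @export
shap_permutation <- function(model, x, background = x, n_perm = 10,
                             max_background = 100, seed = 1) {
  f <- if (is.function(model)) model else function(m) predict(model, m)
  x <- as.matrix(x)
  background <- as.matrix(background)
  if (!identical(colnames(x), colnames(background))) {
    stop("samples and background must share the feature set")
  }
  if (nrow(background) == 0) stop("empty background")
  set.seed(seed)
  if (nrow(background) > max_background) {
    background <- background[sample.int(nrow(background), max_background), ,
                             drop = FALSE]
  }
  n <- nrow(x); p <- ncol(x); m <- nrow(background)
  phi <- matrix(0, n, p, dimnames = list(rownames(x), colnames(x)))
  base_preds <- f(background)
  pred_x <- f(x)
  n_pass <- 0L
  for (b in seq_len(m)) {
    brow <- background[b, ]
    for (kp in seq_len(n_perm)) {
      ord_fwd <- sample.int(p)
      for (ord in list(ord_fwd, rev(ord_fwd))) {
        z <- matrix(rep(brow, each = n), n, p,
                    dimnames = list(NULL, colnames(x)))
        f_prev <- rep(base_preds[b], n)
        for (j in ord) {
          z[, j] <- x[, j]
          f_new <- f(z)
          phi[, j] <- phi[, j] + (f_new - f_prev)
          f_prev <- f_new
        }
        n_pass <- n_pass + 1L
      }
    }
  }
  phi <- phi / (m * 2 * n_perm)
  base <- mean(base_preds)
  add_err <- max(abs(rowSums(phi) + base - pred_x))
  if (add_err > 1e-4) {
    stop("additivity violated (max error ", format(add_err),
         "): implementation bug")
  }
  structure(list(values = phi, base = base, pred = pred_x,
                 n_perm = n_perm, n_background = m, seed = seed),
            class = "rss_shap")
}

#' Per-feature importance as mean absolute attribution
#'
#' @param shap An `rss_shap` object (or bare attribution matrix).
#' @return data.frame with `feature`, `mean_abs_shap`, sorted decreasing;
#'   attribute `global_mean` is the mean over all features and samples.
#' @export
mean_abs_attribution <- function(shap) {
  v <- if (inherits(shap, "rss_shap")) shap$values else as.matrix(shap)
  imp <- colMeans(abs(v))
  out <- data.frame(feature = names(imp), mean_abs_shap = unname(imp))
  out <- out[order(-out$mean_abs_shap), ]
  rownames(out) <- NULL
  attr(out, "global_mean") <- mean(abs(v))
  out
}

#' Cumulative attribution traces (decision paths)
#'
#' For each requested sample, features are ordered by global importance
#' (mean absolute attribution) and the running attribution sum is traced
#' from the base prediction to the model prediction.
#'
#' @param shap An `rss_shap` object.
#' @param sample_ids Row names (or indices) of the samples to trace.
#' @return Long data.frame: `sample`, `step`, `feature`, `shap`,
#'   `cumulative` (starting at the base prediction, ending at the model
#'   prediction).
#' @export
decision_path <- function(shap, sample_ids) {
  v <- shap$values
  if (is.character(sample_ids)) {
    missing <- setdiff(sample_ids, rownames(v))
    if (length(missing) > 0) {
      stop("unknown sample id(s): ", paste(missing, collapse = ","))
    }
    idx <- match(sample_ids, rownames(v))
  } else {
    if (any(sample_ids < 1 | sample_ids > nrow(v))) stop("sample index out of range")
    idx <- sample_ids
  }
  ord <- order(-colMeans(abs(v)))
  rows <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    vals <- v[i, ord]
    data.frame(sample = if (is.character(sample_ids)) sample_ids[k] else
                 as.character(i),
               step = seq_along(vals),
               feature = colnames(v)[ord],
               shap = unname(vals),
               cumulative = shap$base + cumsum(unname(vals)))
  })
  do.call(rbind, rows)
}

#' Write an attribution matrix with its JSON sidecar
#'
#' @param shap An `rss_shap` object.
#' @param tsv_path,json_path Output paths.
#' @export
write_attributions <- function(shap, tsv_path, json_path) {
  df <- data.frame(sequence = rownames(shap$values), shap$values,
                   check.names = FALSE)
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(base_prediction = shap$base,
                            n_perm = shap$n_perm,
                            n_background = shap$n_background,
                            seed = shap$seed),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
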