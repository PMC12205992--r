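# End-to-end orchestration. These runners chain the pipeline stages
# (complete -> normalize -> stratify -> train -> evaluate -> attribute ->
# CRV -> Tm sweep -> effect maps) over a read-count table and emit
# plot-ready TSV/JSON bundles. The numbered scripts under analysis/ are
# thin drivers over these functions.

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(..., collapse = " ")))
}

#' Run the H4-S2 analysis pipeline
#'
#' @param counts Read-count data.frame (sequence, count, optional
#'   replicate); the first replicate is the training measurement.
#' @param out_dir Output directory (created if needed); NULL skips file
#'   output.
#' @param config An [mlp_config()].
#' @param k Folds/rotations for the stratified split.
#' @param shap_background,shap_perm Permutation-attribution budget.
#' @param n_shap_samples Number of variants attributed (seeded subsample;
#'   NULL = all).
#' @param run_tm_sweep Whether to run the 768-regression Tm sweep.
#' @param seed Master seed for stratification, attribution subsampling.
#' @return List with the trained model, metrics, attributions, CRVs, Tm
#'   results and file manifest.
#' @export
run_h4s2 <- function(counts, out_dir = NULL, config = mlp_config(),
                     k = 20, shap_background = 50, shap_perm = 3,
                     n_shap_samples = NULL, run_tm_sweep = TRUE, seed = 1) {
  library <- enumerate_library()
  log_stage("complete", "zero completion against", length(library),
            "variants")
  counts <- counts[intersect(c("sequence", "count", "replicate"),
                             names(counts))]
  reps <- if (!is.null(counts$replicate)) sort(unique(counts$replicate)) else 1
  first <- if (!is.null(counts$replicate))
    counts[counts$replicate == reps[1], ] else counts
  completed <- complete_with_zeros(first, library)
  log_stage("normalize", "dataset-wide min-max")
  normalized <- minmax_normalize(completed, "dataset-wide")
  enc <- one_hot_encode(normalized$sequence)
  y <- normalized$target
  log_stage("stratify", k, "fold rotations")
  rot <- stratified_rotations(y, k = k, seed = seed)
  ro <- rot$rotations[[1]]
  log_stage("train", "architecture", paste(config$hidden, collapse = "x"))
  model <- mlp_train(enc[ro$train, , drop = FALSE], y[ro$train],
                     enc[ro$validation, , drop = FALSE], y[ro$validation],
                     config)
  pred_all <- predict(model, enc)
  names(pred_all) <- normalized$sequence
  metrics <- list(
    train = evaluate_predictions(pred_all[ro$train], y[ro$train]),
    validation = evaluate_predictions(pred_all[ro$validation],
                                      y[ro$validation]),
    test = evaluate_predictions(pred_all[ro$test], y[ro$test]))
  replicate_eval <- NULL
  if (length(reps) > 1) {
    log_stage("replicates", "evaluating on", length(reps) - 1,
              "unseen replicate(s)")
    replicate_eval <- lapply(reps[-1], function(r) {
      tab <- minmax_normalize(
        complete_with_zeros(counts[counts$replicate == r, ], library),
        "dataset-wide")
      evaluate_predictions(pred_all[tab$sequence], tab$target)
    })
    names(replicate_eval) <- paste0("replicate_", reps[-1])
  }
  log_stage("shap", "background", shap_background, "perms", shap_perm)
  set.seed(seed)
  samp_idx <- if (is.null(n_shap_samples) ||
                  n_shap_samples >= nrow(enc)) seq_len(nrow(enc)) else
    sort(sample.int(nrow(enc), n_shap_samples))
  shap <- shap_permutation(model, enc[samp_idx, , drop = FALSE],
                           background = enc, n_perm = shap_perm,
                           max_background = shap_background, seed = seed)
  importance <- mean_abs_attribution(shap)
  log_stage("crv", "all ordered feature pairs")
  crvs <- all_crvs(shap, enc[samp_idx, , drop = FALSE])
  curves <- cumulative_curve(crvs, "feature1")
  tm_cor <- tm_prediction_correlation(pred_all)
  tm_sweep <- NULL
  if (run_tm_sweep) {
    log_stage("tm", "768 alignment regressions")
    tm_sweep <- sweep_kmer_regressions(pred_all)
  }
  log_stage("effects", "point-mutation maps")
  effects <- effect_heatmaps(pred_all, library)
  result <- list(model = model, normalized = normalized, rotation = ro,
                 predictions = pred_all, metrics = metrics,
                 replicate_eval = replicate_eval, shap = shap,
                 importance = importance, crvs = crvs, curves = curves,
                 tm_correlation = tm_cor, tm_sweep = tm_sweep,
                 effects = effects, seed = seed)
  if (!is.null(out_dir)) write_h4s2_outputs(result, out_dir)
  result
}

write_h4s2_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  save_mlp(result$model, f("model.json"))
  write.table(data.frame(sequence = names(result$predictions),
                         prediction = unname(result$predictions)),
              f("predictions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_attributions(result$shap, f("shap_values.tsv"), f("shap_meta.json"))
  write_crvs(result$crvs, f("crv_table.tsv"))
  write.table(result$curves, f("crv_curves.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(result$tm_sweep)) {
    write.table(result$tm_sweep, f("tm_regressions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(make_report(result), f("report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Machine-readable run report
#'
#' @param result Output of [run_h4s2()].
#' @return Nested list (metrics, top features, CRV quadrant census, Tm
#'   aggregates) suitable for JSON serialization.
#' @export
make_report <- function(result) {
  quad <- table(result$crvs$quadrant[!result$crvs$degenerate])
  rep <- list(
    metrics = result$metrics,
    replicate_eval = result$replicate_eval,
    top_features = head(result$importance, 5),
    shap_global_mean = attr(result$importance, "global_mean"),
    crv_quadrant_census = as.list(quad),
    crv_total = sum(!result$crvs$degenerate),
    tm_correlation = result$tm_correlation,
    seed = result$seed)
  if (!is.null(result$tm_sweep)) {
    agg <- attr(result$tm_sweep, "aggregates")
    rep$tm_aggregates <- agg
    rep$tm_negative_slope_fraction <- mean(result$tm_sweep$slope < 0)
  }
  rep
}

#' Run the nonamer-informed pipeline
#'
#' Replicate averaging, dataset-wide normalization, nonamer-informed
#' training, per-group attribution, global-mean rescaling, cross-group KS
#' matrix and candidate flagging; also fits the heptamer-only model on
#' nonamer-wise normalized targets for comparison.
#'
#' @param counts Read-count data.frame with `nonamer` and `replicate`
#'   columns.
#' @param nonamer_seqs Named vector of the 5 variable nonamer bases per
#'   group.
#' @param config An [mlp_config()].
#' @param shap_background,shap_perm Attribution budget.
#' @param ks_threshold Flagging threshold on the KS statistic.
#' @param seed Master seed.
#' @return List with the dataset, model, metrics, per-group rescaled
#'   attributions, KS matrix and flags.
#' @export
run_cnon <- function(counts, nonamer_seqs, config = mlp_config(),
                     shap_background = 50, shap_perm = 3,
                     ks_threshold = 0.20, seed = 1) {
  log_stage("cnon", "assembling dataset")
  ds <- build_cnon_dataset(counts, nonamer_seqs)
  y <- ds$data$target
  rot <- stratified_rotations(y, k = 10, seed = seed)
  ro <- rot$rotations[[1]]
  log_stage("cnon", "training nonamer-informed model")
  model <- mlp_train(ds$encoding[ro$train, , drop = FALSE], y[ro$train],
                     ds$encoding[ro$validation, , drop = FALSE],
                     y[ro$validation], config)
  pred <- predict(model, ds$encoding)
  metrics <- evaluate_predictions(pred, y)
  log_stage("cnon", "attribution per nonamer group")
  # each group is attributed against its own background so H4-S2
  # contributions are measured within the nonamer context (and the
  # estimator noise scales with the group's own activity range)
  groups <- as.character(ds$data$nonamer)
  values <- matrix(NA_real_, nrow(ds$encoding), ncol(ds$encoding),
                   dimnames = dimnames(ds$encoding))
  shap_by_group <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    sh_g <- shap_permutation(model, ds$encoding[sel, , drop = FALSE],
                             background = ds$encoding[sel, , drop = FALSE],
                             n_perm = shap_perm,
                             max_background = shap_background, seed = seed)
    values[sel, ] <- sh_g$values
    shap_by_group[[g]] <- sh_g
  }
  shap <- shap_by_group
  rescaled <- rescale_by_global_mean(values, groups)
  ks <- nonamer_ks_matrix(rescaled)
  flags <- flag_long_distance_candidates(ks, ks_threshold)
  list(dataset = ds, model = model, predictions = pred, metrics = metrics,
       shap = shap, rescaled = rescaled, ks = ks, flags = flags,
       seed = seed)
}
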