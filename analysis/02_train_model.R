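#!/usr/bin/env Rscript
# Train the heptamer/spacer efficiency regressor on the simulated N(H4-S2)
# library: zero completion, dataset-wide min-max normalization, stratified
# 20-fold rotations, a short cross-validation comparison of two
# architectures, final training with early stopping, and evaluation on the
# held-out fold and the unseen replicates.

suppressMessages(library(rsselect))

seed <- 1
data_dir <- "results/data"
out <- "results/h4s2"
if (!file.exists(file.path(data_dir, "h4s2_counts.tsv"))) {
  stop("run analysis/01_simulate_library.R first")
}
counts <- load_read_counts(file.path(data_dir, "h4s2_counts.tsv"))

lib <- enumerate_library()
enc <- one_hot_encode(lib)
norm <- minmax_normalize(complete_with_zeros(counts[counts$replicate == 1, ],
                                             lib))
rot <- stratified_rotations(norm$target, k = 20, seed = seed)

message("cross-validating two architectures on 5 of the 20 rotations")
cv <- cross_validate(list(mlp_config(hidden = c(64, 32), seed = seed),
                          mlp_config(hidden = c(16, 8), seed = seed)),
                     rot, enc, norm$target, n_rotations = 5)
cv_sum <- attr(cv, "summary")
message(sprintf("  64x32: mean validation FVAF %.3f | 16x8: %.3f",
                cv_sum$val_fvaf[1, "mean"], cv_sum$val_fvaf[2, "mean"]))

res <- run_h4s2(counts, out_dir = out, config = mlp_config(seed = seed),
                k = 20, shap_background = 40, shap_perm = 2,
                n_shap_samples = 512, run_tm_sweep = FALSE, seed = seed)
for (s in c("train", "validation", "test")) {
  m <- res$metrics[[s]]
  message(sprintf("  %-10s FVAF %.3f  rho %.3f  RMSE %.4f (n=%d)",
                  s, m$fvaf, m$spearman_rho, m$rmse, m$n))
}
for (r in names(res$replicate_eval)) {
  m <- res$replicate_eval[[r]]
  message(sprintf("  %-10s FVAF %.3f  RMSE %.4f (unseen)", r, m$fvaf,
                  m$rmse))
}

# residual error against replicate-to-replicate variability
targets <- sapply(1:3, function(r) {
  minmax_normalize(complete_with_zeros(counts[counts$replicate == r, ],
                                       lib))$target
})
ra <- residual_analysis(res$predictions, targets)
message(sprintf("  rho(replicate sd, residual)  = %+.3f", ra$rho_sd_residual))
message(sprintf("  rho(replicate sd, |residual|) = %+.3f",
                ra$rho_sd_abs_residual))
write.table(data.frame(sequence = norm$sequence,
                       residual = ra$residual,
                       replicate_sd = ra$replicate_sd),
            file.path(out, "residuals.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cv, file.path(out, "crossval.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote ", out)
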