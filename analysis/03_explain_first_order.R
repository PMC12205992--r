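#!/usr/bin/env Rscript
# First-order explanation of the trained model: permutation Shapley values
# for a seeded sample of the library, per-feature importance, and
# base-to-prediction decision paths for the strongest and weakest
# predicted variants.

suppressMessages(library(rsselect))

seed <- 1
out <- "results/h4s2"
if (!file.exists(file.path(out, "model.json"))) {
  stop("run analysis/02_train_model.R first")
}
model <- load_mlp(file.path(out, "model.json"))
lib <- enumerate_library()
enc <- one_hot_encode(lib)

set.seed(seed)
samp <- sort(sample.int(nrow(enc), 512))
shap <- shap_permutation(model, enc[samp, ], background = enc,
                         n_perm = 2, max_background = 40, seed = seed)
write_attributions(shap, file.path(out, "shap_values.tsv"),
                   file.path(out, "shap_meta.json"))

imp <- mean_abs_attribution(shap)
write.table(imp, file.path(out, "feature_importance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("top features by mean |SHAP|:")
for (i in 1:6) {
  message(sprintf("  %-5s %.4f", imp$feature[i], imp$mean_abs_shap[i]))
}
message(sprintf("global mean |SHAP| = %.4f", attr(imp, "global_mean")))

pred <- predict(model, enc[samp, ])
extremes <- rownames(enc[samp, ])[c(which.max(pred), which.min(pred))]
paths <- decision_path(shap, extremes)
write.table(paths, file.path(out, "decision_paths.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("decision paths for ", paste(extremes, collapse = " and "),
        " written")
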