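#!/usr/bin/env Rscript
# Nonamer-informed analysis on the three-group N(H4-H7)K(S2) libraries:
# replicate averaging, zero completion, dataset-wide normalization,
# training the 44-bit nonamer-informed model, per-group attribution,
# global-mean rescaling, cross-group KS comparison and candidate flags for
# long-distance heptamer-nonamer interactions.

suppressMessages(library(rsselect))

seed <- 1
data_dir <- "results/data"
out <- "results/cnon"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
if (!file.exists(file.path(data_dir, "cnon_counts.tsv"))) {
  stop("run analysis/01_simulate_library.R first")
}
counts <- load_read_counts(file.path(data_dir, "cnon_counts.tsv"))
nonamer_tab <- read.delim(file.path(data_dir, "nonamer_sequences.tsv"))
nonamers <- setNames(nonamer_tab$nonamer_bases, nonamer_tab$group)

res <- run_cnon(counts, nonamers,
                config = mlp_config(hidden = c(48, 24), max_epochs = 150,
                                    batch_size = 32, learning_rate = 3e-3,
                                    dropout = 0, seed = seed),
                shap_background = 24, shap_perm = 2, seed = seed)
message(sprintf("nonamer-informed model FVAF %.3f over %d variants",
                res$metrics$fvaf, nrow(res$dataset$data)))
message("per-group attribution scale (global mean |SHAP|):")
for (g in names(res$rescaled$divisors)) {
  message(sprintf("  %-5s %.5f", g, res$rescaled$divisors[[g]]))
}

write.table(res$ks, file.path(out, "ks_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$flags, file.path(out, "candidate_flags.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
if (nrow(res$flags) == 0) {
  message("no KS >= 0.20 candidates: the groups differ only by global scale")
} else {
  message(nrow(res$flags), " candidate feature(s) with KS >= 0.20:")
  for (i in seq_len(nrow(res$flags))) {
    message(sprintf("  %-5s max KS %.3f (%s)", res$flags$feature[i],
                    res$flags$max_statistic[i], res$flags$pairs_above[i]))
  }
  message("note: these groups were simulated as scale-only, so candidates")
  message("here measure how much model-fit error distorts the rescaled")
  message("attribution shapes (an exact model yields zero flags; see the")
  message("methods vignette)")
}

# heptamer-only model on nonamer-wise normalized targets for comparison:
# if the nonamer acts as a pure global scale, group-wise rescaling should
# recover most of the nonamer-informed model's accuracy
avg <- average_replicates(counts)
lib_k <- as.character(enumerate_library(
  H4S2_POSITIONS, c(rep(list(BASE_LEX), 4), list("A"), list(c("G", "T")))))
comp <- complete_with_zeros(avg, lib_k)
nw <- minmax_normalize(comp, "nonamer-wise")
enc_h <- one_hot_encode(nw$sequence)
rot <- stratified_rotations(nw$target, k = 10, seed = seed)
ro <- rot$rotations[[1]]
mh <- mlp_train(enc_h[ro$train, ], nw$target[ro$train],
                enc_h[ro$validation, ], nw$target[ro$validation],
                mlp_config(hidden = c(48, 24), max_epochs = 150,
                           batch_size = 32, learning_rate = 3e-3,
                           dropout = 0, seed = seed))
ev <- evaluate_predictions(predict(mh, enc_h), nw$target)
message(sprintf(
  "heptamer-only model on nonamer-wise targets: FVAF %.3f (gap %.3f)",
  ev$fvaf, res$metrics$fvaf - ev$fvaf))
message("wrote ", out)
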