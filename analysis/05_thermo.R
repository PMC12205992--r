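#!/usr/bin/env Rscript
# Melting-temperature analysis of the H4-S2 duplex: nearest-neighbor Tm for
# all 4096 variants, correlation with the model prediction, and the
# 768-regression 4-mer alignment sweep (256 4-mers x alignments -1/0/+1,
# log10 prediction on Tm over the 16 matching sequences each).

suppressMessages(library(rsselect))

out <- "results/h4s2"
if (!file.exists(file.path(out, "predictions.tsv"))) {
  stop("run analysis/02_train_model.R first")
}
pred_df <- read.delim(file.path(out, "predictions.tsv"))
pred <- setNames(pred_df$prediction, pred_df$sequence)

tm <- duplex_tm(names(pred))
write.table(data.frame(sequence = names(pred), tm_celsius = tm),
            file.path(out, "melting_temperatures.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

usable <- pred[pred > 0]
cor_res <- tm_prediction_correlation(usable)
message(sprintf(
  "Tm vs prediction: Spearman %.3f, Pearson (log10) %.3f (n=%d, %d excluded)",
  cor_res$spearman_rho, cor_res$pearson_r_log, cor_res$n_used,
  cor_res$n_excluded))

# regressions need predictions for the complete library; shift nonpositive
# outputs just above zero so every alignment set keeps its 16 members
floor_val <- min(usable) / 2
pred_pos <- pmax(pred, floor_val)
sweep <- sweep_kmer_regressions(pred_pos)
write.table(sweep, file.path(out, "tm_regressions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
agg <- attr(sweep, "aggregates")
write.table(agg, file.path(out, "tm_regression_aggregates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("per-alignment aggregates over 768 regressions:")
for (i in seq_len(nrow(agg))) {
  message(sprintf(
    "  alignment %2s: mean slope %+.4f, mean R2 %.3f, %.0f%% negative",
    agg$alignment[i], agg$mean_slope[i], agg$mean_r_squared[i],
    100 * agg$frac_negative_slope[i]))
}
plus1 <- sweep[sweep$alignment == "+1", ]
message(sprintf(
  "+1 alignment: mean R2 %.3f with G at H6, %.3f without",
  mean(plus1$r_squared[plus1$has_G_at_H6]),
  mean(plus1$r_squared[!plus1$has_G_at_H6])))
message("wrote ", out)
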