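#!/usr/bin/env Rscript
# Second-order analysis: cooperative relationship vectors for every ordered
# feature pair and binary-encoding combination, the cumulative
# length-angle curves per feature, quadrant census, and per-position
# nucleotide groupings by curve covariation (as IUPAC codes).

suppressMessages(library(rsselect))

seed <- 1
out <- "results/h4s2"
shap_tsv <- file.path(out, "shap_values.tsv")
if (!file.exists(shap_tsv)) {
  stop("run analysis/03_explain_first_order.R first")
}
shap_df <- read.delim(shap_tsv, check.names = FALSE)
values <- as.matrix(shap_df[, -1])
rownames(values) <- shap_df$sequence
enc <- one_hot_encode(shap_df$sequence)

crvs <- all_crvs(values, enc)
write_crvs(crvs, file.path(out, "crv_table.tsv"))
live <- crvs[!crvs$degenerate, ]
census <- table(live$quadrant)
message("CRV quadrant census (", nrow(live), " vectors):")
for (q in names(census)) message(sprintf("  %-5s %d", q, census[[q]]))
message(sprintf("longest CRV: %s vs %s combo %s, length %.4f at %.1f deg",
                live$feature1[which.max(live$length)],
                live$feature2[which.max(live$length)],
                live$combo[which.max(live$length)],
                max(live$length), live$angle_deg[which.max(live$length)]))

curves <- cumulative_curve(crvs, "feature1")
write.table(curves, file.path(out, "crv_curves.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("per-position nucleotide groupings from curve covariation:")
groups <- list()
for (pos in H4S2_POSITIONS) {
  pos_curves <- curves[sub("_.*", "", curves$group) == pos, ]
  gr <- covariation_groups(pos_curves, threshold = 0.2)
  groups[[pos]] <- gr$codes
  message(sprintf("  %s: %s", pos, paste(gr$codes, collapse = "/")))
}
jsonlite::write_json(groups, file.path(out, "crv_groupings.json"),
                     auto_unbox = TRUE)
message("wrote ", out)
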