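#!/usr/bin/env Rscript
# Generate the synthetic SARP-seq datasets the downstream analyses run on:
# three replicates of the fully randomized N(H4-S2) library (4096
# variants), plus three nonamer-group N(H4-H7)K(S2) libraries (512 variants
# each) with multiplicative nonamer scaling, emulating a canonical nonamer
# and two cryptic ones. The generator truth is serialized alongside so
# every later stage can be checked against known ground truth.

suppressMessages(library(rsselect))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("H4-S2 library: additive + pairwise truth, 3 replicates")
truth <- make_truth(seed = seed)
sim <- simulate_counts(truth, replicates = 3, seed = seed)
write_read_counts(sim, file.path(out, "h4s2_counts.tsv"))
write_truth(truth, file.path(out, "h4s2_truth.json"))

lib <- enumerate_library()
comp <- summarize_distribution(complete_with_zeros(sim[sim$replicate == 1, ],
                                                   lib))
message(sprintf("replicate 1 composition: %d%% >=10 reads, %d%% 1-9, %d%% zero",
                comp$pct_at_or_above, comp$pct_below, comp$pct_zero))

message("cryptic-nonamer libraries: scales 1 / 0.6 / 0.25, replicates 3/2/2")
truth_n <- make_truth(nonamer_scales = c(CF1 = 1, Pax3 = 0.6, LMO2 = 0.25),
                      seed = seed)
sim_n <- simulate_counts(truth_n,
                         replicates = c(CF1 = 3, Pax3 = 2, LMO2 = 2),
                         depth = 5000, dispersion = 1e5, zero_target = 0,
                         seed = seed)
# restrict to the K(S2) design: S1 fixed to A, S2 in {G,T}
sim_n <- sim_n[substr(sim_n$sequence, 5, 5) == "A" &
                 substr(sim_n$sequence, 6, 6) %in% c("G", "T"), ]
write_read_counts(sim_n, file.path(out, "cnon_counts.tsv"))
write_truth(truth_n, file.path(out, "cnon_truth.json"))
writeLines(c("group\tnonamer_bases",
             "CF1\tACAAC", "Pax3\tGTCAC", "LMO2\tTGGGG"),
           file.path(out, "nonamer_sequences.tsv"))

message("wrote ", out)
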