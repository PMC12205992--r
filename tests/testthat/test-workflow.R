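# Reduced-size end-to-end runs: small attribution budgets and epoch counts
# keep the smoke tests fast while touching every pipeline stage.

test_that("the heptamer/spacer pipeline runs end to end and is reproducible", {
  truth <- make_truth(seed = 17)
  sim <- simulate_counts(truth, replicates = 2, seed = 17)
  cfg <- mlp_config(hidden = c(16, 8), max_epochs = 15, seed = 3)
  out_dir <- withr::local_tempdir()
  res <- suppressMessages(
    run_h4s2(sim, out_dir = out_dir, config = cfg, k = 10,
             shap_background = 10, shap_perm = 1, n_shap_samples = 48,
             run_tm_sweep = FALSE, seed = 3))
  expect_s3_class(res$model, "rss_mlp")
  expect_length(res$predictions, 4096)
  expect_true(all(c("train", "validation", "test") %in% names(res$metrics)))
  expect_identical(nrow(res$shap$values), 48L)
  expect_identical(names(res$replicate_eval), "replicate_2")
  expect_true(file.exists(file.path(out_dir, "model.json")))
  expect_true(file.exists(file.path(out_dir, "crv_table.tsv")))
  expect_true(file.exists(file.path(out_dir, "report.json")))

  # rerun with the same config and seed gives identical metrics
  res2 <- suppressMessages(
    run_h4s2(sim, out_dir = NULL, config = cfg, k = 10,
             shap_background = 10, shap_perm = 1, n_shap_samples = 48,
             run_tm_sweep = FALSE, seed = 3))
  expect_equal(res2$metrics, res$metrics, tolerance = 1e-12)
  expect_identical(res2$shap$values, res$shap$values)
})

test_that("the run report conserves the CRV census", {
  truth <- make_truth(seed = 19)
  sim <- simulate_counts(truth, seed = 19)
  res <- suppressMessages(
    run_h4s2(sim, out_dir = NULL, config = mlp_config(hidden = c(8),
                                                      max_epochs = 8,
                                                      seed = 2),
             k = 10, shap_background = 8, shap_perm = 1,
             n_shap_samples = 32, run_tm_sweep = FALSE, seed = 2))
  rep <- make_report(res)
  expect_identical(sum(unlist(rep$crv_quadrant_census)),
                   rep$crv_total)
  expect_identical(rep$crv_total, sum(!res$crvs$degenerate))
  expect_true(is.finite(rep$shap_global_mean))
})

# Attribution -> rescale -> KS -> flag chain for a given predictor over the
# nonamer-informed encoding, each group against its own background.
cnon_flag_chain <- function(predictor, ds, seed = 4) {
  groups <- as.character(ds$data$nonamer)
  values <- matrix(NA_real_, nrow(ds$encoding), ncol(ds$encoding),
                   dimnames = dimnames(ds$encoding))
  for (g in unique(groups)) {
    sel <- groups == g
    sh <- shap_permutation(predictor, ds$encoding[sel, , drop = FALSE],
                           background = ds$encoding[sel, , drop = FALSE],
                           n_perm = 2, max_background = 24, seed = seed)
    values[sel, ] <- sh$values
  }
  ks <- nonamer_ks_matrix(rescale_by_global_mean(values, groups))
  flag_long_distance_candidates(ks, 0.20)
}

test_that("scale-only groups flag nothing; group-specific terms are flagged", {
  truth <- make_truth(nonamer_scales = c(CF1 = 1, Pax3 = 0.6, LMO2 = 0.25),
                      seed = 23)
  sim <- simulate_counts(truth, replicates = 1, depth = 5000,
                         dispersion = 1e5, zero_target = 0, seed = 23)
  sim <- sim[substr(sim$sequence, 5, 5) == "A" &
               substr(sim$sequence, 6, 6) %in% c("G", "T"), ]
  nonamers <- c(CF1 = "ACAAC", Pax3 = "GTCAC", LMO2 = "TGGGG")
  ds <- build_cnon_dataset(sim, nonamers)
  group_of <- setNames(as.character(ds$data$nonamer),
                       rownames(ds$encoding))
  scale_of <- c(CF1 = 1, Pax3 = 0.6, LMO2 = 0.25)
  latent_of <- function(m) {
    h <- m[, names(truth$beta), drop = FALSE] %*% truth$beta +
      truth$intercept
    for (i in seq_len(nrow(truth$pairwise))) {
      h <- h + truth$pairwise$delta[i] *
        m[, truth$pairwise$f1[i]] * m[, truth$pairwise$f2[i]]
    }
    as.vector(h)
  }
  # nonamer group recognized from the N1 block bits of each input row
  nona_enc <- one_hot_encode(unname(nonamers), NONAMER_POSITIONS)
  rownames(nona_enc) <- names(nonamers)
  group_from_bits <- function(m) {
    scores <- m[, colnames(nona_enc), drop = FALSE] %*% t(nona_enc)
    names(nonamers)[max.col(scores, ties.method = "first")]
  }

  # pure global scaling: the flag list is empty
  f_scaled <- function(m) {
    unname(scale_of[group_from_bits(m)]) * plogis(latent_of(m))
  }
  flags0 <- cnon_flag_chain(f_scaled, ds)
  expect_identical(nrow(flags0), 0L)

  # a heptamer term active in one group only: that feature is flagged,
  # with every exceeding pair involving the deviant group
  f_specific <- function(m) {
    extra <- ifelse(group_from_bits(m) == "LMO2", 2.5 * m[, "H4_T"], 0)
    unname(scale_of[group_from_bits(m)]) * plogis(latent_of(m) + extra)
  }
  flags1 <- cnon_flag_chain(f_specific, ds)
  expect_true("H4_T" %in% flags1$feature)
  pairs <- strsplit(flags1$pairs_above[flags1$feature == "H4_T"], ",")[[1]]
  expect_true(all(grepl("LMO2", pairs)))
})

test_that("the trained nonamer-informed pipeline reports all components", {
  truth <- make_truth(nonamer_scales = c(CF1 = 1, Pax3 = 0.6, LMO2 = 0.25),
                      seed = 23)
  sim <- simulate_counts(truth, replicates = c(CF1 = 3, Pax3 = 2, LMO2 = 2),
                         depth = 5000, dispersion = 1e5, zero_target = 0,
                         seed = 23)
  sim <- sim[substr(sim$sequence, 5, 5) == "A" &
               substr(sim$sequence, 6, 6) %in% c("G", "T"), ]
  res <- suppressMessages(
    run_cnon(sim, c(CF1 = "ACAAC", Pax3 = "GTCAC", LMO2 = "TGGGG"),
             config = mlp_config(hidden = c(48, 24), max_epochs = 150,
                                 batch_size = 32, learning_rate = 3e-3,
                                 dropout = 0, seed = 4),
             shap_background = 16, shap_perm = 1, seed = 4))
  expect_identical(nrow(res$dataset$data), 1536L)
  expect_identical(ncol(res$dataset$encoding), 44L)
  expect_identical(nrow(res$ks), 24L * 3L)
  expect_gt(res$metrics$fvaf, 0.99)
  # per-group attribution scale follows the planted nonamer ordering
  d <- res$rescaled$divisors
  expect_gt(d[["CF1"]], d[["Pax3"]])
  expect_gt(d[["Pax3"]], d[["LMO2"]])
})
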