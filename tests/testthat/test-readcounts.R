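test_that("read-count tables load, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tcount", "ACGTAC\t10", "AAAAAA\t0", "TTTTTT\t3"),
             path)
  tab <- load_read_counts(path)
  expect_identical(tab$sequence, c("ACGTAC", "AAAAAA", "TTTTTT"))
  expect_identical(tab$count, c(10, 0, 3))

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence,count,replicate", "ACGTAC,7,r1"), csv)
  expect_identical(load_read_counts(csv)$replicate, "r1")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tcount", "ACGTAC\t-1"), bad)
  expect_error(load_read_counts(bad), "nonnegative")
  writeLines(c("sequence\tcount", "ACGXAC\t1"), bad)
  expect_error(load_read_counts(bad), "non-ACGT")

  # full-library round trip is bit-identical
  lib <- enumerate_library()
  set.seed(9)
  full <- data.frame(sequence = as.character(lib),
                     count = as.numeric(rpois(4096, 5)))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_read_counts(full, out)
  expect_identical(load_read_counts(out), full)
})

test_that("zero completion restores the full library and is idempotent", {
  lib <- enumerate_library(c("H4", "H5", "H6", "H7", "S2"),
                           list(H4 = c("A", "C", "G", "T"),
                                H5 = c("A", "C", "G", "T"),
                                H6 = c("A", "C", "G", "T"),
                                H7 = c("A", "C", "G", "T"),
                                S2 = c("G", "T")))
  expect_length(lib, 512)
  set.seed(4)
  observed <- data.frame(sequence = sample(as.character(lib), 500),
                         count = rpois(500, 20) + 1)
  comp <- complete_with_zeros(observed, lib)
  expect_identical(nrow(comp), 512L)
  expect_identical(sum(comp$count == 0), 12L)
  expect_identical(comp$sequence, as.character(lib))
  expect_identical(complete_with_zeros(comp, lib), comp)
  expect_error(
    complete_with_zeros(data.frame(sequence = "AAAAAA", count = 1), lib),
    "outside the library")
})

test_that("replicate averaging is group-wise and preserves group sizes", {
  expect_identical(
    average_replicates(list(
      data.frame(sequence = "ACGTAC", count = 10),
      data.frame(sequence = "ACGTAC", count = 20)))$count, 15)
  one <- data.frame(sequence = c("AA", "CC"), count = c(3, 4))
  expect_identical(average_replicates(list(one))$count, c(3, 4))

  # three CF1 replicates, two Pax3, two LMO2
  make_rep <- function(g, r, offset) {
    data.frame(sequence = c("AAAA", "CCCC"), count = c(1, 2) + offset,
               replicate = r, nonamer = g)
  }
  tabs <- rbind(make_rep("CF1", 1, 0), make_rep("CF1", 2, 1),
                make_rep("CF1", 3, 2), make_rep("Pax3", 1, 0),
                make_rep("Pax3", 2, 2), make_rep("LMO2", 1, 0),
                make_rep("LMO2", 2, 4))
  avg <- average_replicates(tabs)
  expect_identical(nrow(avg), 6L)  # 2 variants x 3 groups
  expect_identical(avg$count[avg$nonamer == "CF1" &
                             avg$sequence == "AAAA"], 2)  # mean(1,2,3)
  expect_identical(avg$count[avg$nonamer == "LMO2" &
                             avg$sequence == "CCCC"], 4)  # mean(2,6)

  expect_error(average_replicates(rbind(
    data.frame(sequence = "AAAA", count = 1, replicate = 1),
    data.frame(sequence = c("AAAA", "CCCC"), count = c(1, 2),
               replicate = 2))), "mismatched")
})

test_that("min-max normalization rescales per group", {
  t1 <- minmax_normalize(data.frame(sequence = c("A", "C", "G"),
                                    count = c(0, 5, 10)))
  expect_equal(t1$target, c(0, 0.5, 1))

  two <- data.frame(sequence = rep(c("A", "C"), 2),
                    count = c(0, 40, 0, 10),
                    nonamer = rep(c("g1", "g2"), each = 2))
  ds <- minmax_normalize(two, "dataset-wide")
  expect_equal(max(ds$target[ds$nonamer == "g2"]), 0.25)
  nw <- minmax_normalize(two, "nonamer-wise")
  expect_equal(as.numeric(tapply(nw$target, nw$nonamer, max)), c(1, 1))

  expect_warning(
    const <- minmax_normalize(data.frame(sequence = c("A", "C"),
                                         count = c(5, 5))),
    "constant")
  expect_equal(const$target, c(0, 0))
  # monotone: ranks preserved
  set.seed(2)
  tb <- data.frame(sequence = paste0("s", 1:50), count = rpois(50, 30))
  nm <- minmax_normalize(tb)
  expect_identical(rank(nm$target), rank(nm$count))
})

test_that("distribution summary recovers planted composition", {
  all_zero <- data.frame(sequence = c("A", "C"), count = c(0, 0))
  s <- summarize_distribution(all_zero)
  expect_identical(c(s$pct_at_or_above, s$pct_below, s$pct_zero),
                   c(0, 0, 100))

  # planted composition: 35 high, 21 low, 44 zero out of 100
  planted <- data.frame(
    sequence = paste0("s", 1:100),
    count = c(rep(50, 35), rep(5, 21), rep(0, 44)))
  s <- summarize_distribution(planted)
  expect_identical(c(s$pct_at_or_above, s$pct_below, s$pct_zero),
                   c(35, 21, 44))
  expect_error(summarize_distribution(planted[0, ]), "empty")
})

test_that("stratified rotations partition folds with matched distributions", {
  lib <- enumerate_library()
  set.seed(7)
  truth <- make_truth(seed = 2)
  sim <- simulate_counts(truth, seed = 2)
  norm <- minmax_normalize(complete_with_zeros(sim, lib))
  rot <- stratified_rotations(norm$target, k = 20, seed = 5)
  expect_length(rot$rotations, 20)
  expect_true(all(rot$fold %in% 1:20))

  val_seen <- integer(0); test_seen <- integer(0)
  for (r in seq_len(20)) {
    ro <- rot$rotations[[r]]
    # partition of the dataset
    expect_identical(sort(c(ro$train, ro$validation, ro$test)),
                     seq_len(4096))
    val_seen <- c(val_seen, unique(rot$fold[ro$validation]))
    test_seen <- c(test_seen, unique(rot$fold[ro$test]))
  }
  # each fold exactly once as validation and once as test
  expect_identical(sort(val_seen), 1:20)
  expect_identical(sort(test_seen), 1:20)

  # per-bin fold sizes differ by at most 1 (overall sizes nearly equal)
  expect_lte(diff(range(table(rot$fold))), 10L)

  # stratification: each subset shares the full distribution (high KS p)
  ro <- rot$rotations[[1]]
  for (part in c("train", "validation", "test")) {
    ks <- ks_two_sample(norm$target[ro[[part]]], norm$target)
    expect_gt(ks$p_value, 0.9)
  }

  expect_error(stratified_rotations(norm$target, k = 2), "k must be")
})

test_that("two-sample KS statistic hits its extremes", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(x, x + 100)$statistic, 1)
  expect_error(ks_two_sample(numeric(0), x), "empty")
})
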