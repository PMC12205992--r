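test_that("point-mutation effects recover planted additive differences", {
  lib <- enumerate_library()
  flat <- setNames(rep(0.4, 4096), as.character(lib))
  pm <- point_mutation_effect(flat, lib, "H4", "A", "T")
  expect_equal(pm$effect, 0)
  expect_identical(pm$n_from, 1024L)
  expect_identical(pm$n_to, 1024L)

  truth <- make_truth(pairwise = NULL, seed = 6)
  oracle <- truth_oracle(truth)
  latent <- setNames(oracle$latent, oracle$sequence)
  for (pos in c("H4", "H6", "S2")) {
    for (to in c("T", "G")) {
      pm <- point_mutation_effect(latent, lib, pos, "A", to)
      planted <- unname(truth$beta[paste0(pos, "_", to)] -
                        truth$beta[paste0(pos, "_A")])
      expect_equal(pm$effect, planted, tolerance = 1e-9)
    }
  }
  expect_error(point_mutation_effect(latent[1:100], lib, "H4", "A", "T"),
               "missing")
})

test_that("effect heatmaps are antisymmetric with zero diagonals", {
  lib <- enumerate_library()
  truth <- make_truth(seed = 7)
  oracle <- truth_oracle(truth)
  scores <- setNames(oracle$efficiency, oracle$sequence)
  maps <- effect_heatmaps(scores, lib)
  expect_identical(names(maps), H4S2_POSITIONS)
  for (m in maps) {
    expect_identical(dim(m), c(4L, 4L))
    expect_equal(unname(diag(m)), rep(0, 4))
    expect_equal(m, -t(m), tolerance = 1e-12, ignore_attr = TRUE)
  }

  reduced <- effect_heatmaps(scores, lib, scheme = CRV_REFERENCE_GROUPS)
  expect_identical(dim(reduced$H6), c(3L, 3L))  # R/T/C
  expect_identical(dim(reduced$H4), c(2L, 2L))  # D/C
  expect_equal(unname(diag(reduced$S2)), rep(0, 3))
  expect_error(
    effect_heatmaps(scores, lib, scheme = list(H4 = c("R", "S"))),
    "partition")
})

test_that("score correlation handles transforms and degenerate input", {
  lib <- enumerate_library(c("H4", "H5", "H6"))
  set.seed(3)
  a <- setNames(runif(64, 0.01, 1), as.character(lib))
  res <- correlate_scores(a, a)
  expect_equal(res$spearman_rho, 1)
  expect_equal(res$pearson_r, 1)
  anti <- correlate_scores(a, setNames(-a, names(a)))
  expect_equal(anti$spearman_rho, -1)

  # symmetric in rho without transform
  b <- setNames(runif(64), names(a))
  expect_equal(correlate_scores(a, b)$spearman_rho,
               correlate_scores(b, a)$spearman_rho)

  # log transform linearizes an exponential relationship
  c_scores <- setNames(10^(seq(-3, 0, length.out = 64)), names(a))
  d_scores <- setNames(seq(-30, -10, length.out = 64), names(a))
  lg <- correlate_scores(c_scores, d_scores, transform = "log10_on_a")
  expect_equal(lg$pearson_r, 1, tolerance = 1e-9)
  expect_error(correlate_scores(a[1:2], a[1:2]), "3 shared")
})

test_that("striation sampling isolates equal-x groups", {
  xs <- setNames(c(rep(-20, 5), rep(-30, 4), -10),
                 paste0("S", 1:10))
  ys <- setNames(c(0.1, 0.9, 0.5, 0.3, 0.7, rep(0.2, 4), 0.4),
                 names(xs))
  rep1 <- striation_sample(xs, ys, centers = c(-20, -25), half_width = 0.5)
  expect_identical(rep1[[1]]$n, 5L)
  expect_equal(unname(rep1[[1]]$y_range), c(0.1, 0.9))
  expect_identical(unname(rep1[[1]]$top_sequence), "S2")
  expect_identical(rep1[[2]]$n, 0L)  # empty striation flagged, not fatal

  # half_width 0 with an exact center: singleton, zero y range
  rep2 <- striation_sample(xs, ys, centers = -10, half_width = 0)
  expect_identical(rep2[[1]]$n, 1L)
  expect_equal(diff(rep2[[1]]$y_range), 0)
})

test_that("position frequency matrices count bases per column", {
  pfm1 <- position_frequency_matrix("ACGTAC")
  expect_identical(colnames(pfm1), H4S2_POSITIONS)
  expect_true(all(colSums(pfm1) == 1))
  expect_identical(pfm1["A", "H4"], 1L)

  lib <- enumerate_library()
  pfm <- position_frequency_matrix(as.character(lib))
  expect_true(all(pfm == 1024))
  expect_true(all(colSums(pfm) == 4096))
  expect_error(position_frequency_matrix(c("AC", "ACG")), "share")
})

test_that("external score tables load as named vectors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tscore", "ACGTAC\t-17.2", "AAAAAA\t-38.9"), path)
  sc <- read_score_table(path)
  expect_equal(unname(sc), c(-17.2, -38.9))
  expect_identical(names(sc), c("ACGTAC", "AAAAAA"))
  # shipped functional threshold constant sits between them
  expect_true(sc["ACGTAC"] > RIC_FUNCTIONAL_THRESHOLD)
  expect_true(sc["AAAAAA"] < RIC_FUNCTIONAL_THRESHOLD)
})
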