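test_that("mode partition matches one-hot combinatorics", {
  lib <- enumerate_library()
  enc <- one_hot_encode(lib)
  modes <- partition_modes(enc, "H4_A", "H5_T")
  expect_identical(lengths(modes)[c("00", "01", "10", "11")],
                   c("00" = 2304L, "01" = 768L, "10" = 768L, "11" = 256L))
  expect_identical(sort(unname(unlist(modes))), seq_len(4096))

  same_pos <- partition_modes(enc, "H4_A", "H4_T")
  expect_length(same_pos[["11"]], 0)
  expect_error(partition_modes(enc, "H4_A", "H4_A"), "differ")
  expect_error(partition_modes(enc, "H4_A", "XX_Z"), "unknown feature")
})

test_that("CRV geometry follows the length/angle definitions", {
  # x99 = 3, y99 = 4 -> length 5 (values constant within the mode)
  pts <- cbind(rep(3, 50), rep(4, 50)) + cbind(rnorm(50, 0, 1e-9), 0)
  rec <- fit_crv(pts, combo = "11")
  expect_equal(rec$length, 5, tolerance = 1e-6)

  a <- 0.7
  diag_pts <- cbind(seq(0.1, a, length.out = 60),
                    seq(0.1, a, length.out = 60))
  q1 <- fit_crv(diag_pts)
  expect_equal(q1$angle_deg, 45, tolerance = 1e-8)
  expect_identical(q1$quadrant, "Q1")
  q3 <- fit_crv(-diag_pts)
  expect_equal(q3$angle_deg, 225, tolerance = 1e-8)
  expect_identical(q3$quadrant, "Q3")
  q2 <- fit_crv(cbind(-diag_pts[, 1], diag_pts[, 2]))
  expect_identical(q2$quadrant, "Q2")
  q4 <- fit_crv(cbind(diag_pts[, 1], -diag_pts[, 2]))
  expect_identical(q4$quadrant, "Q4")

  # degenerate inputs keep zero length for bookkeeping
  expect_identical(fit_crv(cbind(1, 1))$degenerate, TRUE)
  expect_identical(fit_crv(cbind(1, 1))$length, 0)
  expect_identical(fit_crv(cbind(c(1, 1), c(2, 2)))$degenerate, TRUE)

  # length is invariant to point order and duplication
  set.seed(3)
  xy <- cbind(rnorm(100), rnorm(100))
  l1 <- fit_crv(xy)$length
  expect_equal(fit_crv(xy[sample.int(100), ])$length, l1)
  expect_equal(fit_crv(rbind(xy, xy))$length, l1, tolerance = 1e-10)
})

test_that("quadrant labels are consistent with angles", {
  angles <- c(10, 45, 80, 100, 170, 200, 260, 300, 350)
  quads <- c("Q1", "Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4")
  for (i in seq_along(angles)) {
    r <- a2rec(angles[i])
    expect_identical(r$quadrant, quads[i])
  }
  expect_identical(a2rec(90)$quadrant, "axis")
  expect_identical(a2rec(180)$quadrant, "axis")
})

test_that("ordered-pair swap mirrors CRVs across the 45-225 diagonal", {
  truth <- tiny_truth(seed = 14)
  fit <- fit_tiny_model(truth, seed = 14, epochs = 25)
  sh <- shap_permutation(fit$model, fit$enc, background = fit$enc,
                         n_perm = 1, max_background = 20, seed = 2)
  crvs <- all_crvs(sh, fit$enc)
  swap_combo <- c("00" = "00", "01" = "10", "10" = "01", "11" = "11")
  key <- paste(crvs$feature1, crvs$feature2, crvs$combo)
  for (i in which(!crvs$degenerate)) {
    j <- match(paste(crvs$feature2[i], crvs$feature1[i],
                     swap_combo[[crvs$combo[i]]]), key)
    expect_false(is.na(j))
    expect_equal(crvs$length[j], crvs$length[i], tolerance = 1e-12)
    expect_equal(crvs$angle_deg[j], (90 - crvs$angle_deg[i]) %% 360,
                 tolerance = 1e-9)
  }
  # same-position (1,1) never emitted
  same <- crvs$combo == "11" &
    sub("_.*", "", crvs$feature1) == sub("_.*", "", crvs$feature2)
  expect_identical(sum(same), 0L)
  # full combinatorial census: 16*15 ordered pairs x 4 combos minus the
  # 16*3 same-position (1,1) exclusions
  expect_identical(nrow(crvs), 16L * 15L * 4L - 16L * 3L * 1L)
})

test_that("cumulative curves are nondecreasing and conserve length", {
  rec1 <- a2rec(225)
  cu <- cumulative_curve(rec1)
  expect_equal(cu$sweep_angle, 0)
  expect_equal(cu$cumulative_length, rec1$length)

  recs <- do.call(rbind, lapply(c(225, 250, 10, 100, 359), a2rec))
  recs$feature1 <- "H4_A"
  cu <- cumulative_curve(recs)
  expect_true(all(diff(cu$cumulative_length) >= 0))
  expect_true(all(diff(cu$sweep_angle) >= 0))
  expect_equal(max(cu$cumulative_length), sum(recs$length))
})

test_that("covariation grouping merges equivalent nucleotides", {
  base_curve <- function(feature, angles, lengths) {
    recs <- do.call(rbind, lapply(seq_along(angles), function(i)
      a2rec(angles[i], lengths[i])))
    recs$feature1 <- feature
    recs
  }
  # A and T share a shape; G and C each differ
  crvs <- rbind(
    base_curve("H4_A", c(230, 300, 40), c(1, 2, 1)),
    base_curve("H4_T", c(230, 300, 40), c(2, 4, 2)),  # scaled copy of A
    base_curve("H4_G", c(250, 90, 130), c(1, 3, 1)),
    base_curve("H4_C", c(300, 350, 200), c(5, 1, 2)))
  curves <- cumulative_curve(crvs, "feature1")
  gr <- covariation_groups(curves, threshold = 0.05)
  at_group <- gr$groups[vapply(gr$groups, function(g) "A" %in% g,
                               logical(1))][[1]]
  expect_identical(sort(at_group), c("A", "T"))
  expect_true("W" %in% gr$codes)  # A/T = W
  expect_equal(gr$distance["A", "T"], 0, tolerance = 1e-12)
})
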