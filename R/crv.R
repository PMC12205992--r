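# Second-order interaction analysis. The joint distribution of two binary
# features' Shapley values is multimodal, with modes indexed by the
# features' binary-encoding combination (0,0), (0,1), (1,0), (1,1). Each
# mode forms a half-line from the origin; a cooperative relationship vector
# (CRV) summarizes it: PC1 gives the slope, the centroid the direction, and
# the 99th percentiles of the absolute attribution values give the
# components X99, Y99 from which
#   length = sqrt(X99^2 + Y99^2),   angle = atan2(+-Y99, +-X99)
# with the component signs taken from the mode centroid (the percentiles
# themselves are nonnegative; the centroid carries the quadrant).

feature_position <- function(feature) sub("_[ATGC]$", "", feature)

#' Partition samples by the binary-encoding combination of two features
#'
#' @param encoding One-hot matrix (samples x features).
#' @param f1,f2 Feature names (e.g. `"H6_T"`, `"H7_G"`).
#' @return Named list of integer index vectors `"00"`, `"01"`, `"10"`,
#'   `"11"` (`"xy"` = bit of `f1`, bit of `f2`); disjoint, covering all
#'   samples.
#' @export
partition_modes <- function(encoding, f1, f2) {
  if (f1 == f2) stop("f1 and f2 must differ")
  for (f in c(f1, f2)) {
    if (!f %in% colnames(encoding)) stop("unknown feature: ", f)
  }
  b1 <- encoding[, f1]
  b2 <- encoding[, f2]
  key <- paste0(b1, b2)
  out <- list("00" = which(key == "00"), "01" = which(key == "01"),
              "10" = which(key == "10"), "11" = which(key == "11"))
  out
}

quadrant_of_angle <- function(angle_deg) {
  a <- angle_deg %% 360
  if (a %% 90 == 0) return("axis")
  if (a < 90) "Q1" else if (a < 180) "Q2" else if (a < 270) "Q3" else "Q4"
}

#' Fit a cooperative relationship vector to one mode
#'
#' @param xy Two-column matrix of (feature1, feature2) attribution pairs for
#'   the samples of one binary-encoding mode.
#' @param f1,f2 Feature names (carried into the record).
#' @param combo Combination label (`"00"`, `"01"`, `"10"`, `"11"`).
#' @param axis_tol Angular half-width (degrees) of the axis-proximity tag.
#' @return One-row data.frame: `feature1`, `feature2`, `combo`, `n_points`,
#'   `slope`, `centroid_x`, `centroid_y`, `x99`, `y99`, `length`,
#'   `angle_deg`, `quadrant`, `axis_proximal`, `degenerate`.
#' @export
fit_crv <- function(xy, f1 = "f1", f2 = "f2", combo = "11", axis_tol = 10) {
  xy <- as.matrix(xy)
  rec <- data.frame(feature1 = f1, feature2 = f2, combo = combo,
                    n_points = nrow(xy), slope = NA_real_,
                    centroid_x = NA_real_, centroid_y = NA_real_,
                    x99 = NA_real_, y99 = NA_real_, length = 0,
                    angle_deg = NA_real_, quadrant = NA_character_,
                    axis_proximal = NA, degenerate = TRUE,
                    stringsAsFactors = FALSE)
  if (nrow(xy) < 2) return(rec)
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  centered <- sweep(xy, 2, c(cx, cy))
  if (all(abs(centered) < 1e-300)) return(rec)  # identical points
  cv <- crossprod(centered) / (nrow(xy) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  pc1 <- ev$vectors[, 1]
  slope <- if (abs(pc1[1]) < 1e-300) Inf else pc1[2] / pc1[1]
  x99 <- unname(quantile(abs(xy[, 1]), 0.99, type = 7))
  y99 <- unname(quantile(abs(xy[, 2]), 0.99, type = 7))
  sx <- if (cx < 0) -1 else 1  # zero treated as positive
  sy <- if (cy < 0) -1 else 1
  angle <- (atan2(sy * y99, sx * x99) * 180 / pi) %% 360
  rec$slope <- slope
  rec$centroid_x <- cx; rec$centroid_y <- cy
  rec$x99 <- x99; rec$y99 <- y99
  rec$length <- sqrt(x99^2 + y99^2)
  rec$angle_deg <- angle
  rec$quadrant <- quadrant_of_angle(angle)
  rec$axis_proximal <- min(abs((angle %% 90)), 90 - (angle %% 90)) <= axis_tol
  rec$degenerate <- FALSE
  rec
}

#' All CRVs over a feature set
#'
#' One record per ordered feature pair and binary-encoding combination.
#' Same-position (1,1) modes are structurally empty under one-hot encoding
#' and are skipped.
#'
#' @param shap An `rss_shap` object (or attribution matrix).
#' @param encoding One-hot matrix aligned with the attribution rows.
#' @param features Features to compare; default all encoding columns.
#' @param axis_tol Passed to [fit_crv()].
#' @return data.frame of CRV records.
#' @export
all_crvs <- function(shap, encoding, features = colnames(encoding),
                     axis_tol = 10) {
  v <- if (inherits(shap, "rss_shap")) shap$values else as.matrix(shap)
  if (length(features) < 2) stop("need at least 2 features")
  if (nrow(v) != nrow(encoding)) stop("attribution/encoding row mismatch")
  recs <- list()
  for (f1 in features) {
    for (f2 in features) {
      if (f1 == f2) next
      same_pos <- feature_position(f1) == feature_position(f2)
      modes <- partition_modes(encoding, f1, f2)
      for (combo in names(modes)) {
        if (same_pos && combo == "11") next
        idx <- modes[[combo]]
        recs[[length(recs) + 1]] <-
          fit_crv(cbind(v[idx, f1], v[idx, f2]), f1, f2, combo, axis_tol)
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Cumulative length-angle curves
#'
#' CRVs in a group are swept counterclockwise starting at 225 degrees; the
#' curve is the running total of vector lengths against the sweep angle
#' (0-360 degrees of sweep). Steep regions mark angles dense in (or
#' dominated by long) CRVs.
#'
#' @param crvs data.frame from [all_crvs()] (degenerate records contribute
#'   zero length and are dropped).
#' @param group_by `"feature1"` (one curve per feature) or `"position"`.
#' @param sweep_start Sweep origin in degrees (default 225).
#' @return Long data.frame: `group`, `sweep_angle`, `angle_deg`,
#'   `cumulative_length`.
#' @export
cumulative_curve <- function(crvs, group_by = c("feature1", "position"),
                             sweep_start = 225) {
  group_by <- match.arg(group_by)
  crvs <- crvs[!crvs$degenerate, , drop = FALSE]
  grp <- if (group_by == "feature1") crvs$feature1 else
    feature_position(crvs$feature1)
  parts <- lapply(split(seq_len(nrow(crvs)), grp), function(idx) {
    sweep_angle <- (crvs$angle_deg[idx] - sweep_start) %% 360
    sweep_angle[sweep_angle > 360 - 1e-9] <- 0  # guard float wrap at 360
    o <- order(sweep_angle, crvs$length[idx])
    data.frame(group = grp[idx][1],
               sweep_angle = sweep_angle[o],
               angle_deg = crvs$angle_deg[idx][o],
               cumulative_length = cumsum(crvs$length[idx][o]))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Evaluate a cumulative step curve at arbitrary sweep angles.
eval_curve <- function(curve, at) {
  vapply(at, function(a) {
    below <- curve$cumulative_length[curve$sweep_angle <= a]
    if (length(below) == 0) 0 else max(below)
  }, numeric(1))
}

#' Group a position's nucleotides by covariation of their cumulative curves
#'
#' Curves are normalized by their final value (shape, not scale, is
#' compared); the distance between two curves is the maximum absolute
#' difference over the union of their step angles; single-linkage clustering
#' at `threshold` merges covarying nucleotides, which are reported as IUPAC
#' ambiguity codes.
#'
#' @param curves Cumulative-curve data.frame for the four features of one
#'   position (groups named `<pos>_A` etc.).
#' @param threshold Single-linkage merge distance.
#' @return List with `groups` (list of base vectors), `codes` (IUPAC code
#'   per group), and the `distance` matrix.
#' @export
covariation_groups <- function(curves, threshold = 0.2) {
  gnames <- sort(unique(curves$group))
  if (length(gnames) != 4) stop("expected 4 curves (one per base)")
  bases <- sub("^.*_", "", gnames)
  curve_list <- split(curves, curves$group)[gnames]
  norm_list <- lapply(curve_list, function(cu) {
    tot <- max(cu$cumulative_length)
    if (tot > 0) cu$cumulative_length <- cu$cumulative_length / tot
    cu
  })
  grid <- sort(unique(curves$sweep_angle))
  vals <- sapply(norm_list, eval_curve, at = grid)
  d <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in 1:3) for (j in (i + 1):4) {
    d[i, j] <- d[j, i] <- max(abs(vals[, i] - vals[, j]))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  cl <- stats::cutree(hc, h = threshold)
  groups <- split(bases, cl)
  names(groups) <- NULL
  groups <- groups[order(vapply(groups, function(g)
    min(match(g, BASE_LEX)), numeric(1)))]
  list(groups = groups,
       codes = vapply(groups, iupac_code, character(1)),
       distance = d)
}

#' Reference CRV nucleotide groupings
#'
#' Per-position nucleotide groupings (as IUPAC codes) derived from the
#' covariation of cumulative CRV curves on the trained heptamer/spacer
#' model; used as the reduced-category scheme for mutation-effect maps.
#'
#' @export
CRV_REFERENCE_GROUPS <- list(
  H4 = c("D", "C"), H5 = c("R", "Y"), H6 = c("R", "T", "C"),
  H7 = c("R", "Y"), S1 = c("W", "S"), S2 = c("M", "T", "G")
)

#' Write CRV tables
#'
#' @param crvs data.frame from [all_crvs()].
#' @param path Output TSV path.
#' @export
write_crvs <- function(crvs, path) {
  write.table(crvs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
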