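# Synthetic SARP-seq generator with known ground truth. Emulates the
# structure of the experimental libraries: a 4096-variant N(H4-S2) library
# (or the 512-per-group N(H4-H7)K(S2) design) with additive
# nucleotide:position effects on a latent scale, selectable pairwise
# interaction terms, a logistic link to expected efficiency in (0,1),
# multiplicative nonamer scaling across groups, and replicate-level
# negative-binomial count noise with detection dropout (weak recombinators
# fail to appear among sequenced products; the dropout probability decays
# exponentially with the expected read count). Default noise and effect
# scales are chosen so the default library reproduces the experimental
# composition (roughly 35% of variants at >= 10 reads, 21% below, 43%
# zeros at the default depth) while keeping the attainable model accuracy
# comparable to what the experimental data support.

#' Ground truth for a synthetic SARP-seq dataset
#'
#' First-order effects are drawn per nucleotide:position feature
#' (block-centered within each position so the parametrization is
#' identifiable under one-hot encoding); pairwise terms add a latent bonus
#' or penalty when both named features are present. Expected efficiency is
#' the logistic of the latent sum, keeping expectations in (0,1) so min-max
#' normalization of noiseless data is close to the identity.
#'
#' @param positions Position labels of the library.
#' @param alphabets Allowed bases (vector or per-position list).
#' @param effect_sd SD of first-order latent effects.
#' @param intercept Latent intercept; negative values make the efficiency
#'   distribution asymmetric with most variants inactive.
#' @param pairwise data.frame with columns `f1`, `f2`, `delta` (latent
#'   interaction when both features are present), or NULL. Defaults to a
#'   positive synergy and a negative (mutually suppressive) pair.
#' @param nonamer_scales Optional named positive multipliers on expected
#'   efficiency, one per nonamer group.
#' @param seed Integer seed.
#' @return List of class `synth_truth`.
#' @export
make_truth <- function(positions = H4S2_POSITIONS, alphabets = BASE_LEX,
                       effect_sd = 2.0, intercept = -4.5,
                       pairwise = data.frame(
                         f1 = c("H6_T", "H5_C"), f2 = c("H7_G", "S1_G"),
                         delta = c(2.0, -2.0)),
                       nonamer_scales = NULL, seed = 1) {
  set.seed(seed)
  feat <- as.vector(t(outer(positions, BASE_ORDER, paste, sep = "_")))
  beta <- rnorm(length(feat), 0, effect_sd)
  names(beta) <- feat
  for (p in positions) {  # center each position block
    blk <- paste0(p, "_", BASE_ORDER)
    beta[blk] <- beta[blk] - mean(beta[blk])
  }
  if (!is.null(pairwise) && nrow(pairwise) > 0) {
    for (i in seq_len(nrow(pairwise))) {
      p1 <- feature_position(pairwise$f1[i])
      p2 <- feature_position(pairwise$f2[i])
      if (p1 == p2) {
        stop("pairwise term within one position (", p1,
             ") is unidentifiable under one-hot encoding")
      }
      if (!all(c(pairwise$f1[i], pairwise$f2[i]) %in% feat)) {
        stop("pairwise term names unknown feature")
      }
    }
  }
  if (!is.null(nonamer_scales)) {
    stopifnot(all(nonamer_scales > 0), !is.null(names(nonamer_scales)))
  }
  structure(list(positions = positions, alphabets = alphabets,
                 intercept = intercept, beta = beta,
                 pairwise = pairwise, nonamer_scales = nonamer_scales,
                 effect_sd = effect_sd, seed = seed),
            class = "synth_truth")
}

#' Latent scores and expected efficiencies under a truth
#'
#' Brute-force evaluation of the generator's expectation for arbitrary
#' variants: the latent additive-plus-pairwise score and its logistic
#' transform (scaled per nonamer group when requested). Serves as the
#' oracle that model, attribution and CRV recovery tests compare against.
#'
#' @param truth A `synth_truth`.
#' @param seqs Sequences over the truth's positions (default the full
#'   library).
#' @param group Optional nonamer group label (applies that group's scale).
#' @return data.frame: `sequence`, `latent`, `efficiency`.
#' @export
truth_oracle <- function(truth, seqs = NULL, group = NULL) {
  if (is.null(seqs)) {
    seqs <- as.character(enumerate_library(truth$positions, truth$alphabets))
  }
  enc <- one_hot_encode(seqs, truth$positions)
  latent <- truth$intercept + as.vector(enc %*% truth$beta[colnames(enc)])
  if (!is.null(truth$pairwise) && nrow(truth$pairwise) > 0) {
    for (i in seq_len(nrow(truth$pairwise))) {
      both <- enc[, truth$pairwise$f1[i]] * enc[, truth$pairwise$f2[i]]
      latent <- latent + truth$pairwise$delta[i] * both
    }
  }
  eff <- plogis(latent)
  if (!is.null(group)) {
    if (is.null(truth$nonamer_scales[[group]])) {
      stop("unknown nonamer group: ", group)
    }
    eff <- pmin(1, eff * truth$nonamer_scales[[group]])
  }
  data.frame(sequence = seqs, latent = latent, efficiency = eff,
             stringsAsFactors = FALSE)
}

# Dropout scale tau giving the target overall zero fraction: a variant
# with expected count m escapes detection with probability exp(-m/tau), on
# top of negative-binomial sampling zeros.
solve_dropout_scale <- function(mu_counts, size, zero_target) {
  z_nb <- dnbinom(0, size = size, mu = mu_counts)
  if (mean(z_nb) >= zero_target) return(0)  # no dropout needed
  fz <- function(tau) {
    e <- exp(-mu_counts / tau)
    mean(e + (1 - e) * z_nb) - zero_target
  }
  if (fz(1e-9) * fz(1e5) > 0) return(0)
  uniroot(fz, c(1e-9, 1e5))$root
}

# Expected fraction of variants with 0 < count < threshold once the
# dropout scale has been solved for the zero target.
expected_low_fraction <- function(depth, mu_eff, size, zero_target,
                                  threshold) {
  m <- depth * mu_eff
  tau <- solve_dropout_scale(m, size, zero_target)
  e <- if (tau == 0) rep(0, length(m)) else exp(-m / tau)
  z_nb <- dnbinom(0, size = size, mu = m)
  mean((1 - e) * (pnbinom(threshold - 1, size = size, mu = m) - z_nb))
}

# Depth giving the target below-threshold fraction for this truth's
# efficiency distribution (deeper sequencing pushes counts above the
# threshold). Falls back to the nearest bracket end when the target is
# unreachable.
calibrate_depth <- function(mu_eff, size, zero_target, low_target,
                            threshold = 10, bracket = c(5, 20000)) {
  # floor: depth at which sampling zeros alone match the zero target (the
  # dropout scale can only add zeros, never remove them)
  nat_zero <- function(d) mean(dnbinom(0, size = size, mu = d * mu_eff))
  if (nat_zero(bracket[1]) > zero_target) {
    if (nat_zero(bracket[2]) > zero_target) {
      bracket[1] <- bracket[2]
    } else {
      bracket[1] <- uniroot(function(d) nat_zero(d) - zero_target,
                            bracket, tol = 0.01)$root
    }
  }
  f <- function(d) expected_low_fraction(d, mu_eff, size, zero_target,
                                         threshold) - low_target
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (flo * fhi > 0) {
    return(if (abs(flo) < abs(fhi)) bracket[1] else bracket[2])
  }
  uniroot(f, bracket, tol = 0.01)$root
}

#' Simulate SARP-seq read-count tables from a truth
#'
#' Counts are negative binomial with mean proportional to depth times
#' expected efficiency, thinned by detection dropout: a variant escapes
#' detection with probability `exp(-expected_count/tau)`, emulating weak
#' recombinators whose products were never sequenced. `tau` is solved so
#' the expected overall zero fraction matches `zero_target`. With
#' `nonamer_scales` in the truth, one library per group is simulated with
#' the group's efficiency scaling.
#'
#' @param truth A `synth_truth`.
#' @param depth Sequencing depth factor (expected count of a
#'   full-efficiency variant). The default `NULL` calibrates the depth per
#'   truth so the expected fraction of low-count variants
#'   (`0 < count < 10`) matches `low_target`, reproducing the experimental
#'   read-count composition.
#' @param replicates Number of replicate tables (or a named vector of
#'   per-group replicate counts when groups are present).
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param zero_target Target overall zero fraction (default 0.432).
#' @param low_target Target fraction of variants with 1-9 reads (used only
#'   when `depth` is NULL).
#' @param seed Integer seed; the truth's seed is not reused so datasets
#'   and truth are independently reproducible.
#' @return data.frame with columns `sequence`, `count`, `replicate` (and
#'   `nonamer` when groups are present); attribute `truth` carries the
#'   generator truth.
#' @export
simulate_counts <- function(truth, depth = NULL, replicates = 1,
                            dispersion = 8, zero_target = 0.432,
                            low_target = 0.214, seed = 1) {
  set.seed(seed)
  groups <- if (is.null(truth$nonamer_scales)) "" else
    names(truth$nonamer_scales)
  rep_counts <- if (length(replicates) == 1) {
    rep(replicates, length(groups))
  } else {
    unname(replicates[groups])
  }
  oracles <- lapply(groups, function(g)
    truth_oracle(truth, group = if (nzchar(g)) g else NULL))
  pooled_eff <- unlist(lapply(oracles, `[[`, "efficiency"))
  # depth and dropout are calibrated once, on the pooled efficiency
  # distribution, so nonamer scales shift the per-group count levels
  # exactly as planted
  if (is.null(depth)) {
    depth <- calibrate_depth(pooled_eff, dispersion, zero_target,
                             low_target)
  }
  stopifnot(depth > 0)
  tau <- solve_dropout_scale(depth * pooled_eff, dispersion, zero_target)
  parts <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    oracle <- oracles[[gi]]
    mu_counts <- depth * oracle$efficiency
    p_drop <- if (tau == 0) rep(0, length(mu_counts)) else
      exp(-mu_counts / tau)
    for (r in seq_len(rep_counts[gi])) {
      n <- length(mu_counts)
      counts <- rnbinom(n, size = dispersion, mu = mu_counts)
      dropped <- rbinom(n, 1, p_drop) == 1
      counts[dropped] <- 0
      part <- data.frame(sequence = oracle$sequence, count = counts,
                         replicate = r, stringsAsFactors = FALSE)
      if (nzchar(g)) part$nonamer <- g
      parts[[length(parts) + 1]] <- part
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Serialize a truth as JSON
#'
#' @param truth A `synth_truth`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  payload <- unclass(truth)
  payload$beta <- as.list(payload$beta)  # keep feature names in JSON
  payload$alphabets <- if (is.list(payload$alphabets)) payload$alphabets else
    as.list(setNames(rep(list(payload$alphabets),
                         length(payload$positions)), payload$positions))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
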