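# Nonamer-informed dataset assembly, per-nonamer attribution rescaling,
# KS-based cross-nonamer comparison, and long-distance interaction
# candidate flagging. The nonamer-informed model sees the H4-S2 one-hot
# block (24 bits) plus an encoding of the variable nonamer positions
# N1-N3, N8-N9 (20 bits), so sequence context outside the randomized
# heptamer/spacer window can rescale predictions per nonamer group.

#' Assemble the nonamer-informed dataset and encoding
#'
#' Replicate tables are averaged per nonamer group, zero-completed against
#' the N(H4-H7)K(S2) library (H4-H7 fully randomized, S2 either T or G, S1
#' constant), and min-max normalized dataset-wide across the combined
#' groups.
#'
#' @param tables Read-count data.frame(s) carrying `nonamer` (and
#'   optionally `replicate`) columns, or a list of per-replicate tables.
#' @param nonamer_seqs Named character vector: for every nonamer group the
#'   5 variable nonamer bases (N1,N2,N3,N8,N9 concatenated, e.g.
#'   `"ACAAC"`).
#' @param s1_base Constant S1 base of the library design (default `"A"`).
#' @return List with `data` (normalized data.frame: sequence, nonamer,
#'   count, target) and `encoding` (one-hot matrix, 44 columns).
#' @export
build_cnon_dataset <- function(tables, nonamer_seqs, s1_base = "A") {
  if (!is.data.frame(tables)) {
    tables <- do.call(rbind, tables)
  }
  if (is.null(tables$nonamer)) stop("tables must carry a nonamer column")
  groups <- unique(tables$nonamer)
  missing <- setdiff(groups, names(nonamer_seqs))
  if (length(missing) > 0) {
    stop("nonamer sequence missing for group(s): ",
         paste(missing, collapse = ","))
  }
  library <- as.character(enumerate_library(
    H4S2_POSITIONS,
    c(rep(list(BASE_LEX), 4), list(s1_base), list(c("G", "T")))
  ))
  averaged <- average_replicates(tables)
  completed <- complete_with_zeros(averaged, library)
  normalized <- minmax_normalize(completed, "dataset-wide")
  enc_h4s2 <- one_hot_encode(normalized$sequence, H4S2_POSITIONS)
  nona <- vapply(as.character(normalized$nonamer), function(g)
    toupper(nonamer_seqs[[g]]), character(1))
  if (any(nchar(nona) != 5)) {
    stop("each nonamer sequence must give the 5 variable bases N1N2N3N8N9")
  }
  enc_nona <- one_hot_encode(nona, NONAMER_POSITIONS)
  encoding <- cbind(enc_h4s2, enc_nona)
  rownames(encoding) <- paste0(normalized$sequence, "|", normalized$nonamer)
  list(data = normalized, encoding = encoding)
}

h4s2_feature_names <- function() {
  as.vector(t(outer(H4S2_POSITIONS, BASE_ORDER, paste, sep = "_")))
}

#' Rescale attributions by each nonamer group's global mean
#'
#' Divides every attribution value of a group by that group's global mean
#' absolute attribution over all H4-S2 features and samples, redefining
#' each value as a fold change from the group's own scale. After rescaling
#' each group's global mean absolute attribution is exactly 1, so
#' cross-group comparisons see distribution shape rather than the
#' nonamer's global scaling.
#'
#' @param values Attribution matrix (samples x features) or `rss_shap`.
#' @param groups Nonamer group label per sample.
#' @param features Columns over which the global mean is taken (default the
#'   24 H4-S2 features).
#' @return List with `values` (rescaled matrix, H4-S2 feature columns),
#'   `divisors` (named per-group global means), `groups`.
#' @export
rescale_by_global_mean <- function(values, groups,
                                   features = h4s2_feature_names()) {
  v <- if (inherits(values, "rss_shap")) values$values else as.matrix(values)
  if (length(groups) != nrow(v)) stop("one group label per sample required")
  features <- intersect(features, colnames(v))
  v <- v[, features, drop = FALSE]
  out <- v
  divisors <- c()
  for (g in unique(groups)) {
    sel <- groups == g
    gm <- mean(abs(v[sel, , drop = FALSE]))
    if (gm == 0) stop("zero global mean attribution in group ", g)
    out[sel, ] <- v[sel, , drop = FALSE] / gm
    divisors[g] <- gm
  }
  list(values = out, divisors = divisors, groups = groups)
}

#' KS statistics between nonamer groups per feature
#'
#' Two-sample KS statistic of the rescaled attribution distributions for
#' every H4-S2 feature and every unordered group pair.
#'
#' @param rescaled Result of [rescale_by_global_mean()].
#' @return data.frame: `feature`, `pair` (e.g. `"CF1-LMO2"`), `statistic`,
#'   `p_value`.
#' @export
nonamer_ks_matrix <- function(rescaled) {
  v <- rescaled$values
  groups <- rescaled$groups
  gl <- unique(groups)
  if (length(gl) < 2) stop("need at least 2 nonamer groups")
  for (g in gl) {
    if (sum(groups == g) < 2) stop("group ", g, " has fewer than 2 samples")
  }
  rows <- list()
  for (i in seq_len(length(gl) - 1)) {
    for (j in seq(i + 1, length(gl))) {
      for (f in colnames(v)) {
        ks <- ks_two_sample(v[groups == gl[i], f], v[groups == gl[j], f])
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, pair = paste0(gl[i], "-", gl[j]),
          statistic = ks$statistic, p_value = ks$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag candidate long-distance heptamer-nonamer interactions
#'
#' Features whose rescaled-attribution KS statistic reaches the threshold
#' for at least one group pair; the exceeding pairs are listed so patterns
#' such as "differs only against one nonamer" are visible.
#'
#' @param ks data.frame from [nonamer_ks_matrix()].
#' @param threshold KS statistic cutoff (default 0.20).
#' @return data.frame: `feature`, `max_statistic`, `pairs_above` (comma
#'   separated); empty when nothing reaches the threshold.
#' @export
flag_long_distance_candidates <- function(ks, threshold = 0.20) {
  hits <- ks[ks$statistic >= threshold, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(feature = character(), max_statistic = numeric(),
                      pairs_above = character(), stringsAsFactors = FALSE))
  }
  parts <- lapply(split(hits, hits$feature), function(d) {
    data.frame(feature = d$feature[1],
               max_statistic = max(d$statistic),
               pairs_above = paste(d$pair[order(-d$statistic)],
                                   collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(-out$max_statistic), ]
  rownames(out) <- NULL
  out
}
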