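# Nearest-neighbor duplex melting temperature of the H4-S2 window and the
# 4-mer alignment regressions of log-prediction on Tm.
#
# Thermodynamics: unified nearest-neighbor DNA parameters (SantaLucia 1998;
# enthalpy kcal/mol, entropy cal/mol/K per stacked dinucleotide, plus
# terminal initiation terms), entropy-based monovalent salt correction
# 0.368*(N-1)*ln[Na+], and Tm = 1000*dH / (dS + R*ln(CT)) - 273.15 with
# R = 1.987 cal/mol/K and CT the molar strand concentration factor
# (dnac1 - dnac2/2 for non-self-complementary duplexes).

NN_DH <- c("AA" = -7.9, "AT" = -7.2, "TA" = -7.2, "CA" = -8.5, "GT" = -8.4,
           "CT" = -7.8, "GA" = -8.2, "CG" = -10.6, "GC" = -9.8, "GG" = -8.0)
NN_DS <- c("AA" = -22.2, "AT" = -20.4, "TA" = -21.3, "CA" = -22.7,
           "GT" = -22.4, "CT" = -21.0, "GA" = -22.2, "CG" = -27.2,
           "GC" = -24.4, "GG" = -19.9)
INIT_AT <- c(dh = 2.3, ds = 4.1)
INIT_GC <- c(dh = 0.1, ds = -2.8)

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(seq, ""), function(s)
           paste(rev(s), collapse = ""), character(1)))
}

nn_lookup <- function(dinuc, table) {
  # stacks are duplex-symmetric: XY pairs with revcomp(XY)
  v <- table[dinuc]
  miss <- is.na(v)
  if (any(miss)) v[miss] <- table[revcomp(dinuc[miss])]
  unname(v)
}

#' Nearest-neighbor duplex melting temperature
#'
#' @param seq Sequence of the duplex top strand over `{A,C,G,T}` (the H4-S2
#'   analyses use the 6-base window only).
#' @param Na Monovalent sodium concentration in mM (default 50).
#' @param dnac1,dnac2 Strand concentrations in nM (defaults 25 and 25; the
#'   total concentration factor is `dnac1 - dnac2/2`).
#' @return Tm in degrees Celsius.
#' @export
duplex_tm <- function(seq, Na = 50, dnac1 = 25, dnac2 = 25) {
  seq <- toupper(seq)
  vapply(seq, function(s) {
    chars <- strsplit(s, "")[[1]]
    check_bases(chars)
    if (length(chars) < 2) stop("sequence too short for a stack sum")
    dh <- 0; ds <- 0
    for (end_base in chars[c(1, length(chars))]) {
      if (end_base %in% c("A", "T")) {
        dh <- dh + INIT_AT["dh"]; ds <- ds + INIT_AT["ds"]
      } else {
        dh <- dh + INIT_GC["dh"]; ds <- ds + INIT_GC["ds"]
      }
    }
    dinucs <- paste0(chars[-length(chars)], chars[-1])
    dh <- dh + sum(nn_lookup(dinucs, NN_DH))
    ds <- ds + sum(nn_lookup(dinucs, NN_DS))
    ds_salt <- ds + 0.368 * (length(chars) - 1) * log(Na / 1000)
    ct <- (dnac1 - dnac2 / 2) * 1e-9
    unname(1000 * dh / (ds_salt + 1.987 * log(ct)) - 273.15)
  }, numeric(1))
}

#' Correlation between melting temperature and model prediction
#'
#' Spearman on the raw predictions and Pearson on the base-10 log
#' predictions (variants with nonpositive predictions are excluded from
#' both, count reported).
#'
#' @param predictions Named numeric vector (names = sequences) or plain
#'   vector aligned with `sequences`.
#' @param sequences Sequences; defaults to `names(predictions)`.
#' @return List with `spearman_rho`, `pearson_r_log`, `n_used`,
#'   `n_excluded`.
#' @export
tm_prediction_correlation <- function(predictions,
                                      sequences = names(predictions)) {
  if (is.null(sequences)) stop("sequences required")
  keep <- predictions > 0
  if (sum(keep) < 3) stop("fewer than 3 usable (positive) predictions")
  tm <- duplex_tm(sequences[keep])
  p <- predictions[keep]
  list(spearman_rho = suppressWarnings(cor(tm, p, method = "spearman")),
       pearson_r_log = suppressWarnings(cor(tm, log10(p))),
       n_used = sum(keep), n_excluded = sum(!keep))
}

#' Linear regression of log-prediction on Tm for one 4-mer alignment
#'
#' The 4-mer is fixed at its alignment within the H4-S2 window; the 16
#' sequences matching the motif are regressed (ordinary least squares) as
#' `log10(prediction) ~ Tm`.
#'
#' @param kmer 4-base string.
#' @param alignment `"-1"`, `"0"` or `"+1"`.
#' @param predictions Named numeric vector over the full 4096-member
#'   library (names = sequences).
#' @return One-row data.frame: `kmer`, `alignment`, `n_used`, `slope`,
#'   `r_squared`, `centroid_tm`, `centroid_log_pred`, `h6_base`.
#' @export
alignment_regression <- function(kmer, alignment, predictions) {
  motif <- kmer_alignments(kmer)[[as.character(alignment)]]
  if (is.null(motif)) stop("alignment must be -1, 0 or +1")
  seqs <- match_motif(names(predictions), motif)
  p <- predictions[seqs]
  keep <- p > 0
  if (sum(keep) == 0) stop("all predictions nonpositive for ", kmer, " ",
                           alignment)
  tm <- duplex_tm(seqs[keep])
  if (length(unique(round(tm, 12))) < 2) {
    stop("constant Tm within the alignment set: slope undefined")
  }
  y <- log10(p[keep])
  fit <- lm(y ~ tm)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  # position of H6 inside the kmer window: -1 -> 3rd, 0 -> 2nd, +1 -> 1st
  h6_idx <- c("-1" = 3, "0" = 2, "+1" = 1)[[as.character(alignment)]]
  data.frame(kmer = kmer, alignment = as.character(alignment),
             n_used = sum(keep),
             slope = unname(coef(fit)[2]),
             r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot,
             centroid_tm = mean(tm),
             centroid_log_pred = mean(y),
             h6_base = substr(kmer, h6_idx, h6_idx),
             stringsAsFactors = FALSE)
}

#' Regression sweep over all 256 4-mers and three alignments
#'
#' @param predictions Named numeric vector over the full library.
#' @return data.frame of 768 regression summaries with an added
#'   `has_G_at_H6` flag; attribute `aggregates` holds per-alignment mean
#'   slope, mean R-squared and the fraction of negative slopes.
#' @export
sweep_kmer_regressions <- function(predictions) {
  if (is.null(names(predictions))) stop("predictions must be named")
  seqs <- names(predictions)
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  tm_all <- duplex_tm(seqs)
  kmers <- all_kmers()
  offsets <- c("-1" = 0L, "0" = 1L, "+1" = 2L)
  rows <- vector("list", length(kmers) * 3)
  ri <- 0
  for (km in kmers) {
    kb <- strsplit(km, "")[[1]]
    for (al in names(offsets)) {
      off <- offsets[[al]]
      sel <- chars[, 1 + off] == kb[1] & chars[, 2 + off] == kb[2] &
        chars[, 3 + off] == kb[3] & chars[, 4 + off] == kb[4]
      p <- predictions[sel]
      keep <- p > 0
      if (sum(keep) == 0) stop("all predictions nonpositive for ", km)
      tm <- tm_all[sel][keep]
      y <- log10(p[keep])
      vx <- var(tm)
      if (vx == 0) stop("constant Tm within the alignment set for ", km)
      slope <- cov(tm, y) / vx
      vy <- var(y)
      r2 <- if (vy == 0) 0 else cov(tm, y)^2 / (vx * vy)
      h6_idx <- 3L - off
      ri <- ri + 1
      rows[[ri]] <- data.frame(
        kmer = km, alignment = al, n_used = sum(keep), slope = slope,
        r_squared = r2, centroid_tm = mean(tm), centroid_log_pred = mean(y),
        h6_base = substr(km, h6_idx, h6_idx), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$has_G_at_H6 <- out$h6_base == "G"
  agg <- do.call(rbind, lapply(split(out, out$alignment), function(d) {
    data.frame(alignment = d$alignment[1],
               mean_slope = mean(d$slope),
               mean_r_squared = mean(d$r_squared),
               frac_negative_slope = mean(d$slope < 0))
  }))
  rownames(agg) <- NULL
  attr(out, "aggregates") <- agg
  out
}
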