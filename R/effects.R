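# Point-mutation effect maps on any per-variant score, reduced-category
# maps via CRV nucleotide groupings, score-vs-prediction correlation with
# striation sampling, and position-frequency matrices for sequence logos.

score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    if (!all(c("sequence", "score") %in% names(scores))) {
      stop("score table needs columns sequence, score")
    }
    setNames(scores$score, toupper(scores$sequence))
  } else {
    if (is.null(names(scores))) stop("scores must be named by sequence")
    setNames(as.numeric(scores), toupper(names(scores)))
  }
}

#' Mean score change of a point mutation
#'
#' Compares the set of library sequences carrying `from_base` at `position`
#' against the set carrying `to_base` there (all other positions
#' degenerate): the effect is mean(mutated set) - mean(original set).
#'
#' @param scores Named numeric vector or (sequence, score) data.frame
#'   covering the complete library.
#' @param library Character vector of library sequences with a `positions`
#'   attribute (as from [enumerate_library()]), or plain sequences plus
#'   `positions`.
#' @param position Position label (e.g. `"H4"`).
#' @param from_base,to_base Bases in `{A,C,G,T}`.
#' @param positions Position labels if `library` carries none.
#' @return List with `effect`, `n_from`, `n_to`.
#' @export
point_mutation_effect <- function(scores, library, position, from_base,
                                  to_base,
                                  positions = attr(library, "positions")) {
  if (is.null(positions)) positions <- H4S2_POSITIONS
  s <- score_vector(scores)
  missing <- setdiff(toupper(library), names(s))
  if (length(missing) > 0) {
    stop("scores missing for ", length(missing), " library variant(s), e.g. ",
         paste(head(missing, 3), collapse = ","))
  }
  j <- match(position, positions)
  if (is.na(j)) stop("unknown position: ", position)
  motif_of <- function(b) {
    m <- rep("N", length(positions)); m[j] <- b
    paste(m, collapse = "")
  }
  from_set <- match_motif(library, motif_of(from_base))
  to_set <- match_motif(library, motif_of(to_base))
  list(effect = mean(s[to_set]) - mean(s[from_set]),
       n_from = length(from_set), n_to = length(to_set))
}

#' Mutation-effect heatmaps per position
#'
#' With `scheme = "bases"` each position yields a 4x4 from-by-to matrix of
#' mean score changes. With a reduced scheme (named list mapping positions
#' to IUPAC category codes, e.g. `CRV_REFERENCE_GROUPS`), category scores
#' are pooled means over all member sequences, so the matrices shrink to
#' the category count.
#'
#' @param scores As in [point_mutation_effect()].
#' @param library Library sequences.
#' @param scheme `"bases"` or a named list of IUPAC codes per position.
#' @param positions Position labels.
#' @return Named list (per position) of effect matrices (from = rows,
#'   to = columns; zero diagonal).
#' @export
effect_heatmaps <- function(scores, library, scheme = "bases",
                            positions = attr(library, "positions")) {
  if (is.null(positions)) positions <- H4S2_POSITIONS
  s <- score_vector(scores)
  out <- list()
  for (j in seq_along(positions)) {
    pos <- positions[j]
    cats <- if (identical(scheme, "bases")) BASE_LEX else {
      if (is.null(scheme[[pos]])) stop("scheme missing position ", pos)
      scheme[[pos]]
    }
    # verify the categories partition {A,C,G,T}
    members <- lapply(cats, iupac_bases)
    all_bases <- sort(unlist(members))
    if (!identical(all_bases, BASE_LEX)) {
      stop("categories at ", pos, " do not partition {A,C,G,T}")
    }
    cat_mean <- vapply(members, function(bs) {
      m <- rep("N", length(positions)); m[j] <- iupac_code(bs)
      mean(s[match_motif(library, paste(m, collapse = ""))])
    }, numeric(1))
    mat <- outer(cat_mean, cat_mean, function(a, b) b - a)
    dimnames(mat) <- list(from = cats, to = cats)
    out[[pos]] <- mat
  }
  out
}

#' Correlate two per-variant score tables
#'
#' @param a,b Named numeric vectors or (sequence, score) data.frames.
#' @param transform `"none"` or `"log10_on_a"` (nonpositive `a` values
#'   excluded, count reported).
#' @return List with `spearman_rho`, `pearson_r`, `n`, `n_excluded`.
#' @export
correlate_scores <- function(a, b, transform = c("none", "log10_on_a")) {
  transform <- match.arg(transform)
  av <- score_vector(a); bv <- score_vector(b)
  shared <- intersect(names(av), names(bv))
  if (length(shared) < 3) stop("fewer than 3 shared variants")
  x <- av[shared]; y <- bv[shared]
  n_excl <- 0L
  if (transform == "log10_on_a") {
    keep <- x > 0
    n_excl <- sum(!keep)
    x <- log10(x[keep]); y <- y[keep]
    if (length(x) < 3) stop("fewer than 3 usable variants after log filter")
  }
  list(spearman_rho = suppressWarnings(cor(x, y, method = "spearman")),
       pearson_r = suppressWarnings(cor(x, y)),
       n = length(x), n_excluded = n_excl)
}

#' Sample vertical striations of a score-vs-score scatter
#'
#' For each center on the x-axis score, collects the variants within
#' `half_width` and reports the spread of the y-axis score together with a
#' position-frequency matrix of the sampled sequences (sequence-logo-ready
#' counts). Used to inspect x-axis scores that lump together variants the
#' y-axis score separates.
#'
#' @param a X-axis score table (e.g. an external functionality score).
#' @param b Y-axis score table (e.g. model predictions).
#' @param centers X values to sample near (defaults to the four quoted
#'   striations -17, -20, -26, -32).
#' @param half_width Window half-width in x units.
#' @return List of per-center reports: `center`, `n`, `sequences`,
#'   `top_sequence`, `bottom_sequence`, `x_range`, `y_range`, `pfm`;
#'   empty striations are flagged with `n = 0`.
#' @export
striation_sample <- function(a, b, centers = c(-17, -20, -26, -32),
                             half_width = 0.25) {
  av <- score_vector(a); bv <- score_vector(b)
  shared <- intersect(names(av), names(bv))
  lapply(centers, function(ct) {
    sel <- shared[abs(av[shared] - ct) <= half_width]
    if (length(sel) == 0) {
      return(list(center = ct, n = 0L))
    }
    y <- bv[sel]
    list(center = ct, n = length(sel), sequences = sel,
         top_sequence = sel[which.max(y)],
         bottom_sequence = sel[which.min(y)],
         x_range = range(av[sel]), y_range = range(y),
         pfm = position_frequency_matrix(sel))
  })
}

#' Position frequency matrix of a sequence set
#'
#' @param variants Equal-length sequences.
#' @param positions Position labels (default H4-S2 when lengths match).
#' @return Integer matrix (bases x positions) of counts; every column sums
#'   to the number of sequences.
#' @export
position_frequency_matrix <- function(variants, positions = NULL) {
  L <- unique(nchar(variants))
  if (length(L) != 1) stop("variants must share positions")
  if (is.null(positions)) {
    positions <- if (L == 6) H4S2_POSITIONS else paste0("P", seq_len(L))
  }
  chars <- do.call(rbind, strsplit(toupper(variants), ""))
  pfm <- sapply(seq_len(L), function(j) {
    vapply(BASE_LEX, function(b) sum(chars[, j] == b), integer(1))
  })
  colnames(pfm) <- positions
  pfm
}

#' Functional threshold of the RSS information content (RIC) score
#'
#' 12-RSSs with RIC scores between -38.81 and 0 are classified functional,
#' below -38.81 nonfunctional; shipped as metadata for external-score
#' comparisons (the RIC algorithm itself is not part of this package).
#'
#' @export
RIC_FUNCTIONAL_THRESHOLD <- -38.81

#' Read an external per-variant score table
#'
#' Two-column TSV (sequence, score), e.g. precomputed RSS information
#' content (RIC) scores. The scoring algorithm itself is external to this
#' package; its output is consumed as-is.
#'
#' @param path File path.
#' @return Named numeric vector of scores.
#' @export
read_score_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "score") %in% names(df))) {
    stop("score table must have columns sequence, score")
  }
  setNames(as.numeric(df$score), toupper(df$sequence))
}
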