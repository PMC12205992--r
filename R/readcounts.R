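# Ingest, complete, normalize, summarize and stratify SARP-seq read-count
# tables. A read-count table is a data.frame with columns:
#   sequence (chr), count (numeric >= 0) and optionally replicate, nonamer.

#' Load a SARP-seq read-count table
#'
#' Reads a TSV or CSV with header columns `sequence` and `count` (optional
#' `replicate` and `nonamer` are preserved). The dialect is chosen by file
#' extension (`.csv` is comma-separated, anything else tab-separated).
#'
#' @param path File path.
#' @return A read-count data.frame.
#' @export
load_read_counts <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (!all(c("sequence", "count") %in% names(df))) {
    stop("read-count file must have header columns sequence, count: ", path)
  }
  df$sequence <- toupper(df$sequence)
  bad <- grep("[^ACGT]", df$sequence)
  if (length(bad) > 0) {
    stop("non-ACGT sequence at data line(s): ",
         paste(head(bad, 5), collapse = ","))
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad) > 0) {
    stop("count must be a nonnegative integer; offending data line(s): ",
         paste(head(bad, 5), collapse = ","))
  }
  df$count <- cnt
  keep <- intersect(c("sequence", "count", "replicate", "nonamer"), names(df))
  df[keep]
}

#' Write a read-count table as TSV
#'
#' @param table Read-count data.frame.
#' @param path File path.
#' @export
write_read_counts <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

group_split_idx <- function(table) {
  key <- rep("", nrow(table))
  if (!is.null(table$replicate)) key <- paste0(key, table$replicate, "|")
  if (!is.null(table$nonamer)) key <- paste0(key, table$nonamer)
  split(seq_len(nrow(table)), key)
}

#' Reintroduce library members absent from a read-count table as zeros
#'
#' Variants that showed no detectable recombination are missing from the
#' sequenced output; completion adds them back with zero counts so the full
#' library (e.g. all 4096 N(H4-S2) members) is represented. Applied per
#' replicate/nonamer stratum when those columns are present.
#'
#' @param table Read-count data.frame.
#' @param library Character vector of all library sequences.
#' @return Completed table with exactly one row per library variant per
#'   stratum, in library order.
#' @export
complete_with_zeros <- function(table, library) {
  library <- toupper(as.character(library))
  outside <- setdiff(unique(table$sequence), library)
  if (length(outside) > 0) {
    stop("observed sequence(s) outside the library: ",
         paste(head(outside, 5), collapse = ","),
         if (length(outside) > 5) " ..." else "")
  }
  parts <- lapply(group_split_idx(table), function(idx) {
    sub <- table[idx, , drop = FALSE]
    if (anyDuplicated(sub$sequence)) {
      stop("duplicate sequence within one replicate/nonamer stratum")
    }
    missing <- setdiff(library, sub$sequence)
    if (length(missing) > 0) {
      add <- sub[rep(1, length(missing)), , drop = FALSE]
      add$sequence <- missing
      add$count <- 0
      sub <- rbind(sub, add)
    }
    sub[match(library, sub$sequence), , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Average experimental replicates within each nonamer group
#'
#' @param tables A list of read-count data.frames (one per replicate), or a
#'   single data.frame carrying a `replicate` column.
#' @return Read-count data.frame with real-valued mean counts and no
#'   replicate column.
#' @export
average_replicates <- function(tables) {
  if (is.data.frame(tables)) {
    df <- tables
  } else {
    df <- do.call(rbind, lapply(seq_along(tables), function(i) {
      t <- tables[[i]]
      t$replicate <- if (!is.null(t$replicate)) t$replicate else i
      t
    }))
  }
  key_cols <- intersect(c("sequence", "nonamer"), names(df))
  split_key <- interaction(df[key_cols], drop = TRUE)
  n_per <- table(split_key)
  reps <- split(df$replicate, split_key)
  # replicate sets must agree across variants of one nonamer group
  nona <- if (!is.null(df$nonamer)) df$nonamer else ""
  for (g in unique(nona)) {
    sel <- nona == g
    sizes <- table(df$sequence[sel])
    if (length(unique(sizes)) != 1) {
      stop("replicate tables cover mismatched variant sets",
           if (nzchar(g)) paste0(" in nonamer group ", g) else "")
    }
  }
  agg <- aggregate(df["count"], by = df[key_cols], FUN = mean)
  agg <- agg[do.call(order, agg[rev(key_cols)]), c(key_cols, "count")]
  rownames(agg) <- NULL
  agg
}

#' Min-max normalize read counts to a [0,1] efficiency target
#'
#' Dataset-wide mode rescales all counts jointly; nonamer-wise mode rescales
#' independently within each nonamer group, removing the nonamer's global
#' scaling of recombination efficiency.
#'
#' @param table Read-count data.frame.
#' @param mode `"dataset-wide"` or `"nonamer-wise"`.
#' @return The table with an added `target` column in `[0,1]` and attribute
#'   `normalization_mode`.
#' @export
minmax_normalize <- function(table, mode = c("dataset-wide", "nonamer-wise")) {
  mode <- match.arg(mode)
  if (nrow(table) == 0) stop("empty table")
  grp <- if (mode == "nonamer-wise") {
    if (is.null(table$nonamer)) stop("nonamer-wise mode needs a nonamer column")
    table$nonamer
  } else {
    rep("all", nrow(table))
  }
  target <- numeric(nrow(table))
  for (g in unique(grp)) {
    sel <- grp == g
    rng <- range(table$count[sel])
    if (diff(rng) == 0) {
      warning("constant normalization group '", g, "': targets set to 0")
      target[sel] <- 0
    } else {
      target[sel] <- (table$count[sel] - rng[1]) / diff(rng)
    }
  }
  out <- table
  out$target <- target
  attr(out, "normalization_mode") <- mode
  out
}

#' Composition of a completed read-count table
#'
#' Splits the library into variants with counts at or above a threshold,
#' below it but nonzero, and exactly zero, reporting whole-number
#' percentages (round half away from zero, as percentages are quoted to the
#' nearest percent).
#'
#' @param table Completed read-count data.frame.
#' @param threshold Count threshold (default 10 reads).
#' @return List with `pct_at_or_above`, `pct_below`, `pct_zero`, `n`,
#'   `threshold`.
#' @export
summarize_distribution <- function(table, threshold = 10) {
  if (nrow(table) == 0) stop("empty table")
  n <- nrow(table)
  round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
  list(
    pct_at_or_above = round_half_up(100 * sum(table$count >= threshold) / n),
    pct_below = round_half_up(
      100 * sum(table$count > 0 & table$count < threshold) / n),
    pct_zero = round_half_up(100 * sum(table$count == 0) / n),
    n = n, threshold = threshold
  )
}

#' Stratified k-fold rotations
#'
#' Bins the normalized targets (a dedicated zero bin plus quantile bins over
#' the nonzero values), deals each bin's variants across k folds so every
#' fold inherits the dataset's asymmetric target distribution, then forms k
#' rotations of fold roles: rotation r uses fold r for testing, the next
#' fold for validation, and the remaining k-2 folds for training. Across the
#' k rotations each fold serves exactly once as validation and once as test.
#'
#' @param targets Numeric vector of normalized targets (one per variant).
#' @param k Number of folds (and rotations); default 20.
#' @param n_bins Number of quantile bins over the nonzero targets.
#' @param seed Integer seed controlling the within-bin shuffle.
#' @return List with `fold` (integer fold id per variant, 1..k) and
#'   `rotations` (list of k lists with integer index vectors `train`,
#'   `validation`, `test`).
#' @export
stratified_rotations <- function(targets, k = 20, n_bins = 10, seed = 1) {
  if (k < 3) stop("k must be at least 3")
  if (n_bins < 2) stop("n_bins must be at least 2")
  n <- length(targets)
  nonzero <- targets[targets > 0]
  edges <- unique(quantile(nonzero, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- ifelse(targets == 0, 0L,
                cut(targets, breaks = edges, include.lowest = TRUE,
                    labels = FALSE))
  # merge bins too small to spread over k folds into their lower neighbor
  repeat {
    sizes <- table(bin)
    small <- names(sizes)[sizes < k]
    if (length(small) == 0 || length(sizes) <= 1) break
    b <- as.integer(small[length(small)])
    lv <- sort(unique(bin))
    nb <- if (b == min(lv)) lv[2] else max(lv[lv < b])
    warning("stratification bin ", b, " has fewer than k members; ",
            "merged with bin ", nb)
    bin[bin == b] <- nb
  }
  fold <- integer(n)
  set.seed(seed)
  for (b in sort(unique(bin))) {
    idx <- which(bin == b)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  rotations <- lapply(seq_len(k), function(r) {
    test_fold <- r
    val_fold <- if (r == k) 1L else r + 1L
    list(train = which(!fold %in% c(test_fold, val_fold)),
         validation = which(fold == val_fold),
         test = which(fold == test_fold))
  })
  list(fold = fold, rotations = rotations, k = k, seed = seed)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Asymptotic two-sided two-sample KS test (ties, abundant among zero
#' targets, are tolerated; only the statistic and asymptotic p-value are
#' reported).
#'
#' @param a,b Numeric samples.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Serialize fold rotations
#'
#' Writes the per-variant fold assignment as TSV and the rotation role map
#' as JSON.
#'
#' @param rot Result of [stratified_rotations()].
#' @param sequences Variant sequences in target order.
#' @param tsv_path,json_path Output paths.
#' @export
write_rotations <- function(rot, sequences, tsv_path, json_path) {
  write.table(data.frame(sequence = sequences, fold_index = rot$fold),
              tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  roles <- lapply(seq_len(rot$k), function(r) {
    list(test_fold = r, validation_fold = if (r == rot$k) 1L else r + 1L)
  })
  jsonlite::write_json(list(k = rot$k, seed = rot$seed, rotations = roles),
                       json_path, auto_unbox = TRUE)
  invisible(NULL)
}
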