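#' @importFrom stats quantile sd var cov cor ks.test runif rnorm rbinom rnbinom
#'   dnbinom pnbinom lm coef residuals setNames aggregate plogis uniroot hclust
#'   as.dist cutree
#' @importFrom utils read.delim read.table write.table head tail
NULL

#' Position and base-order constants
#'
#' `H4S2_POSITIONS`: labels of the randomized H4-S2 window, 5'->3' on the
#' top strand. `NONAMER_POSITIONS`: the variable nonamer positions encoded
#' by the nonamer-informed model (N4-N7 are shared across the nonamer
#' groups and carry no information). `BASE_ORDER`: base order inside each
#' one-hot block and in feature names (A,T,G,C, the order features are
#' named in, e.g. H4_A, H4_T, H4_G, H4_C). `BASE_LEX`: lexicographic base
#' order used when enumerating libraries.
#'
#' @name constants
#' @export
H4S2_POSITIONS <- c("H4", "H5", "H6", "H7", "S1", "S2")

#' @rdname constants
#' @export
NONAMER_POSITIONS <- c("N1", "N2", "N3", "N8", "N9")

#' @rdname constants
#' @export
BASE_ORDER <- c("A", "T", "G", "C")

#' @rdname constants
#' @export
BASE_LEX <- c("A", "C", "G", "T")

# Full IUPAC ambiguous DNA code table.
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Bases matched by an IUPAC ambiguity code
#'
#' @param code A single IUPAC DNA letter.
#' @return Character vector of the bases the code stands for.
#' @export
iupac_bases <- function(code) {
  code <- toupper(code)
  if (!code %in% names(IUPAC_DNA)) {
    stop("unknown IUPAC code: ", code)
  }
  IUPAC_DNA[[code]]
}

#' IUPAC code for a set of bases
#'
#' Inverse of [iupac_bases()]: maps a base set such as `c("A","G")` to its
#' ambiguity code (`"R"`).
#'
#' @param bases Character vector of bases from `{A,C,G,T}`.
#' @return A single IUPAC letter.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  for (code in names(IUPAC_DNA)) {
    if (identical(sort(IUPAC_DNA[[code]]), bases)) {
      return(code)
    }
  }
  stop("no IUPAC code for base set: ", paste(bases, collapse = ","))
}

check_bases <- function(bases, where = "sequence") {
  bad <- setdiff(unique(bases), BASE_LEX)
  if (length(bad) > 0) {
    stop("invalid base(s) ", paste(bad, collapse = ","), " in ", where)
  }
  invisible(TRUE)
}

#' Enumerate a variant library as the Cartesian product of per-position
#' alphabets
#'
#' Produces every sequence over the given positions, ordered
#' lexicographically by position (first position varies slowest) with base
#' order A < C < G < T. The fully randomized H4-S2 window yields the
#' 4096-member N(H4-S2) library.
#'
#' @param positions Character vector of position labels (e.g.
#'   [H4S2_POSITIONS]).
#' @param alphabets Either a character vector of bases shared by all
#'   positions, or a named list mapping each position to its allowed bases.
#' @return Character vector of sequences; `attr(,"positions")` records the
#'   position labels.
#' @export
enumerate_library <- function(positions = H4S2_POSITIONS,
                              alphabets = BASE_LEX) {
  if (length(positions) == 0) stop("empty position list")
  if (anyDuplicated(positions)) stop("duplicate position labels")
  if (!is.list(alphabets)) {
    alphabets <- setNames(rep(list(alphabets), length(positions)), positions)
  }
  if (is.null(names(alphabets)) && length(alphabets) == length(positions)) {
    names(alphabets) <- positions  # positional alphabet list
  }
  if (!all(positions %in% names(alphabets))) {
    stop("alphabets missing for position(s): ",
         paste(setdiff(positions, names(alphabets)), collapse = ","))
  }
  alpha <- lapply(positions, function(p) {
    a <- toupper(alphabets[[p]])
    if (length(a) == 0) stop("empty alphabet at position ", p)
    bad <- setdiff(a, BASE_LEX)
    if (length(bad) > 0) {
      stop("invalid base(s) ", paste(bad, collapse = ","),
           " at position ", p)
    }
    sort(a)  # A < C < G < T
  })
  # expand.grid varies the first factor fastest; reverse so position 1 is
  # the most significant digit of the lexicographic order.
  grid <- expand.grid(rev(alpha), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(alpha)), drop = FALSE]
  seqs <- do.call(paste0, grid)
  stopifnot(!anyDuplicated(seqs))
  structure(seqs, positions = positions)
}

#' One-hot encode sequences into nucleotide:position binary features
#'
#' Each position contributes a 4-column block named
#' `<position>_A, <position>_T, <position>_G, <position>_C`; exactly one bit
#' per block is set for every sequence.
#'
#' @param seqs Character vector of equal-length sequences over `{A,C,G,T}`.
#' @param positions Position labels, one per sequence character.
#' @return Integer 0/1 matrix, rows named by sequence, columns by feature.
#' @export
one_hot_encode <- function(seqs, positions = H4S2_POSITIONS) {
  if (length(seqs) == 0) stop("no sequences")
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1 || L != length(positions)) {
    stop("sequences must all have length ", length(positions),
         " (one base per position)")
  }
  chars <- do.call(rbind, strsplit(seqs, ""))
  check_bases(as.vector(chars))
  feat_names <- as.vector(t(outer(positions, BASE_ORDER, paste, sep = "_")))
  enc <- matrix(0L, nrow = length(seqs), ncol = length(feat_names),
                dimnames = list(seqs, feat_names))
  for (j in seq_along(positions)) {
    for (b in BASE_ORDER) {
      enc[, paste0(positions[j], "_", b)] <- as.integer(chars[, j] == b)
    }
  }
  enc
}

#' Decode a one-hot matrix back to sequences
#'
#' @param encoding Matrix from [one_hot_encode()].
#' @return Character vector of sequences.
#' @export
one_hot_decode <- function(encoding) {
  feat <- colnames(encoding)
  pos <- unique(sub("_[ATGC]$", "", feat))
  out <- character(nrow(encoding))
  seq_chars <- matrix("", nrow(encoding), length(pos))
  for (j in seq_along(pos)) {
    block <- encoding[, paste0(pos[j], "_", BASE_ORDER), drop = FALSE]
    if (any(rowSums(block) != 1)) {
      stop("invalid one-hot block at position ", pos[j])
    }
    seq_chars[, j] <- BASE_ORDER[max.col(block)]
  }
  apply(seq_chars, 1, paste, collapse = "")
}

#' Select library members matching an IUPAC motif
#'
#' @param library Character vector of sequences (e.g. from
#'   [enumerate_library()]).
#' @param motif String of IUPAC codes, one per position.
#' @return The matching sequences, library order preserved.
#' @export
match_motif <- function(library, motif) {
  motif <- toupper(motif)
  L <- unique(nchar(library))
  if (length(L) != 1 || nchar(motif) != L) {
    stop("motif length must equal library position count (", L, ")")
  }
  codes <- strsplit(motif, "")[[1]]
  keep <- rep(TRUE, length(library))
  chars <- do.call(rbind, strsplit(toupper(library), ""))
  for (j in seq_along(codes)) {
    keep <- keep & chars[, j] %in% iupac_bases(codes[j])
  }
  library[keep]
}

#' The three alignment motifs of a 4-mer within the H4-S2 window
#'
#' Alignment -1 places the 4-mer at H4-H7 (`<kmer>NN`), alignment 0 at
#' H5-S1 (`N<kmer>N`), and alignment +1 at H6-S2 (`NN<kmer>`). Each motif
#' leaves two positions degenerate and so matches 16 sequences of the
#' 4096-member library.
#'
#' @param kmer A 4-base string over `{A,C,G,T}`.
#' @return Named character vector of motifs with names `"-1"`, `"0"`, `"+1"`.
#' @export
kmer_alignments <- function(kmer) {
  kmer <- toupper(kmer)
  if (nchar(kmer) != 4) stop("kmer must have length 4")
  check_bases(strsplit(kmer, "")[[1]], where = "kmer")
  c("-1" = paste0(kmer, "NN"),
    "0"  = paste0("N", kmer, "N"),
    "+1" = paste0("NN", kmer))
}

#' All 256 4-mers over {A,C,G,T}
#'
#' @return Character vector of length 256 in lexicographic order.
#' @export
all_kmers <- function() {
  as.character(enumerate_library(paste0("P", 1:4), BASE_LEX))
}

#' Read/write variant lists
#'
#' `write_variants_tsv()`/`read_variants_tsv()` use a two-column
#' (id, sequence) TSV; `write_variants_fasta()`/`read_variants_fasta()` use
#' FASTA via Biostrings.
#'
#' @param seqs Character vector of sequences; names used as ids (generated
#'   if absent).
#' @param path File path.
#' @return The sequences (readers), invisibly the path (writers).
#' @export
write_variants_tsv <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("v%04d", seq_along(seqs))
  write.table(data.frame(id = ids, sequence = toupper(as.character(seqs))),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence") %in% names(df))) {
    stop("variant TSV must have columns id, sequence")
  }
  setNames(toupper(df$sequence), df$id)
}

#' @rdname write_variants_tsv
#' @export
write_variants_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("v%04d", seq_along(seqs))
  x <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a one-hot encoding matrix as TSV
#'
#' @param encoding Matrix from [one_hot_encode()].
#' @param path File path.
#' @export
write_encoding_tsv <- function(encoding, path) {
  df <- data.frame(sequence = rownames(encoding), encoding,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
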