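#' Enumerate all DNA k-mers in lexicographic order
#'
#' Generates the complete hexamer universe (or k-mer universe for other `k`):
#' all `4^k` words over the alphabet A < C < G < T, from `AAAAAA` to
#' `TTTTTT` for the default `k = 6`. The position of a motif in this vector
#' is the canonical index used by every count vector in the package.
#'
#' @param k Word length in bases. Default 6 (hexamers, `4^6 = 4096` motifs).
#' @return Character vector of length `4^k`, strictly lexicographically
#'   increasing.
#' @examples
#' h <- hexamers()
#' length(h)   # 4096
#' h[1]        # "AAAAAA"
#' h[4096]     # "TTTTTT"
#' @export
hexamers <- function(k = 6L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("'k' must be a single positive integer")
  n <- 4L^k
  idx <- 0:(n - 1L)
  cols <- lapply(seq_len(k), function(j) DNA_BASES[(idx %/% 4L^(k - j)) %% 4L + 1L])
  do.call(paste0, cols)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide sequence to the A/C/G/T/N alphabet
#'
#' Uppercases, converts RNA U to T, and replaces any residual character that
#' is not A, C, G or T (soft-masked bases are kept, ambiguity codes and other
#' symbols are not) with N. Masked or ambiguous positions therefore survive
#' as N rather than being dropped, and downstream window counting skips them.
#'
#' @param x Character vector of sequences.
#' @return Character vector over the alphabet `{A,C,G,T,N}`.
#' @export
normalize_sequence <- function(x) {
  x <- toupper(as.character(x))
  x <- chartr("U", "T", x)
  gsub("[^ACGT]", "N", x)
}

# Integer base-4 codes (A=0 .. T=3, N/other = NA) for one sequence.
.seq_codes <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
}

# Raw k-mer count vector for one normalized sequence. Rolls the base-4
# window index along the sequence; any N in a window propagates NA and the
# window is skipped. Returns list(counts, n_valid_windows).
.count_kmers_one <- function(seq, k) {
  nbin <- 4L^k
  codes <- .seq_codes(seq)
  L <- length(codes)
  if (L < k)
    return(list(counts = integer(nbin), n_valid = 0L))
  idx <- codes[1:(L - k + 1L)]
  for (j in seq_len(k - 1L)) idx <- idx * 4L + codes[(1L + j):(L - k + 1L + j)]
  list(counts = tabulate(idx + 1L, nbins = nbin), n_valid = sum(!is.na(idx)))
}

# Per-sequence count matrix: 4^k rows (motifs, lexicographic) x length(seqs)
# columns. Workhorse shared by aggregation, the resampling null and the
# element scan cross-checks.
.count_matrix <- function(seqs, k = 6L) {
  nbin <- 4L^k
  out <- vapply(seqs, function(s) .count_kmers_one(s, k)$counts,
                integer(nbin), USE.NAMES = FALSE)
  if (is.null(dim(out))) out <- matrix(out, nrow = nbin)
  out
}

new_hexamer_counts <- function(counts, k, n_promoters, n_valid_windows) {
  structure(list(counts = counts, k = as.integer(k),
                 n_promoters = as.integer(n_promoters),
                 n_valid_windows = as.integer(n_valid_windows)),
            class = "hexamer_counts")
}

#' Count overlapping hexamer occurrences in one sequence
#'
#' Slides a width-`k` window in steps of 1 over the given (gene-oriented)
#' sequence and tallies each of the `4^k` motifs. Windows containing any N
#' are excluded from both the counts and the valid-window total, so masked
#' sequence biases neither numerator nor denominator. Counting is on the
#' given strand only; promoters are assumed already oriented 5' to 3'
#' relative to their gene.
#'
#' @param seq A single nucleotide sequence (normalized internally).
#' @param k Word length, default 6.
#' @return A `hexamer_counts` object: named integer vector `counts` of length
#'   `4^k`, plus `n_promoters` (here 1) and `n_valid_windows` (number of
#'   N-free windows; `sum(counts) == n_valid_windows` always). A sequence
#'   shorter than `k` yields an all-zero vector, not an error.
#' @examples
#' ct <- count_hexamers("AAAAAAA")
#' ct$counts[["AAAAAA"]]  # 2 (overlapping windows)
#' ct$n_valid_windows     # 2
#' @export
count_hexamers <- function(seq, k = 6L) {
  if (length(seq) != 1L || !is.character(seq))
    stop("'seq' must be a single character string")
  k <- as.integer(k)
  seq <- normalize_sequence(seq)
  res <- .count_kmers_one(seq, k)
  counts <- res$counts
  names(counts) <- hexamers(k)
  new_hexamer_counts(counts, k, 1L, res$n_valid)
}

#' Aggregate hexamer counts over a promoter set
#'
#' Elementwise sum of per-promoter count vectors for a whole gene set, the
#' quantity that is standardized per 100 promoters in enrichment analysis.
#'
#' @param promoters A [promoter_set] (or character vector of sequences).
#' @param k Word length, default 6.
#' @return A `hexamer_counts` object with `n_promoters = length(promoters)`.
#' @export
aggregate_counts <- function(promoters, k = 6L) {
  seqs <- promoter_seqs(promoters)
  if (length(seqs) == 0L) stop("empty promoter set")
  k <- as.integer(k)
  seqs <- normalize_sequence(seqs)
  m <- .count_matrix(seqs, k)
  counts <- as.integer(round(.rowSums(m, nrow(m), ncol(m))))
  names(counts) <- hexamers(k)
  n_valid <- sum(vapply(seqs, function(s) .count_kmers_one(s, k)$n_valid,
                        integer(1)))
  new_hexamer_counts(counts, k, length(seqs), n_valid)
}

#' @export
print.hexamer_counts <- function(x, ...) {
  cat(sprintf("Hexamer counts (k = %d): %d motifs over %d promoter(s)\n",
              x$k, length(x$counts), x$n_promoters))
  cat(sprintf("  valid windows: %d (sum of counts %d)\n",
              x$n_valid_windows, sum(x$counts)))
  top <- sort(x$counts, decreasing = TRUE)[1:5]
  cat("  most frequent:", paste(sprintf("%s=%d", names(top), top),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Reverse complement of a concrete DNA motif
#'
#' Watson-Crick complement, reversed. Accepts only concrete A/C/G/T motifs;
#' use for hexamer utilities and double-strand scans.
#'
#' @param motif Character vector of ACGT strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("CGTCCA")  # "TGGACG"
#' @export
reverse_complement <- function(motif) {
  if (any(grepl("[^ACGT]", motif)))
    stop("reverse_complement() accepts only A/C/G/T motifs")
  vapply(motif, function(m) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", m), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Reverse complement allowing the full IUPAC alphabet (dictionary patterns).
.iupac_revcomp <- function(motif) {
  vapply(motif, function(m) {
    paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", m),
                       "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
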