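IUPAC_CLASSES <- c(A = "A", C = "C", G = "G", T = "T",
                   R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                   K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                   H = "[ACT]", V = "[ACG]", N = "[ACGT]")

# IUPAC pattern -> regex over the concrete ACGT alphabet. Ambiguity codes in
# the pattern expand to character classes; N in the *subject* never matches,
# which keeps occurrence counts consistent with valid-window counting.
.iupac_regex <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- !chars %in% names(IUPAC_CLASSES)
  if (any(bad))
    stop("invalid IUPAC character(s) in pattern '", pattern, "': ",
         paste(unique(chars[bad]), collapse = ", "))
  paste(IUPAC_CLASSES[chars], collapse = "")
}

#' Load a cis-element dictionary
#'
#' A dictionary maps element names to (possibly IUPAC-degenerate) nucleotide
#' patterns. The bundled default covers named plant cis-elements reported
#' for DREB-type transcription factors — DRE and DRE-like motifs, ARR1AT,
#' MYBST1, BOXIII, the novel CGTCCA (New3) and TTCTCT (New4) elements, the
#' AT-rich hexamers recurrent in lignin and sugar-metabolism gene promoters,
#' and classical bait elements (GCC-box, ABRE, MYBCORE, AuxRR-core, CE3).
#' Entries whose exact sequence is not established are sourced
#' "external-literature, editable" or carry an all-N placeholder; edit the
#' TSV (columns `name`, `motif`, `source`) to refine them.
#'
#' @param path TSV path; default the dictionary bundled with the package.
#' @param include_placeholders Keep all-N placeholder entries (default
#'   FALSE: an all-N pattern matches every window, so placeholders are
#'   dropped from matching until a real sequence is filled in).
#' @return Data frame of class `element_dictionary` with columns `name`
#'   (unique), `motif` (validated IUPAC) and `source`.
#' @export
element_dictionary <- function(path = system.file("extdata",
                                                  "cis_elements.tsv",
                                                  package = "promhex"),
                               include_placeholders = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("name", "motif", "source")
  if (!all(need %in% names(df)))
    stop("dictionary must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("duplicate element names in dictionary: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  df$motif <- toupper(df$motif)
  for (m in df$motif) .iupac_regex(m)  # validates; errors at load time
  if (!include_placeholders)
    df <- df[!grepl("^N+$", df$motif), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("element_dictionary", "data.frame")
  df
}

#' @export
print.element_dictionary <- function(x, ...) {
  cat(sprintf("Cis-element dictionary: %d entries\n", nrow(x)))
  print.data.frame(x)
  invisible(x)
}

#' Annotate a hexamer with matching known cis-elements
#'
#' An element matches a hexamer if its IUPAC pattern equals the hexamer
#' (same length) or is contained anywhere within it (shorter patterns such
#' as the 5-mer BOXIII `CATTT` match at any offset). Patterns longer than
#' the hexamer never match.
#'
#' @param motif A single concrete A/C/G/T motif.
#' @param dictionary An [element_dictionary()].
#' @return Character vector of matching element names (possibly empty).
#' @examples
#' dict <- element_dictionary()
#' annotate_hexamer("TATCCC", dict)  # MYBST1
#' annotate_hexamer("CATTTT", dict)  # includes BOXIII via contained CATTT
#' @export
annotate_hexamer <- function(motif, dictionary) {
  stopifnot(length(motif) == 1L)
  if (grepl("[^ACGT]", motif))
    stop("'motif' must be a concrete A/C/G/T string")
  hits <- vapply(dictionary$motif,
                 function(p) nchar(p) <= nchar(motif) &&
                   grepl(.iupac_regex(p), motif), logical(1))
  dictionary$name[hits]
}

# Vectorized annotation: one comma-separated string per motif (used to fill
# the enrichment table's `elements` column over all 4096 hexamers).
annotate_hexamers <- function(motifs, dictionary) {
  out <- rep("", length(motifs))
  for (i in seq_len(nrow(dictionary))) {
    p <- dictionary$motif[i]
    if (nchar(p) > nchar(motifs[1])) next
    hit <- grepl(.iupac_regex(p), motifs)
    out[hit] <- ifelse(nzchar(out[hit]),
                       paste(out[hit], dictionary$name[i], sep = ","),
                       dictionary$name[i])
  }
  out
}

# All overlapping match start positions (0-based) of an IUPAC pattern in one
# normalized sequence; lookahead regex so overlapping hits are all found.
.match_positions <- function(seq, pattern_regex) {
  m <- gregexpr(paste0("(?=", pattern_regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan gene-set promoters for cis-element occurrences
#'
#' IUPAC-aware overlapping occurrence counts of every dictionary element in
#' every promoter, plus per-element summaries: how many genes carry at least
#' one hit and the fraction of genes with a hit. Windows containing N never
#' match. With `both_strands = TRUE`, occurrences of each pattern's reverse
#' complement are added (self-reverse-complementary matches are counted once
#' per strand orientation they occur in).
#'
#' @param promoters A [promoter_set] (non-empty).
#' @param elements An [element_dictionary()] (non-empty).
#' @param both_strands Also count reverse-complement pattern occurrences
#'   (default FALSE; promoters are already gene-oriented).
#' @return An `element_occurrences` object: list with `counts` (genes x
#'   elements integer matrix), `summary` (data frame: `element`, `motif`,
#'   `total_occurrences`, `genes_with_hit`, `fraction_with_hit`),
#'   and `matches` (data frame of individual hits: `gene_id`, `element`,
#'   `start`, `end` promoter-local 0-based half-open, `strand` of the
#'   matched pattern orientation).
#' @export
scan_geneset <- function(promoters, elements, both_strands = FALSE) {
  if (!inherits(promoters, "promoter_set") || nrow(promoters) == 0L)
    stop("empty promoter set")
  if (!inherits(elements, "element_dictionary") || nrow(elements) == 0L)
    stop("empty element dictionary")
  genes <- promoters$gene_id
  seqs <- promoters$seq
  nm <- elements$name
  counts <- matrix(0L, nrow = length(genes), ncol = length(nm),
                   dimnames = list(genes, nm))
  match_list <- vector("list", 0)
  for (j in seq_along(nm)) {
    pat <- elements$motif[j]
    w <- nchar(pat)
    orientations <- list(c(.iupac_regex(pat), "+"))
    if (both_strands) {
      rc <- .iupac_revcomp(pat)
      orientations <- c(orientations, list(c(.iupac_regex(rc), "-")))
    }
    for (ori in orientations) {
      for (i in seq_along(seqs)) {
        pos <- .match_positions(seqs[i], ori[1])
        if (length(pos)) {
          counts[i, j] <- counts[i, j] + length(pos)
          match_list[[length(match_list) + 1L]] <-
            data.frame(gene_id = genes[i], element = nm[j], start = pos,
                       end = pos + w, strand = ori[2],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  matches <- if (length(match_list)) do.call(rbind, match_list)
    else data.frame(gene_id = character(), element = character(),
                    start = integer(), end = integer(),
                    strand = character(), stringsAsFactors = FALSE)
  with_hit <- colSums(counts > 0L)
  summary <- data.frame(element = nm, motif = elements$motif,
                        total_occurrences = colSums(counts),
                        genes_with_hit = as.integer(with_hit),
                        fraction_with_hit = with_hit / length(genes),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(counts = counts, summary = summary, matches = matches,
                 n_genes = length(genes), both_strands = both_strands),
            class = "element_occurrences")
}

#' @export
print.element_occurrences <- function(x, ...) {
  cat(sprintf("Element occurrences: %d gene(s) x %d element(s)%s\n",
              x$n_genes, ncol(x$counts),
              if (x$both_strands) " (both strands)" else ""))
  print(x$summary[order(-x$summary$fraction_with_hit), ], row.names = FALSE)
  invisible(x)
}

#' Write element-scan outputs
#'
#' `write_occurrence_tsv()` writes the per-element summary plus the
#' gene-by-element count matrix; `write_match_bed()` writes each individual
#' match as a BED6 interval in promoter-local 0-based coordinates (the
#' "chromosome" is the gene ID).
#'
#' @param occurrences An `element_occurrences` from [scan_geneset()].
#' @param path Output path.
#' @export
write_occurrence_tsv <- function(occurrences, path) {
  long <- data.frame(gene_id = rep(rownames(occurrences$counts),
                                   ncol(occurrences$counts)),
                     element = rep(colnames(occurrences$counts),
                                   each = nrow(occurrences$counts)),
                     count = as.vector(occurrences$counts),
                     stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrence_tsv
#' @export
write_match_bed <- function(occurrences, path) {
  m <- occurrences$matches
  bed <- data.frame(m$gene_id, m$start, m$end, m$element, 0L, m$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
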