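#' Construct a promoter set
#'
#' A `promoter_set` is a data frame with one row per gene promoter: the
#' gene-oriented (5' to 3') sequence plus its provenance on the forward
#' genomic strand. All coordinates are 0-based half-open, so
#' `end - start == nchar(seq)` always, including truncated windows.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param seq Nucleotide sequences (normalized to A/C/G/T/N on construction).
#'   For minus-strand genes this is the reverse complement of the forward
#'   genomic slice `[start, end)`.
#' @param chrom Source chromosome/contig names (NA if unknown).
#' @param start,end 0-based half-open window on the forward genomic strand.
#' @param strand `"+"` or `"-"`.
#' @param truncated Logical; TRUE where the window was clipped at a
#'   chromosome edge and is shorter than requested.
#' @return A data frame of class `promoter_set`.
#' @export
promoter_set <- function(gene_id, seq, chrom = NA_character_,
                         start = NA_integer_, end = NA_integer_,
                         strand = "+", truncated = FALSE) {
  seq <- normalize_sequence(seq)
  df <- data.frame(gene_id = as.character(gene_id), seq = seq,
                   chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), strand = as.character(strand),
                   truncated = as.logical(truncated),
                   stringsAsFactors = FALSE)
  bad <- !is.na(df$start) & !is.na(df$end) &
    (df$end - df$start) != nchar(df$seq)
  if (any(bad))
    stop("window length (end - start) disagrees with sequence length for: ",
         paste(utils::head(df$gene_id[bad], 5), collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  class(df) <- c("promoter_set", "data.frame")
  df
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("Promoter set: %d promoter(s), lengths %d-%d bp%s\n",
              nrow(x), min(nchar(x$seq)), max(nchar(x$seq)),
              if (any(x$truncated)) sprintf(" (%d truncated)",
                                            sum(x$truncated)) else ""))
  print.data.frame(utils::head(
    data.frame(x[setdiff(names(x), "seq")],
               seq = paste0(substr(x$seq, 1, 24), "...")), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

# Sequence accessor: accepts a promoter_set or a plain character vector.
promoter_seqs <- function(x) {
  if (inherits(x, "promoter_set")) return(x$seq)
  if (is.character(x)) return(unname(x))
  stop("expected a promoter_set or a character vector of sequences")
}

#' Extract TSS-anchored promoters from a genome and annotation
#'
#' Takes the `window_len` bases immediately upstream of each gene's 5' end:
#' for a plus-strand gene with 1-based start S the window is 1-based
#' `[S - window_len, S - 1]` (positions -window_len .. -1 relative to the
#' TSS); for a minus-strand gene with 1-based end E it is `[E + 1,
#' E + window_len]` reverse-complemented, so every promoter reads 5' to 3'
#' relative to its gene. Windows running off a chromosome edge are clipped
#' to their actual length and flagged `truncated`. One record per gene; the
#' gene-level feature defines the TSS.
#'
#' @param genome Path to a genome FASTA, or a [Biostrings::DNAStringSet].
#'   FASTA headers are trimmed to their first whitespace-separated token.
#' @param annotation Path to a GFF3 or BED file of gene features (format
#'   inferred from the extension, or set `format`). GFF3 rows are filtered
#'   to `feature`; gene IDs come from the first available of `id_attr`.
#' @param window_len Promoter length in bases upstream of the TSS
#'   (default 1000, the classical "-1 to -1000" window).
#' @param feature GFF3 feature type to keep (default `"gene"`). Ignored
#'   for BED.
#' @param id_attr GFF3 attribute keys tried in order for the gene ID.
#' @param format `"auto"`, `"gff3"` or `"bed"`.
#' @param overlap_filter If TRUE, drop genes whose promoter window overlaps
#'   another annotated gene body on either strand (off by default).
#' @return A [promoter_set]. Genes skipped for missing strand are dropped
#'   with one warning; their IDs are in `attr(result, "skipped")`.
#' @export
extract_promoters <- function(genome, annotation, window_len = 1000L,
                              feature = "gene",
                              id_attr = c("ID", "locus_tag", "Name"),
                              format = c("auto", "gff3", "bed"),
                              overlap_filter = FALSE) {
  window_len <- as.integer(window_len)
  if (window_len < 1L) stop("'window_len' must be positive")
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))

  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", annotation, ignore.case = TRUE))
      "bed" else "gff3"
  gr <- rtracklayer::import(annotation,
                            format = if (format == "bed") "BED" else "GFF3")
  ann <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),   # 1-based
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (format == "gff3") {
    if ("type" %in% names(mc)) {
      keep <- as.character(mc$type) == feature
      ann <- ann[keep, , drop = FALSE]
      mc <- mc[keep, , drop = FALSE]
    }
    id <- rep(NA_character_, nrow(ann))
    for (key in id_attr) {
      if (key %in% names(mc)) {
        val <- as.character(mc[[key]])
        id[is.na(id) & !is.na(val)] <- val[is.na(id) & !is.na(val)]
      }
    }
    ann$gene_id <- id
  } else {
    ann$gene_id <- if ("name" %in% names(mc)) as.character(mc$name)
      else paste0("gene", seq_len(nrow(ann)))
  }
  if (nrow(ann) == 0L) stop("no '", feature, "' features in annotation")

  missing_chr <- setdiff(unique(ann$chrom), names(genome))
  if (length(missing_chr) > 0L)
    stop("annotation references chromosome(s) absent from the genome: ",
         paste(missing_chr, collapse = ", "))

  skipped <- ann$gene_id[!ann$strand %in% c("+", "-")]
  if (length(skipped) > 0L) {
    warning(length(skipped), " gene(s) without strand skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "))
    ann <- ann[ann$strand %in% c("+", "-"), , drop = FALSE]
  }

  # 0-based half-open promoter windows on the forward strand
  p_start <- ifelse(ann$strand == "+", ann$start - 1L - window_len, ann$end)
  p_end   <- ifelse(ann$strand == "+", ann$start - 1L, ann$end + window_len)
  clip_s <- pmax(p_start, 0)
  clip_e <- pmin(p_end, chrom_len[ann$chrom])
  keep <- clip_e > clip_s
  if (!all(keep)) {
    skipped <- c(skipped, ann$gene_id[!keep])
    warning(sum(!keep), " gene(s) with empty promoter window skipped")
  }
  ann <- ann[keep, , drop = FALSE]
  clip_s <- clip_s[keep]; clip_e <- clip_e[keep]
  truncated <- (clip_e - clip_s) < window_len

  if (overlap_filter) {
    body <- GenomicRanges::GRanges(ann$chrom,
                                   IRanges::IRanges(ann$start, ann$end))
    win <- GenomicRanges::GRanges(ann$chrom,
                                  IRanges::IRanges(clip_s + 1L, clip_e))
    hits <- GenomicRanges::countOverlaps(win, body, ignore.strand = TRUE)
    keep2 <- hits == 0L
    ann <- ann[keep2, , drop = FALSE]
    clip_s <- clip_s[keep2]; clip_e <- clip_e[keep2]
    truncated <- truncated[keep2]
  }

  seqs <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    sl <- Biostrings::subseq(genome[[ann$chrom[i]]],
                             start = clip_s[i] + 1L, end = clip_e[i])
    if (ann$strand[i] == "-") sl <- Biostrings::reverseComplement(sl)
    seqs[i] <- as.character(sl)
  }
  out <- promoter_set(gene_id = ann$gene_id, seq = seqs, chrom = ann$chrom,
                      start = clip_s, end = clip_e, strand = ann$strand,
                      truncated = truncated)
  attr(out, "skipped") <- as.character(skipped)
  out
}

#' Read a ranked gene list
#'
#' One identifier per line, most significant first (e.g. up-regulated genes
#' ranked by differential-expression evidence). Blank lines and `#` comments
#' are ignored; duplicates are dropped keeping the first occurrence; an
#' optional cap retains only the head of the ranking (the "top 100
#' up-regulated genes" convention).
#'
#' @param path Path to the gene list file.
#' @param max_genes Optional integer cap applied after de-duplication.
#' @param name Label for the set (default: file name without extension).
#' @return A `gene_set`: list with `name`, `gene_ids` (ordered, unique) and
#'   `max_genes`.
#' @export
read_gene_list <- function(path, max_genes = NULL, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  ids <- lines[nzchar(lines)]
  ids <- ids[!duplicated(ids)]
  if (length(ids) == 0L) stop("empty gene set: ", path)
  if (!is.null(max_genes)) {
    if (max_genes < 1L) stop("'max_genes' must be positive")
    ids <- utils::head(ids, max_genes)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_set(ids, name = name, max_genes = max_genes)
}

#' @rdname read_gene_list
#' @param gene_ids Character vector of identifiers (ordered, duplicates
#'   dropped keeping first occurrence).
#' @export
gene_set <- function(gene_ids, name = "geneset", max_genes = NULL) {
  gene_ids <- as.character(gene_ids[!duplicated(gene_ids)])
  if (!is.null(max_genes)) gene_ids <- utils::head(gene_ids, max_genes)
  structure(list(name = name, gene_ids = gene_ids,
                 max_genes = if (is.null(max_genes)) NA_integer_
                             else as.integer(max_genes)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d gene(s)%s\n", x$name, length(x$gene_ids),
              if (!is.na(x$max_genes)) sprintf(" (cap %d)", x$max_genes)
              else ""))
  cat(" ", paste(utils::head(x$gene_ids, 8), collapse = ", "),
      if (length(x$gene_ids) > 8) "..." else "", "\n")
  invisible(x)
}

#' Subset a promoter set to the genes of a gene set
#'
#' @param promoters A [promoter_set].
#' @param genes A `gene_set` or character vector of gene IDs.
#' @param strict Error if some requested genes have no promoter (default
#'   TRUE; otherwise they are silently dropped).
#' @return A [promoter_set] in the gene-set order.
#' @export
promoters_for_genes <- function(promoters, genes, strict = TRUE) {
  ids <- if (inherits(genes, "gene_set")) genes$gene_ids
         else as.character(genes)
  hit <- match(ids, promoters$gene_id)
  if (anyNA(hit)) {
    if (strict)
      stop(sum(is.na(hit)), " gene(s) have no promoter record, e.g. ",
           paste(utils::head(ids[is.na(hit)], 3), collapse = ", "))
    hit <- hit[!is.na(hit)]
  }
  out <- promoters[hit, , drop = FALSE]
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Write / read a promoter FASTA
#'
#' Headers carry provenance as `gene_id chrom:start-end(strand)` with
#' 0-based half-open coordinates; `read_promoter_fasta()` parses them back
#' when present so a write/read round trip reproduces the set.
#'
#' @param promoters A [promoter_set].
#' @param path Output (or input) FASTA path.
#' @param width Line-wrap width for sequences.
#' @return `write_promoter_fasta()` returns `path` invisibly;
#'   `read_promoter_fasta()` returns a [promoter_set].
#' @export
write_promoter_fasta <- function(promoters, path, width = 70L) {
  hdr <- ifelse(is.na(promoters$chrom),
                promoters$gene_id,
                sprintf("%s %s:%d-%d(%s)", promoters$gene_id,
                        promoters$chrom, promoters$start, promoters$end,
                        promoters$strand))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(promoters))) {
    writeLines(paste0(">", hdr[i]), con)
    s <- promoters$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_promoter_fasta
#' @export
read_promoter_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  gene_id <- sub("\\s.*$", "", hdr)
  loc <- regmatches(hdr,
                    regexpr("\\S+:\\d+-\\d+\\([+-]\\)$", hdr))
  has_loc <- grepl("\\S+:\\d+-\\d+\\([+-]\\)$", hdr)
  chrom <- rep(NA_character_, length(hdr))
  start <- rep(NA_integer_, length(hdr))
  end <- rep(NA_integer_, length(hdr))
  strand <- rep("+", length(hdr))
  if (any(has_loc)) {
    parts <- regmatches(hdr[has_loc],
                        regexec("(\\S+):(\\d+)-(\\d+)\\(([+-])\\)$",
                                hdr[has_loc]))
    chrom[has_loc] <- vapply(parts, `[`, "", 2)
    start[has_loc] <- as.integer(vapply(parts, `[`, "", 3))
    end[has_loc] <- as.integer(vapply(parts, `[`, "", 4))
    strand[has_loc] <- vapply(parts, `[`, "", 5)
  }
  promoter_set(gene_id = gene_id, seq = as.character(ss), chrom = chrom,
               start = start, end = end, strand = strand,
               truncated = FALSE)
}
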