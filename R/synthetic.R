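#' Configuration for the synthetic promoter generator
#'
#' Defines a synthetic study: a background universe of iid-composition
#' promoters standing in for a genome-wide promoter set, and (via
#' [generate_geneset()]) focal gene sets whose promoters carry planted
#' motifs at known rates. Defaults mirror the scale of a genome-wide
#' promoter enrichment study: 5000 background promoters of 1000 bp with
#' uniform base composition.
#'
#' @param n_background Number of background promoters (default 5000).
#' @param promoter_len Promoter length in bp (default 1000).
#' @param base_probs Named probabilities for A, C, G, T (must sum to 1;
#'   default uniform).
#' @param seed Integer seed; every downstream draw is a function of it.
#' @param n_frac Fraction of promoter bases replaced by N (default 0),
#'   emulating masked sequence.
#' @param markov_order 0 for iid bases (default) or 1 for a first-order
#'   Markov chain (stationary transitions biased toward the previous base)
#'   to stress-test robustness to local composition structure.
#' @param n_truncated Number of background genes given edge-truncated
#'   promoters (default 0); used to exercise window clipping.
#' @param truncated_len Length of those truncated promoters (default 400).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_background = 5000L, promoter_len = 1000L,
                         base_probs = c(A = 0.25, C = 0.25, G = 0.25,
                                        T = 0.25),
                         seed = 1L, n_frac = 0, markov_order = 0L,
                         n_truncated = 0L, truncated_len = 400L) {
  if (length(base_probs) != 4L || abs(sum(base_probs) - 1) > 1e-12 ||
      any(base_probs < 0))
    stop("'base_probs' must be 4 non-negative values summing to 1")
  names(base_probs) <- DNA_BASES
  if (n_frac < 0 || n_frac >= 1) stop("'n_frac' must be in [0, 1)")
  if (!markov_order %in% c(0L, 1L)) stop("'markov_order' must be 0 or 1")
  if (n_truncated > 0 && truncated_len >= promoter_len)
    stop("'truncated_len' must be shorter than 'promoter_len'")
  structure(list(n_background = as.integer(n_background),
                 promoter_len = as.integer(promoter_len),
                 base_probs = base_probs, seed = as.integer(seed),
                 n_frac = n_frac, markov_order = as.integer(markov_order),
                 n_truncated = as.integer(n_truncated),
                 truncated_len = as.integer(truncated_len)),
            class = "synth_config")
}

# One random sequence under the config's composition model. Assumes the RNG
# has already been seeded by the caller.
.random_seq <- function(len, config) {
  if (config$markov_order == 0L) {
    s <- sample(DNA_BASES, len, replace = TRUE, prob = config$base_probs)
  } else {
    # sticky first-order chain: stay on the previous base with weight 2
    s <- character(len)
    s[1] <- sample(DNA_BASES, 1, prob = config$base_probs)
    for (i in 2:len) {
      p <- config$base_probs
      p[s[i - 1]] <- p[s[i - 1]] * 2
      s[i] <- sample(DNA_BASES, 1, prob = p / sum(p))
    }
  }
  if (config$n_frac > 0) {
    nn <- stats::rbinom(1, len, config$n_frac)
    if (nn > 0) s[sample.int(len, nn)] <- "N"
  }
  paste(s, collapse = "")
}

#' Generate a synthetic background promoter universe
#'
#' Draws `n_background` promoters under the configured composition model and
#' embeds them in a synthetic multi-contig genome with a BED gene annotation
#' constructed so that [extract_promoters()] on the genome + annotation
#' reproduces the generated promoter sequences exactly — including
#' minus-strand genes (every other gene) and optional edge-truncated
#' promoters. Deterministic under `config$seed`.
#'
#' @param config A [synth_config()].
#' @param dir Optional directory; when given, writes `genome.fa`,
#'   `genes.bed` and `promoters.fa` there.
#' @param genes_per_contig Genes placed per synthetic contig (default 50).
#' @return List with `promoters` (the ground-truth [promoter_set], gene IDs
#'   `bg00001`...), `genome` (named character vector of contig sequences),
#'   `annotation` (BED6 data frame of gene bodies) and, if `dir` was given,
#'   `paths`.
#' @export
generate_background <- function(config, dir = NULL, genes_per_contig = 50L) {
  stopifnot(inherits(config, "synth_config"))
  old <- .preserve_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)

  n <- config$n_background
  wl <- config$promoter_len
  ids <- sprintf("bg%05d", seq_len(n))
  plen <- rep(wl, n)
  if (config$n_truncated > 0)
    plen[seq_len(min(config$n_truncated, n))] <- config$truncated_len
  pseq <- vapply(plen, .random_seq, "", config = config)

  # contig layout: [gap][promoter][body] for + genes,
  #                [gap][body][rc(promoter)] for - genes (alternating).
  # Truncated genes each get a dedicated contig with the promoter flush at
  # the contig edge (start for +, end for -), so clipping the standard
  # window there reproduces exactly the shortened ground-truth sequence.
  strand <- rep(c("+", "-"), length.out = n)
  gap_len <- 20L; body_len <- 30L
  is_trunc <- plen < wl
  contig_of <- integer(n)
  contig_of[is_trunc] <- seq_len(sum(is_trunc))
  contig_of[!is_trunc] <- sum(is_trunc) +
    (seq_len(sum(!is_trunc)) - 1L) %/% genes_per_contig + 1L
  n_contig <- max(contig_of)
  contigs <- character(n_contig)
  chrom <- sprintf("ctg%03d", contig_of)
  g_start0 <- integer(n); g_end0 <- integer(n)
  p_start0 <- integer(n); p_end0 <- integer(n)
  for (ci in seq_len(n_contig)) {
    parts <- character(0)
    cursor <- 0L
    for (i in which(contig_of == ci)) {
      gap <- if (is_trunc[i]) 0L else gap_len
      gap_seq <- if (gap > 0) .random_seq(gap, config) else ""
      body_seq <- .random_seq(body_len, config)
      if (strand[i] == "+") {
        p_start0[i] <- cursor + gap
        p_end0[i] <- p_start0[i] + plen[i]
        g_start0[i] <- p_end0[i]
        g_end0[i] <- g_start0[i] + body_len
        parts <- c(parts, gap_seq, pseq[i], body_seq)
        cursor <- g_end0[i]
      } else {
        g_start0[i] <- cursor + gap
        g_end0[i] <- g_start0[i] + body_len
        p_start0[i] <- g_end0[i]
        p_end0[i] <- p_start0[i] + plen[i]
        parts <- c(parts, gap_seq, body_seq,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(pseq[i]))))
        cursor <- p_end0[i]
      }
    }
    contigs[ci] <- paste(parts, collapse = "")
  }
  names(contigs) <- sprintf("ctg%03d", seq_len(n_contig))

  promoters <- promoter_set(gene_id = ids, seq = pseq, chrom = chrom,
                            start = p_start0, end = p_end0, strand = strand,
                            truncated = plen < wl)
  annotation <- data.frame(chrom = chrom, start = g_start0, end = g_end0,
                           name = ids, score = 0L, strand = strand,
                           stringsAsFactors = FALSE)
  out <- list(promoters = promoters, genome = contigs,
              annotation = annotation, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  annotation = file.path(dir, "genes.bed"),
                  promoters = file.path(dir, "promoters.fa"))
    gss <- Biostrings::DNAStringSet(contigs)
    Biostrings::writeXStringSet(gss, paths$genome)
    utils::write.table(annotation, paths$annotation, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_promoter_fasta(promoters, paths$promoters)
    out$paths <- paths
  }
  out
}

#' Generate a focal gene set with planted motifs
#'
#' Draws `n_genes` fresh promoters from the same composition model as the
#' background, then overwrites `copies` non-overlapping, uniformly chosen
#' positions per promoter with the given motif (planting replaces bases
#' rather than inserting, so promoter length — and hence window counts —
#' stays fixed). With `copies = 0` the set is statistically
#' indistinguishable from background, the null-calibration fixture. Planted
#' positions are recorded as ground truth.
#'
#' @param config A [synth_config()].
#' @param motif Concrete A/C/G/T motif to plant (ignored if `copies = 0`).
#' @param n_genes Number of focal genes (default 100, the conventional
#'   top-ranked gene-set size).
#' @param copies Planted copies per promoter (default 1).
#' @param name Gene-set label.
#' @param seed Seed for this set's draws (default `config$seed + 1` so the
#'   focal set is independent of the background under the same config).
#' @param dir Optional directory; writes `<name>_promoters.fa`,
#'   `<name>_genes.txt` and `<name>_truth.json`.
#' @return List with `gene_set`, `promoters` (a [promoter_set]; gene IDs
#'   `<name>_g0001`...), and `planted` (data frame `gene_id`, `motif`,
#'   `start`, `end`, 0-based half-open promoter-local coordinates).
#' @export
generate_geneset <- function(config, motif = "CGTCCA", n_genes = 100L,
                             copies = 1L, name = "focal",
                             seed = config$seed + 1L, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  copies <- as.integer(copies)
  n_genes <- as.integer(n_genes)
  if (copies < 0L) stop("'copies' must be >= 0")
  wl <- config$promoter_len
  mw <- nchar(motif)
  if (copies > 0L) {
    if (grepl("[^ACGT]", motif))
      stop("'motif' must be a concrete A/C/G/T string")
    if (copies * mw > wl)
      stop("cannot place ", copies, " non-overlapping copies of a ", mw,
           "-mer in a ", wl, "-bp promoter")
  }
  old <- .preserve_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  ids <- sprintf("%s_g%04d", name, seq_len(n_genes))
  seqs <- character(n_genes)
  planted <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    s <- .random_seq(wl, config)
    if (copies > 0L) {
      pos <- .place_nonoverlapping(wl, mw, copies)
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      for (p in pos) chars[(p + 1):(p + mw)] <- strsplit(motif, "",
                                                         fixed = TRUE)[[1]]
      s <- paste(chars, collapse = "")
      planted[[i]] <- data.frame(gene_id = ids[i], motif = motif,
                                 start = pos, end = pos + mw,
                                 stringsAsFactors = FALSE)
    }
    seqs[i] <- s
  }
  planted <- if (copies > 0L) do.call(rbind, planted)
    else data.frame(gene_id = character(), motif = character(),
                    start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  promoters <- promoter_set(gene_id = ids, seq = seqs)
  gs <- gene_set(ids, name = name)
  out <- list(gene_set = gs, promoters = promoters, planted = planted,
              motif = motif, copies = copies, seed = as.integer(seed))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      promoters = file.path(dir, paste0(name, "_promoters.fa")),
      genes = file.path(dir, paste0(name, "_genes.txt")),
      truth = file.path(dir, paste0(name, "_truth.json")))
    write_promoter_fasta(promoters, paths$promoters)
    writeLines(ids, paths$genes)
    jsonlite::write_json(list(seed = out$seed, motif = motif,
                              copies = copies, planted = planted),
                         paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

# `copies` non-overlapping 0-based start positions for a width-`mw` motif in
# a length-`wl` window, uniform by rejection; errors if placement fails.
.place_nonoverlapping <- function(wl, mw, copies) {
  for (try in 1:1000) {
    pos <- sort(sample.int(wl - mw + 1L, copies) - 1L)
    if (copies == 1L || all(diff(pos) >= mw)) return(pos)
  }
  stop("could not place ", copies, " non-overlapping copies after 1000 tries")
}
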