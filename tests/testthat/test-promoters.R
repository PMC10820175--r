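# Tiny two-contig genome written in code; gene slots chosen so promoter
# windows are fully predictable.
make_test_genome <- function(dir) {
  set.seed(99)
  ctgA <- random_seq(4000)
  ctgB <- random_seq(600)
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">ctgA extra header words", ctgA, ">ctgB", ctgB), fa)
  list(fa = fa, ctgA = ctgA, ctgB = ctgB)
}

rc_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("plus-strand promoters cover -1000..-1 relative to the gene start", {
  dir <- withr::local_tempdir()
  g <- make_test_genome(dir)
  bed <- file.path(dir, "genes.bed")
  # gene at 1-based start 2001 => BED start 2000; promoter = 0-based [1000, 2000)
  write.table(data.frame("ctgA", 2000L, 2400L, "gplus", 0L, "+"),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  ps <- extract_promoters(g$fa, bed, window_len = 1000)
  expect_identical(nrow(ps), 1L)
  expect_identical(ps$seq, substr(g$ctgA, 1001, 2000))
  expect_identical(ps$start, 1000)
  expect_identical(ps$end, 2000)
  expect_false(ps$truncated)
})

test_that("minus-strand promoters are downstream slices, reverse-complemented,
           and clipped at contig edges", {
  dir <- withr::local_tempdir()
  g <- make_test_genome(dir)
  bed <- file.path(dir, "genes.bed")
  # gene ending at 1-based 500 on a 600-bp contig: promoter 1-based [501, 600],
  # truncated to 100 bp, reverse complement
  write.table(data.frame("ctgB", 100L, 500L, "gminus", 0L, "-"),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  ps <- extract_promoters(g$fa, bed, window_len = 1000)
  expect_identical(nchar(ps$seq), 100L)
  expect_true(ps$truncated)
  expect_identical(ps$seq, rc_chr(substr(g$ctgB, 501, 600)))
})

test_that("GFF3 gene features are extracted with configurable ID attribute", {
  dir <- withr::local_tempdir()
  g <- make_test_genome(dir)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               "ctgA\tsrc\tgene\t2001\t2400\t.\t+\t.\tID=geneX;Name=alias",
               "ctgA\tsrc\tmRNA\t2001\t2400\t.\t+\t.\tID=geneX.1",
               "ctgA\tsrc\tgene\t3001\t3200\t.\t-\t.\tID=geneY"),
             gff)
  ps <- extract_promoters(g$fa, gff, window_len = 500)
  expect_setequal(ps$gene_id, c("geneX", "geneY"))
  px <- ps[ps$gene_id == "geneX", ]
  expect_identical(px$seq, substr(g$ctgA, 1501, 2000))
  py <- ps[ps$gene_id == "geneY", ]
  expect_identical(py$seq, rc_chr(substr(g$ctgA, 3201, 3700)))
})

test_that("missing chromosomes error by name; strandless genes are skipped
           with a warning", {
  dir <- withr::local_tempdir()
  g <- make_test_genome(dir)
  bed <- file.path(dir, "genes.bed")
  write.table(data.frame("ctgZ", 2000L, 2400L, "glost", 0L, "+"),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_error(extract_promoters(g$fa, bed), "ctgZ")

  gff <- file.path(dir, "nostrand.gff3")
  writeLines(c("##gff-version 3",
               "ctgA\tsrc\tgene\t2001\t2400\t.\t+\t.\tID=ok",
               "ctgA\tsrc\tgene\t3001\t3200\t.\t.\t.\tID=nostrand"),
             gff)
  expect_warning(ps <- extract_promoters(g$fa, gff, window_len = 200),
                 "without strand")
  expect_identical(ps$gene_id, "ok")
  expect_identical(attr(ps, "skipped"), "nostrand")
})

test_that("promoter FASTA write/read round-trips gene IDs, sequences and
           provenance", {
  dir <- withr::local_tempdir()
  set.seed(5)
  ps <- promoter_set(gene_id = c("a", "b"),
                     seq = c(random_seq(150), random_seq(90)),
                     chrom = c("c1", "c2"), start = c(10, 0),
                     end = c(160, 90), strand = c("+", "-"))
  fa <- file.path(dir, "prom.fa")
  write_promoter_fasta(ps, fa)
  back <- read_promoter_fasta(fa)
  expect_identical(back$gene_id, ps$gene_id)
  expect_identical(back$seq, ps$seq)
  expect_identical(back$chrom, ps$chrom)
  expect_equal(back$start, ps$start)
  expect_equal(back$end, ps$end)
  expect_identical(back$strand, ps$strand)
})

test_that("reverse-complementing the genome and flipping annotation leaves
           promoter sequences invariant", {
  dir <- withr::local_tempdir()
  g <- make_test_genome(dir)
  bed1 <- file.path(dir, "fwd.bed")
  write.table(data.frame(c("ctgA", "ctgA"), c(2000L, 3000L), c(2400L, 3200L),
                         c("g1", "g2"), 0L, c("+", "-")),
              bed1, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  ps1 <- extract_promoters(g$fa, bed1, window_len = 400)

  # mirror the world: rc the contig, map coordinates, flip strands
  L <- nchar(g$ctgA)
  fa2 <- file.path(dir, "genome_rc.fa")
  writeLines(c(">ctgA", rc_chr(g$ctgA), ">ctgB", g$ctgB), fa2)
  bed2 <- file.path(dir, "rev.bed")
  write.table(data.frame(c("ctgA", "ctgA"), L - c(2400L, 3200L),
                         L - c(2000L, 3000L), c("g1", "g2"), 0L,
                         c("-", "+")),
              bed2, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  ps2 <- extract_promoters(fa2, bed2, window_len = 400)
  expect_identical(ps2$seq[match(ps1$gene_id, ps2$gene_id)], ps1$seq)
})

test_that("gene lists are ranked heads: ordered, de-duplicated, capped", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "genes.txt")

  writeLines(sprintf("AT%04d", 1:250), f)
  gs <- read_gene_list(f, max_genes = 100)
  expect_length(gs$gene_ids, 100L)
  expect_identical(gs$gene_ids, sprintf("AT%04d", 1:100))

  writeLines(c("dup", "# comment", "", "dup"), f)
  expect_length(read_gene_list(f)$gene_ids, 1L)

  writeLines(c("a", "b", "c"), f)
  expect_length(read_gene_list(f, max_genes = 100)$gene_ids, 3L)

  writeLines(c("# only comments", "   "), f)
  expect_error(read_gene_list(f), "empty gene set")
})

test_that("promoters_for_genes subsets in gene-set order and is strict by
           default", {
  ps <- random_promoters(5)
  sel <- promoters_for_genes(ps, c("g0003", "g0001"))
  expect_identical(sel$gene_id, c("g0003", "g0001"))
  expect_error(promoters_for_genes(ps, c("g0001", "nope")), "no promoter")
  lax <- promoters_for_genes(ps, c("g0001", "nope"), strict = FALSE)
  expect_identical(lax$gene_id, "g0001")
})
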