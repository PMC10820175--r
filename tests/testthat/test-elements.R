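dict <- element_dictionary()

test_that("the bundled dictionary is valid and carries the named elements", {
  expect_s3_class(dict, "element_dictionary")
  expect_false(anyDuplicated(dict$name) > 0)
  expect_true(all(grepl("^[ACGTRYSWKMBDHVN]+$", dict$motif)))
  expect_true(all(c("DRE", "DRE-like", "CCCCAC", "ARR1AT", "MYBST1",
                    "BOXIII", "New3", "New4", "CATTTT", "AAACAA", "TTTCTC",
                    "TCTTTT") %in% dict$name))
  # bait names whose sequences are placeholders are retrievable on request
  full <- element_dictionary(include_placeholders = TRUE)
  expect_true(all(c("GCC", "ABRE", "obo-Box", "MYBCORE", "CE3", "AuxRR",
                    "New1", "New2") %in% full$name))
  # but all-N placeholders never pollute default matching
  expect_false(any(grepl("^N+$", dict$motif)))
})

test_that("hexamers are annotated by exact and contained IUPAC matches", {
  expect_true("MYBST1" %in% annotate_hexamer("TATCCC", dict))
  expect_true("BOXIII" %in% annotate_hexamer("CATTTT", dict))  # via CATTT
  expect_true("ARR1AT" %in% annotate_hexamer("GTTATT", dict))
  expect_true("ARR1AT" %in% annotate_hexamer("GTGATT", dict))
  expect_true("New3" %in% annotate_hexamer("CGTCCA", dict))
  # longer patterns never match a hexamer
  expect_false("AuxRR" %in% annotate_hexamer("GGTCCA", dict))

  empty <- dict[0, ]
  class(empty) <- class(dict)
  expect_length(annotate_hexamer("ACGTAC", empty), 0L)
  expect_error(annotate_hexamer("ACGTN", dict), "concrete")
})

test_that("invalid IUPAC characters are rejected at dictionary load time", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.tsv")
  writeLines(c("name\tmotif\tsource", "badel\tACGTXZ\tnowhere"), p)
  expect_error(element_dictionary(p), "invalid IUPAC")
  p2 <- file.path(dir, "dup.tsv")
  writeLines(c("name\tmotif\tsource", "e\tACGTAC\ta", "e\tCCCCCC\tb"), p2)
  expect_error(element_dictionary(p2), "duplicate")
})

test_that("occurrence scanning counts overlapping IUPAC hits per gene", {
  d <- structure(data.frame(name = c("CATTTT", "pal"),
                            motif = c("CATTTT", "ATWTA"),
                            source = "test", stringsAsFactors = FALSE),
                 class = c("element_dictionary", "data.frame"))
  ps <- promoter_set(gene_id = c("g1", "g2", "g3"),
                     seq = c("GGCATTTTGG",           # one CATTTT
                             paste(rep("A", 1000), collapse = ""),  # none
                             "ATATATA"))             # overlapping ATWTA x2
  occ <- scan_geneset(ps, d)
  expect_identical(occ$counts["g1", "CATTTT"], 1L)
  expect_identical(occ$counts["g2", "CATTTT"], 0L)
  expect_identical(occ$counts["g3", "pal"], 2L)
  s <- occ$summary
  expect_equal(s$fraction_with_hit[s$element == "CATTTT"], 1 / 3)
  expect_identical(s$genes_with_hit[s$element == "pal"], 1L)
  expect_error(scan_geneset(ps, d[0, ]), "empty")
})

test_that("an all-N length-6 pattern matches exactly the valid windows", {
  d <- structure(data.frame(name = "anyN", motif = "NNNNNN", source = "t",
                            stringsAsFactors = FALSE),
                 class = c("element_dictionary", "data.frame"))
  set.seed(12)
  seqs <- vapply(1:5, function(i) random_seq(80, n_frac = 0.05), "")
  ps <- promoter_set(gene_id = paste0("g", 1:5), seq = seqs)
  occ <- scan_geneset(ps, d)
  for (i in 1:5)
    expect_identical(unname(occ$counts[i, "anyN"]),
                     count_hexamers(seqs[i])$n_valid_windows)
})

test_that("concrete hexamer scan counts equal hexamer count aggregation", {
  set.seed(33)
  ps <- random_promoters(40, len = 250)
  motifs <- c("CGTCCA", "TATCCC", "AAAAAA")
  d <- structure(data.frame(name = motifs, motif = motifs, source = "t",
                            stringsAsFactors = FALSE),
                 class = c("element_dictionary", "data.frame"))
  occ <- scan_geneset(ps, d)
  agg <- aggregate_counts(ps)
  for (m in motifs)
    expect_identical(sum(occ$counts[, m]), unname(agg$counts[[m]]))
})

test_that("scan results agree with Biostrings matching on N-free sequences", {
  set.seed(44)
  ps <- random_promoters(10, len = 300)
  d <- structure(data.frame(name = c("ARR1AT", "New3"),
                            motif = c("GTKATT", "CGTCCA"), source = "t",
                            stringsAsFactors = FALSE),
                 class = c("element_dictionary", "data.frame"))
  occ <- scan_geneset(ps, d)
  subj <- Biostrings::DNAStringSet(ps$seq)
  for (j in 1:2) {
    bs <- Biostrings::vcountPattern(d$motif[j], subj, fixed = FALSE)
    expect_identical(unname(occ$counts[, d$name[j]]), bs)
  }
})

test_that("double-strand scanning adds reverse-complement occurrences", {
  d <- structure(data.frame(name = "New3", motif = "CGTCCA", source = "t",
                            stringsAsFactors = FALSE),
                 class = c("element_dictionary", "data.frame"))
  #            fwd hit      rc hit (TGGACG)
  ps <- promoter_set(gene_id = "g1", seq = "AACGTCCATTTGGACGAA")
  single <- scan_geneset(ps, d)
  both <- scan_geneset(ps, d, both_strands = TRUE)
  expect_identical(unname(single$counts[1, 1]), 1L)
  expect_identical(unname(both$counts[1, 1]), 2L)
  expect_setequal(both$matches$strand, c("+", "-"))
})

test_that("planted-element recovery: fraction_with_hit is exact when the
           background cannot contain the pattern", {
  # backgrounds over a 3-letter alphabet lacking G cannot contain CGTCCA
  set.seed(55)
  n <- 100
  seqs <- vapply(1:n, function(i)
    paste(sample(c("A", "C", "T"), 120, TRUE), collapse = ""), "")
  hit <- 1:80
  for (i in hit) {
    p <- sample.int(120 - 6 + 1, 1)
    substr(seqs[i], p, p + 5) <- "CGTCCA"
  }
  ps <- promoter_set(gene_id = sprintf("g%03d", 1:n), seq = seqs)
  d <- structure(data.frame(name = "New3", motif = "CGTCCA", source = "t",
                            stringsAsFactors = FALSE),
                 class = c("element_dictionary", "data.frame"))
  occ <- scan_geneset(ps, d)
  expect_identical(occ$summary$genes_with_hit, 80L)
  expect_equal(occ$summary$fraction_with_hit, 0.80)
})

test_that("match coordinates are correct promoter-local 0-based intervals", {
  dir <- withr::local_tempdir()
  d <- structure(data.frame(name = "New3", motif = "CGTCCA", source = "t",
                            stringsAsFactors = FALSE),
                 class = c("element_dictionary", "data.frame"))
  ps <- promoter_set(gene_id = "g1", seq = "AAACGTCCAAA")
  occ <- scan_geneset(ps, d)
  expect_identical(occ$matches$start, 3L)
  expect_identical(occ$matches$end, 9L)
  expect_identical(substr(ps$seq, occ$matches$start + 1, occ$matches$end),
                   "CGTCCA")
  bed <- file.path(dir, "m.bed")
  write_match_bed(occ, bed)
  b <- read.table(bed, sep = "\t")
  expect_identical(b$V2, 3L)
})
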