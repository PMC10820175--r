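# Independent oracles and small fixtures shared across the suite.

# Naive window-by-window hexamer counter: examines every width-k substring
# independently, skipping any containing N. Deliberately unrelated to the
# package's rolling-index implementation.
oracle_count <- function(seq, k = 6L) {
  motifs <- promhex::hexamers(k)
  counts <- stats::setNames(integer(length(motifs)), motifs)
  L <- nchar(seq)
  n_valid <- 0L
  if (L >= k) {
    wins <- substring(seq, 1:(L - k + 1L), k:L)
    clean <- !grepl("N", wins, fixed = TRUE)
    n_valid <- sum(clean)
    tab <- table(wins[clean])
    counts[names(tab)] <- as.integer(tab)
  }
  list(counts = counts, n_valid = n_valid)
}

# Random test sequence with optional N injection.
random_seq <- function(len, n_frac = 0) {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_frac > 0) {
    nn <- rbinom(1, len, n_frac)
    if (nn > 0) s[sample.int(len, nn)] <- "N"
  }
  paste(s, collapse = "")
}

# Quick uniform promoter set for unit tests.
random_promoters <- function(n, len = 200L, prefix = "g") {
  promhex::promoter_set(gene_id = sprintf("%s%04d", prefix, seq_len(n)),
                        seq = vapply(seq_len(n), function(i)
                          random_seq(len), ""))
}

# Memoised full-scale study panel: one synthetic background universe and
# fitted null per seed, shared by the calibration and recovery suites
# (identical study conditions, so the object is reused, not recomputed).
.panel_cache <- new.env(parent = emptyenv())
study_panel <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.panel_cache[[key]])) return(.panel_cache[[key]])
  cfg <- promhex::synth_config(seed = seed)
  bg <- promhex::generate_background(cfg)
  nm <- promhex::build_null(bg$promoters, sample_size = 100,
                            n_replicates = 1000, seed = seed)
  .panel_cache[[key]] <- list(config = cfg, null = nm)
  .panel_cache[[key]]
}
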