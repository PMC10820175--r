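#' Build a resampling null model of hexamer frequencies
#'
#' Fits the "standardized promoter" null: `n_replicates` independent random
#' subsets of `sample_size` promoters are drawn (each without replacement)
#' from a background promoter universe, each hexamer's total count in each
#' subset is recorded, and the per-hexamer mean and sample standard
#' deviation (denominator `n_replicates - 1`) across replicates define the
#' expected frequency per `sample_size` promoters and its spread. Enrichment
#' of a focal gene set is then judged against this null via
#' [hexamer_enrichment()].
#'
#' Randomness is fully seeded: replicate `r`'s draw is a pure function of
#' `(seed, r)`, so the same seed, background and parameters reproduce the
#' model bit-identically, and the caller's RNG state is left untouched.
#'
#' @param background A [promoter_set] (or character vector of sequences):
#'   the background promoter universe. Must contain at least `sample_size`
#'   promoters.
#' @param sample_size Promoters drawn per replicate (default 100).
#' @param n_replicates Number of resampled subsets (default 1000).
#' @param seed Integer seed governing all draws (required).
#' @param k Word length, default 6.
#' @return An object of class `hexamer_null`: list with `mean` and `sd`
#'   (named numeric vectors of length `4^k`), `sample_size`, `n_replicates`,
#'   `seed`, `background_size`, `k` and `degenerate` (TRUE when every
#'   hexamer has sd 0, e.g. background exactly `sample_size` promoters).
#' @examples
#' bg <- replicate(120, paste(sample(c("A","C","G","T"), 50, TRUE),
#'                            collapse = ""))
#' nm <- build_null(bg, sample_size = 20, n_replicates = 50, seed = 1)
#' nm
#' @export
build_null <- function(background, sample_size = 100L, n_replicates = 1000L,
                       seed, k = 6L) {
  if (missing(seed) || is.null(seed))
    stop("an explicit integer 'seed' is required")
  seed <- as.integer(seed)
  sample_size <- as.integer(sample_size)
  n_replicates <- as.integer(n_replicates)
  k <- as.integer(k)
  if (sample_size < 1L) stop("'sample_size' must be >= 1")
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1")
  seqs <- normalize_sequence(promoter_seqs(background))
  n_bg <- length(seqs)
  if (n_bg < sample_size)
    stop("background (", n_bg, ") is smaller than sample_size (",
         sample_size, ")")

  m <- .count_matrix(seqs, k)     # 4^k x n_bg
  nbin <- nrow(m)
  totals <- matrix(0, nbin, n_replicates)
  old <- .preserve_rng()
  on.exit(.restore_rng(old))
  for (r in seq_len(n_replicates)) {
    set.seed(.replicate_seed(seed, r))
    cols <- sample.int(n_bg, sample_size)
    totals[, r] <- .rowSums(m[, cols, drop = FALSE], nbin, sample_size)
  }
  mu <- rowMeans(totals)
  sdv <- if (n_replicates > 1L)
    sqrt(pmax(0, (rowSums(totals^2) - n_replicates * mu^2) /
                   (n_replicates - 1L)))
  else rep(NA_real_, nbin)
  names(mu) <- names(sdv) <- hexamers(k)
  structure(list(mean = mu, sd = sdv, sample_size = sample_size,
                 n_replicates = n_replicates, seed = seed,
                 background_size = n_bg, k = k,
                 degenerate = all(sdv == 0, na.rm = TRUE)),
            class = "hexamer_null")
}

# Replicate r's RNG seed: a fixed affine map of (seed, r) into 32-bit range,
# so each replicate's draw depends only on the user seed and its own index.
.replicate_seed <- function(seed, r) {
  as.integer((as.double(seed) %% 2147483647 + as.double(r) * 1000003) %%
               2147483647)
}

.preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' @export
print.hexamer_null <- function(x, ...) {
  cat(sprintf(
    "Resampling null (k = %d): %d replicates of %d promoters from %d\n",
    x$k, x$n_replicates, x$sample_size, x$background_size))
  cat(sprintf("  seed %d; mean frequency per sample: %.3f (range %.2f-%.2f)\n",
              x$seed, mean(x$mean), min(x$mean), max(x$mean)))
  if (x$degenerate)
    cat("  DEGENERATE: sd is zero for every hexamer",
        "(background no larger than sample_size?)\n")
  else if (any(x$sd == 0))
    cat(sprintf("  %d hexamer(s) with sd = 0 (Z undefined for these)\n",
                sum(x$sd == 0)))
  invisible(x)
}

#' Serialize / restore a null model as JSON
#'
#' Stores parameters and per-hexamer mean/sd so one null can be reused
#' across several contrasts without recounting the background.
#'
#' @param null A `hexamer_null`.
#' @param path JSON file path.
#' @return `write_null_json()` returns `path` invisibly; `read_null_json()`
#'   returns the restored `hexamer_null`.
#' @export
write_null_json <- function(null, path) {
  stopifnot(inherits(null, "hexamer_null"))
  obj <- list(sample_size = null$sample_size,
              n_replicates = null$n_replicates, seed = null$seed,
              background_size = null$background_size, k = null$k,
              degenerate = null$degenerate,
              mean = unname(null$mean), sd = unname(null$sd))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_null_json
#' @export
read_null_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- as.numeric(obj$mean); sdv <- as.numeric(obj$sd)
  names(mu) <- names(sdv) <- hexamers(obj$k)
  structure(list(mean = mu, sd = sdv,
                 sample_size = as.integer(obj$sample_size),
                 n_replicates = as.integer(obj$n_replicates),
                 seed = as.integer(obj$seed),
                 background_size = as.integer(obj$background_size),
                 k = as.integer(obj$k),
                 degenerate = isTRUE(obj$degenerate)),
            class = "hexamer_null")
}
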