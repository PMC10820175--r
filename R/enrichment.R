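#' Per-hexamer enrichment of a focal promoter set against a resampling null
#'
#' The central estimator: each hexamer's aggregate count over the focal
#' promoters is standardized to a frequency per `sample_size` promoters
#' (`count * sample_size / n_promoters`, so focal sets need not contain
#' exactly `sample_size` genes) and converted to a Z-score against the
#' resampling null, `z = (observed_freq - null_mean) / null_sd`. Hexamers
#' whose null sd is zero get an undefined Z (NA) and are excluded from
#' ranking. Ranks are assigned by descending Z with ties broken
#' lexicographically by motif. A two-sided normal p-value is included for
#' convenience; it is approximate and no multiple-testing correction is
#' applied — the method's output is the Z-score ranking.
#'
#' @param observed A `hexamer_counts` from [aggregate_counts()], or a
#'   [promoter_set] / character vector of focal promoter sequences (counted
#'   internally).
#' @param null A `hexamer_null` from [build_null()] with matching `k`.
#' @param dictionary Optional [element_dictionary()]; when supplied, each
#'   hexamer is annotated with the names of matching known cis-elements.
#' @param name Label for the focal set / contrast.
#' @return A data frame of class `hexamer_enrichment` with one row per
#'   hexamer (lexicographic order): `motif`, `count`, `observed_freq`,
#'   `null_mean`, `null_sd`, `z`, `rank`, `approx_p` and (with a dictionary)
#'   `elements`. Attributes carry `sample_size`, `n_promoters`,
#'   `n_replicates`, `seed` and `name`.
#' @seealso [top_hexamers()], [compare_enrichment()], [plot.hexamer_enrichment()]
#' @export
hexamer_enrichment <- function(observed, null, dictionary = NULL,
                               name = "focal") {
  stopifnot(inherits(null, "hexamer_null"))
  if (!inherits(observed, "hexamer_counts"))
    observed <- aggregate_counts(observed, k = null$k)
  if (observed$n_promoters < 1L) stop("focal set has no promoters")
  if (length(observed$counts) != length(null$mean))
    stop("hexamer universe mismatch between observed counts (k = ",
         observed$k, ") and null (k = ", null$k, ")")

  motifs <- names(null$mean)
  freq <- observed$counts * null$sample_size / observed$n_promoters
  sd0 <- null$sd == 0 | is.na(null$sd)
  z <- ifelse(sd0, NA_real_, (freq - null$mean) / null$sd)

  rank <- rep(NA_integer_, length(z))
  def <- which(!is.na(z))
  # rows are already lexicographic by motif, so position is the tie-break
  ord <- def[order(-z[def], def)]
  rank[ord] <- seq_along(ord)

  out <- data.frame(motif = motifs, count = unname(observed$counts),
                    observed_freq = unname(freq),
                    null_mean = unname(null$mean), null_sd = unname(null$sd),
                    z = unname(z), rank = rank,
                    approx_p = ifelse(is.na(z), NA_real_,
                                      2 * stats::pnorm(-abs(z))),
                    stringsAsFactors = FALSE)
  if (!is.null(dictionary))
    out$elements <- annotate_hexamers(motifs, dictionary)
  structure(out,
            class = c("hexamer_enrichment", "data.frame"),
            sample_size = null$sample_size,
            n_promoters = observed$n_promoters,
            n_replicates = null$n_replicates,
            seed = null$seed, name = name)
}

#' Top-ranked enriched hexamers
#'
#' @param table A `hexamer_enrichment`.
#' @param k How many motifs to return (default 10, the conventional
#'   "top 10" report).
#' @return The first `k` rows by rank (descending Z, lexicographic
#'   tie-break), as a data frame.
#' @export
top_hexamers <- function(table, k = 10L) {
  stopifnot(inherits(table, "hexamer_enrichment"))
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  n_def <- sum(!is.na(table$rank))
  if (k > n_def)
    stop("requested top ", k, " but only ", n_def,
         " hexamers have a defined Z-score")
  out <- as.data.frame(table)[match(seq_len(k), table$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.hexamer_enrichment <- function(x, n = 10L, ...) {
  cat(sprintf(
    "Hexamer enrichment '%s': %d promoters vs null (%d x %d, seed %d)\n",
    attr(x, "name"), attr(x, "n_promoters"), attr(x, "n_replicates"),
    attr(x, "sample_size"), attr(x, "seed")))
  n_undef <- sum(is.na(x$z))
  if (n_undef > 0)
    cat(sprintf("  %d hexamer(s) with undefined Z (null sd = 0)\n", n_undef))
  cat(sprintf("Top %d of %d motifs by Z:\n", n, sum(!is.na(x$rank))))
  top <- as.data.frame(x)[match(seq_len(min(n, sum(!is.na(x$rank)))),
                                x$rank), , drop = FALSE]
  rownames(top) <- NULL
  print(format(top, digits = 4))
  invisible(x)
}

#' @export
summary.hexamer_enrichment <- function(object, z_threshold = 1.96, ...) {
  z <- object$z
  res <- list(name = attr(object, "name"),
              n_promoters = attr(object, "n_promoters"),
              n_defined = sum(!is.na(z)),
              n_undefined = sum(is.na(z)),
              mean_z = mean(z, na.rm = TRUE),
              frac_enriched = mean(z >= z_threshold, na.rm = TRUE),
              frac_extreme = mean(abs(z) >= z_threshold, na.rm = TRUE),
              z_threshold = z_threshold,
              top = top_hexamers(object, min(10L, sum(!is.na(z)))))
  class(res) <- "summary.hexamer_enrichment"
  res
}

#' @export
print.summary.hexamer_enrichment <- function(x, ...) {
  cat(sprintf("Enrichment summary '%s' (%d promoters)\n", x$name,
              x$n_promoters))
  cat(sprintf("  defined Z: %d, undefined: %d\n", x$n_defined, x$n_undefined))
  cat(sprintf("  mean Z: %.4f;  |Z| >= %.2f: %.3f;  Z >= %.2f: %.3f\n",
              x$mean_z, x$z_threshold, x$frac_extreme, x$z_threshold,
              x$frac_enriched))
  cat("  top motifs:\n")
  print(format(x$top[, intersect(c("motif", "observed_freq", "z", "rank",
                                   "elements"), names(x$top))], digits = 4))
  invisible(x)
}

#' Z-score scatter of a hexamer enrichment table
#'
#' Observed standardized frequency (x) against Z-score (y), with the top
#' `label_top` motifs labeled in red — the classic presentation of
#' promoter-element enrichment.
#'
#' @param x A `hexamer_enrichment`.
#' @param label_top Number of top-ranked motifs to label (default 10).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hexamer_enrichment <- function(x, label_top = 10L, ...) {
  ok <- !is.na(x$z)
  graphics::plot(x$observed_freq[ok], x$z[ok], pch = 16, cex = 0.4,
                 col = "grey40",
                 xlab = sprintf("Observed frequency per %d promoters",
                                attr(x, "sample_size")),
                 ylab = "Z-score",
                 main = attr(x, "name"), ...)
  graphics::abline(h = c(-1.96, 1.96), lty = 3, col = "grey")
  lab <- which(!is.na(x$rank) & x$rank <= label_top)
  if (length(lab)) {
    graphics::points(x$observed_freq[lab], x$z[lab], pch = 16, col = "red")
    graphics::text(x$observed_freq[lab], x$z[lab], x$motif[lab],
                   col = "red", pos = 4, cex = 0.7, xpd = NA)
  }
  invisible(x)
}

#' Write an enrichment table as TSV
#'
#' @param table A `hexamer_enrichment`.
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(table, path) {
  stopifnot(inherits(table, "hexamer_enrichment"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
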