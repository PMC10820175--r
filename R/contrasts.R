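#' Compare hexamer enrichment between two contrasts
#'
#' Aligns two enrichment tables (e.g. osmotic-stress vs salt-stress focal
#' sets scored against the same background null) over the full hexamer
#' universe, computes `delta = z_y - z_x` wherever both Z-scores are
#' defined, and partitions top-`top_k` membership into motifs shared by both
#' rankings and motifs specific to one.
#'
#' @param table_x,table_y `hexamer_enrichment` tables built against nulls
#'   with the same `sample_size` and identical motif universes.
#' @param top_k Size of the head of each ranking used for the shared /
#'   specific partition (default 10).
#' @param z_min Optional minimum Z: motifs below it are excluded from the
#'   top sets even if ranked within `top_k`.
#' @return An `enrichment_comparison`: list with `name_x`, `name_y`, a
#'   `table` data frame (`motif`, `z_x`, `z_y`, `delta`, `observed_freq_x`,
#'   `observed_freq_y`), and character vectors `shared_top`,
#'   `specific_top_x`, `specific_top_y` (disjoint; their unions reproduce
#'   each table's top set).
#' @export
compare_enrichment <- function(table_x, table_y, top_k = 10L, z_min = NULL) {
  stopifnot(inherits(table_x, "hexamer_enrichment"),
            inherits(table_y, "hexamer_enrichment"))
  if (!identical(table_x$motif, table_y$motif))
    stop("the two tables cover different hexamer universes")
  if (!identical(attr(table_x, "sample_size"), attr(table_y, "sample_size")))
    stop("tables were standardized to different sample sizes (",
         attr(table_x, "sample_size"), " vs ", attr(table_y, "sample_size"),
         ")")
  tab <- data.frame(motif = table_x$motif,
                    z_x = table_x$z, z_y = table_y$z,
                    delta = table_y$z - table_x$z,
                    observed_freq_x = table_x$observed_freq,
                    observed_freq_y = table_y$observed_freq,
                    stringsAsFactors = FALSE)
  top_set <- function(tb) {
    m <- tb$motif[!is.na(tb$rank) & tb$rank <= top_k]
    if (!is.null(z_min)) m <- m[tb$z[match(m, tb$motif)] >= z_min]
    m
  }
  tx <- top_set(table_x); ty <- top_set(table_y)
  structure(list(name_x = attr(table_x, "name"),
                 name_y = attr(table_y, "name"),
                 table = tab,
                 top_k = as.integer(top_k),
                 shared_top = intersect(tx, ty),
                 specific_top_x = setdiff(tx, ty),
                 specific_top_y = setdiff(ty, tx)),
            class = "enrichment_comparison")
}

#' @export
print.enrichment_comparison <- function(x, ...) {
  cat(sprintf("Enrichment comparison: %s (x) vs %s (y)\n", x$name_x,
              x$name_y))
  cat(sprintf("  shared top-%d: %s\n", x$top_k,
              paste(x$shared_top, collapse = ", ")))
  cat(sprintf("  %s-specific: %s\n", x$name_x,
              paste(x$specific_top_x, collapse = ", ")))
  cat(sprintf("  %s-specific: %s\n", x$name_y,
              paste(x$specific_top_y, collapse = ", ")))
  d <- x$table$delta
  cat(sprintf("  delta (z_y - z_x) defined for %d motifs; range %.2f to %.2f\n",
              sum(!is.na(d)), min(d, na.rm = TRUE), max(d, na.rm = TRUE)))
  invisible(x)
}

#' Numeric scatter data behind enrichment plots
#'
#' For a single enrichment table, one row per motif with x = observed
#' standardized frequency and y = Z (the classic single-contrast scatter).
#' For a comparison, x defaults to the first table's observed frequency and
#' y to the second table's Z; set `x_var = "z"` for a Z-vs-Z panel. The
#' `label` column flags top-ranked motifs (both tables' top sets for a
#' comparison).
#'
#' @param x A `hexamer_enrichment` or `enrichment_comparison`.
#' @param ... Passed to methods.
#' @return A data frame with columns `motif`, `x`, `y`, `label`.
#' @export
scatter_data <- function(x, ...) UseMethod("scatter_data")

#' @rdname scatter_data
#' @param label_top Number of top-ranked motifs flagged (default 10).
#' @export
scatter_data.hexamer_enrichment <- function(x, label_top = 10L, ...) {
  data.frame(motif = x$motif, x = x$observed_freq, y = x$z,
             label = !is.na(x$rank) & x$rank <= label_top,
             stringsAsFactors = FALSE)
}

#' @rdname scatter_data
#' @param x_var `"observed_freq"` (default) or `"z"`: quantity on the x axis
#'   for a comparison.
#' @export
scatter_data.enrichment_comparison <- function(x,
                                               x_var = c("observed_freq",
                                                         "z"), ...) {
  x_var <- match.arg(x_var)
  tab <- x$table
  data.frame(motif = tab$motif,
             x = if (x_var == "z") tab$z_x else tab$observed_freq_x,
             y = tab$z_y,
             label = tab$motif %in% c(x$shared_top, x$specific_top_x,
                                      x$specific_top_y),
             stringsAsFactors = FALSE)
}

#' @export
plot.enrichment_comparison <- function(x, x_var = "z", ...) {
  sd_ <- scatter_data(x, x_var = x_var)
  ok <- !is.na(sd_$x) & !is.na(sd_$y)
  graphics::plot(sd_$x[ok], sd_$y[ok], pch = 16, cex = 0.4, col = "grey40",
                 xlab = paste0(x$name_x, if (x_var == "z") " (Z)"
                               else " (observed freq)"),
                 ylab = paste0(x$name_y, " (Z)"), ...)
  lab <- which(sd_$label)
  if (length(lab)) {
    graphics::points(sd_$x[lab], sd_$y[lab], pch = 16, col = "red")
    graphics::text(sd_$x[lab], sd_$y[lab], sd_$motif[lab], col = "red",
                   pos = 4, cex = 0.7, xpd = NA)
  }
  invisible(x)
}

#' Write a comparison (and its scatter data) as TSV
#'
#' @param comparison An `enrichment_comparison`.
#' @param path Output path for the aligned per-motif table.
#' @export
write_comparison_tsv <- function(comparison, path) {
  stopifnot(inherits(comparison, "enrichment_comparison"))
  tab <- comparison$table
  tab$top_set <- ifelse(tab$motif %in% comparison$shared_top, "shared",
                 ifelse(tab$motif %in% comparison$specific_top_x,
                        comparison$name_x,
                 ifelse(tab$motif %in% comparison$specific_top_y,
                        comparison$name_y, "")))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
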