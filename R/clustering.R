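# Pre-clustering missing-data protocol and hierarchical clustering of
# samples/haplotypes. The pipeline order is fixed:
#   filter_missing -> impute_linear -> drop_residual -> cluster_samples
# and the heatmap then displays the imputed matrix in dendrogram leaf order.

#' Remove columns with too much missing data
#'
#' Columns (individuals or haplotypes) with `max_missing` or more of their
#' sites missing are removed before clustering, so that incomplete columns
#' cannot distort the distances. The boundary is inclusive: at the default,
#' a column missing exactly 40% of its sites is removed.
#'
#' @param table A `freq_table`.
#' @param max_missing Missing-data fraction at or above which a column is
#'   dropped; in `(0, 1]`, default 0.40.
#' @return List with `table` (kept columns) and `removed` (character vector
#'   of removed sample names).
#' @export
filter_missing <- function(table, max_missing = 0.40) {
  stopifnot(inherits(table, "freq_table"))
  if (!is.numeric(max_missing) || max_missing <= 0 || max_missing > 1) {
    stop_usage("max_missing must be in (0, 1]")
  }
  frac <- missing_fraction(table)
  removed <- names(frac)[frac >= max_missing]
  kept <- setdiff(table$samples, removed)
  if (length(kept) == 0) {
    stop_data(sprintf(
      "nothing to cluster: all %d column(s) have >= %.0f%% missing data",
      length(removed), 100 * max_missing))
  }
  list(table = freq_table(table$chrom, table$position,
                          table$values[, kept, drop = FALSE]),
       removed = removed)
}

#' Fill missing cells by position-weighted linear interpolation
#'
#' Per column, each missing value at position p strictly between two
#' observed neighbors (p0, v0) and (p1, v1) becomes
#' `v0 + (v1 - v0) * (p - p0) / (p1 - p0)` — weighted by genomic distance,
#' so closer positions contribute more, not by row rank. Leading and
#' trailing gaps (no observed neighbor on one side) are never extrapolated
#' and stay missing; observed cells are untouched. Idempotent.
#'
#' @param table A `freq_table` with sites sorted (always true for the
#'   class).
#' @return A `freq_table` with interior gaps filled.
#' @export
impute_linear <- function(table) {
  stopifnot(inherits(table, "freq_table"))
  vals <- table$values
  if (n_sites(table) == 0 || ncol(vals) == 0) return(table)
  for (chr in unique(table$chrom)) {
    rows <- which(table$chrom == chr)
    pos <- table$position[rows]
    for (j in seq_len(ncol(vals))) {
      v <- vals[rows, j]
      obs <- !is.na(v)
      if (sum(obs) < 2 || all(obs)) next
      filled <- stats::approx(pos[obs], v[obs], xout = pos, method = "linear",
                              rule = 1)$y
      vals[rows[!obs], j] <- filled[!obs]
    }
  }
  freq_table(table$chrom, table$position, vals)
}

#' Drop columns with residual missing data
#'
#' Columns still containing missing values after interpolation (gaps at the
#' edges of the region cannot be interpolated) are removed, leaving a
#' complete matrix for clustering.
#'
#' @param table A `freq_table`.
#' @return List with `table` (complete columns only) and `removed`.
#' @export
drop_residual <- function(table) {
  stopifnot(inherits(table, "freq_table"))
  has_na <- apply(is.na(table$values), 2, any)
  removed <- table$samples[has_na]
  kept <- table$samples[!has_na]
  if (length(kept) == 0) {
    stop_data("nothing to cluster: every column has residual missing values")
  }
  list(table = freq_table(table$chrom, table$position,
                          table$values[, kept, drop = FALSE]),
       removed = removed)
}

#' Hierarchically cluster samples
#'
#' Agglomerative clustering of the sample columns on Euclidean distance
#' between frequency vectors with complete linkage (frequencies all live in
#' [0,1], so no standardization is applied). The dendrogram leaf order is
#' made deterministic: at every merge, the subtree containing the
#' lexicographically smallest original sample name goes to the left, so the
#' result does not depend on input column order.
#'
#' @param table A `freq_table` with no missing cells and at least two
#'   columns.
#' @return A `cluster_result`: `kept_samples` (leaf order, left to right),
#'   `merge` / `height` (hclust-style merge tree), `imputed` (the input
#'   table with columns in leaf order), `removed_pre`, `removed_post`.
#' @export
cluster_samples <- function(table) {
  stopifnot(inherits(table, "freq_table"))
  if (ncol(table$values) < 2) {
    stop_data("clustering needs at least 2 columns")
  }
  if (anyNA(table$values)) {
    stop_data("cluster_samples requires a complete matrix; run impute_linear/drop_residual first")
  }
  d <- stats::dist(t(table$values), method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  leaves <- deterministic_leaf_order(hc$merge, table$samples)
  ord <- match(leaves, table$samples)
  structure(list(
    kept_samples = leaves,
    removed_pre = character(),
    removed_post = character(),
    imputed = freq_table(table$chrom, table$position,
                         table$values[, ord, drop = FALSE]),
    merge = hc$merge,
    height = hc$height,
    labels = table$samples),
    class = "cluster_result")
}

# left-to-right leaf order: at each merge the child subtree whose smallest
# original label sorts first (C locale) goes left
deterministic_leaf_order <- function(merge, labels) {
  n <- length(labels)
  walk <- function(node) {
    if (node < 0) return(labels[-node])
    a <- walk(merge[node, 1L])
    b <- walk(merge[node, 2L])
    min_a <- sort(a, method = "radix")[1L]
    min_b <- sort(b, method = "radix")[1L]
    if (min_a <= min_b) c(a, b) else c(b, a)
  }
  if (n == 1) return(labels)
  walk(nrow(merge))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d leaf/leaves", length(x$kept_samples)))
  if (length(x$removed_pre) || length(x$removed_post)) {
    cat(sprintf(" (removed: %d by missingness filter, %d residual)",
                length(x$removed_pre), length(x$removed_post)))
  }
  cat("\n  leaf order: ",
      paste(utils::head(x$kept_samples, 8), collapse = ", "),
      if (length(x$kept_samples) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Run the full clustering pipeline on a table with missing data
#'
#' Convenience wrapper enforcing the fixed protocol: missingness filter,
#' position-weighted linear interpolation, residual-column removal, then
#' hierarchical clustering. The returned `imputed` table is the matrix the
#' heatmap displays when clustering is on.
#'
#' @param table A `freq_table`.
#' @param max_missing Pre-filter threshold, see [filter_missing()].
#' @return A `cluster_result` with `removed_pre` and `removed_post` filled
#'   in.
#' @export
cluster_table <- function(table, max_missing = 0.40) {
  pre <- filter_missing(table, max_missing = max_missing)
  imp <- impute_linear(pre$table)
  post <- drop_residual(imp)
  res <- cluster_samples(post$table)
  res$removed_pre <- pre$removed
  res$removed_post <- post$removed
  res
}
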