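# The modification-frequency table: one row per genomic position, one column
# per individual or haplotype, cells in [0,1] with an explicit missing state
# (NA). Rows are kept strictly sorted by (chromosome, position).

#' Construct a modification-frequency table
#'
#' The central data structure: a sites-by-samples matrix of modification
#' frequencies. Each column represents an individual or haplotype, each row a
#' genomic position. Rows are sorted by (chromosome, position) with natural
#' ordering of chromosome names (chr2 before chr10); duplicate positions are
#' an error, as they signal an upstream pipeline bug rather than something to
#' merge silently.
#'
#' @param chrom Character vector of chromosome names, one per site.
#' @param position Integer vector of 1-based positions, one per site.
#' @param values Numeric matrix (sites x samples) of frequencies in
#'   `[0, 1]`; `NA` marks missing cells. Column names are the sample names
#'   and must be unique.
#' @return An object of class `freq_table` with fields `chrom`, `position`,
#'   `values`, and `samples` (= `colnames(values)`).
#' @examples
#' ft <- freq_table(
#'   chrom = c("chr1", "chr1"), position = c(100L, 200L),
#'   values = matrix(c(0.1, 0.9, NA, 0.5), 2,
#'                   dimnames = list(NULL, c("S1", "S2")))
#' )
#' ft
#' @export
freq_table <- function(chrom = character(), position = integer(),
                       values = matrix(numeric(), nrow = 0, ncol = 0)) {
  chrom <- as.character(chrom)
  position <- as.numeric(position)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- length(chrom)
  if (length(position) != n || nrow(values) != n) {
    stop_usage("chrom, position and nrow(values) must agree")
  }
  if (ncol(values) > 0 && (is.null(colnames(values)) ||
                           anyNA(colnames(values)) ||
                           !all(nzchar(colnames(values))))) {
    stop_usage("every sample column must be named")
  }
  if (anyDuplicated(colnames(values))) {
    stop_data(sprintf("duplicate sample names: %s",
                      paste(unique(colnames(values)[duplicated(colnames(values))]),
                            collapse = ", ")))
  }
  if (n > 0) {
    if (anyNA(chrom) || anyNA(position) || any(position < 1) ||
        any(position != floor(position))) {
      stop_data("positions must be positive 1-based integers")
    }
    bad <- which(!is.na(values) & (values < 0 | values > 1))
    if (length(bad)) {
      stop_data(sprintf("%d frequency value(s) outside [0, 1]", length(bad)))
    }
    o <- order_sites(chrom, position)
    chrom <- chrom[o]
    position <- position[o]
    values <- values[o, , drop = FALSE]
    dup <- duplicated(paste0(chrom, "\r", position))
    if (any(dup)) {
      stop_data(sprintf("duplicate site(s): %s",
                        paste(utils::head(sprintf("%s:%d", chrom[dup],
                                                  as.integer(position[dup])), 5),
                              collapse = ", ")))
    }
  }
  structure(list(chrom = chrom, position = position, values = values,
                 samples = colnames(values)),
            class = "freq_table")
}

#' @export
dim.freq_table <- function(x) c(length(x$position), ncol(x$values))

n_sites <- function(x) length(x$position)

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d site(s) x %d sample(s)\n",
              n_sites(x), ncol(x$values)))
  if (n_sites(x) > 0) {
    cat(sprintf("  span: %s:%d-%d%s\n", x$chrom[1L],
                as.integer(x$position[1L]),
                as.integer(x$position[n_sites(x)]),
                if (length(unique(x$chrom)) > 1)
                  sprintf(" (+%d more chromosomes)",
                          length(unique(x$chrom)) - 1L) else ""))
    miss <- mean(is.na(x$values))
    cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  }
  if (length(x$samples)) {
    shown <- utils::head(x$samples, 6)
    cat("  samples: ", paste(shown, collapse = ", "),
        if (length(x$samples) > 6) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.freq_table <- function(x, ...) {
  data.frame(chrom = x$chrom, position = as.integer(x$position),
             as.data.frame(x$values, optional = TRUE),
             check.names = FALSE, row.names = NULL)
}

site_keys <- function(x) paste0(x$chrom, "\r", as.integer(x$position))

#' Subset a frequency table to a region
#'
#' @param table A `freq_table`.
#' @param region A `genomic_region` or region string.
#' @return The `freq_table` restricted to sites inside the region.
#' @export
subset_region <- function(table, region) {
  region <- parse_region(region)
  keep <- table$chrom == region$chrom &
    table$position >= region$start & table$position <= region$end
  freq_table(table$chrom[keep], table$position[keep],
             table$values[keep, , drop = FALSE])
}

#' Per-sample missing-data fraction
#'
#' The fraction of sites at which each column has no frequency; this is the
#' quantity the pre-clustering missingness filter thresholds.
#'
#' @param table A `freq_table` with at least one site.
#' @return Named numeric vector in `[0, 1]`, one entry per sample.
#' @export
missing_fraction <- function(table) {
  stopifnot(inherits(table, "freq_table"))
  if (n_sites(table) == 0) {
    stop_data("missing_fraction: table has no sites")
  }
  colMeans(is.na(table$values))
}

#' Merge frequency tables
#'
#' Combines tables over the union of their sites and sample columns, the way
#' per-haplotype or per-chunk intermediate tables are assembled into one
#' cohort table, and sorts the result by genomic position. A cell observed in
#' no part stays missing. Two parts may only contribute to the same sample
#' column on disjoint sites (or with identical values); conflicting
#' non-missing values for one cell are an error, because overlapping chunks
#' that disagree indicate a pipeline bug.
#'
#' @param parts List of `freq_table` objects.
#' @return A single merged `freq_table`.
#' @export
merge_tables <- function(parts) {
  if (inherits(parts, "freq_table")) parts <- list(parts)
  stopifnot(is.list(parts), all(vapply(parts, inherits, logical(1),
                                       "freq_table")))
  if (length(parts) == 0) return(freq_table())
  all_chrom <- unlist(lapply(parts, `[[`, "chrom"), use.names = FALSE)
  all_pos <- unlist(lapply(parts, `[[`, "position"), use.names = FALSE)
  keys <- paste0(all_chrom, "\r", as.integer(all_pos))
  first <- !duplicated(keys)
  u_chrom <- all_chrom[first]
  u_pos <- all_pos[first]
  u_keys <- keys[first]
  samples <- unique(unlist(lapply(parts, `[[`, "samples"), use.names = FALSE))
  out <- matrix(NA_real_, length(u_pos), length(samples),
                dimnames = list(NULL, samples))
  for (p in parts) {
    if (n_sites(p) == 0 || length(p$samples) == 0) next
    ridx <- match(site_keys(p), u_keys)
    for (s in p$samples) {
      new <- p$values[, s]
      old <- out[ridx, s]
      clash <- !is.na(new) & !is.na(old) & new != old
      if (any(clash)) {
        i <- which(clash)[1L]
        stop_data(sprintf(
          "merge conflict at %s:%d sample %s: %g vs %g",
          p$chrom[i], as.integer(p$position[i]), s, old[i], new[i]))
      }
      out[ridx, s] <- ifelse(is.na(new), old, new)
    }
  }
  freq_table(u_chrom, u_pos, out)
}

#' Split a table into fixed genomic windows
#'
#' Partitions the rows into chromosome-wise windows of `chunk_bp` basepairs
#' (window k covers positions `k*chunk_bp + 1 .. (k+1)*chunk_bp`), the
#' chunking used to keep per-piece memory bounded when building cohort-scale
#' tables. Merging the chunks back reproduces the input exactly.
#'
#' @param table A `freq_table`.
#' @param chunk_bp Window size in basepairs (default 25,000,000).
#' @return List of `freq_table` chunks ordered by (chromosome, window).
#' @export
split_table <- function(table, chunk_bp = 25000000L) {
  stopifnot(inherits(table, "freq_table"))
  chunk_bp <- as.numeric(chunk_bp)
  if (is.na(chunk_bp) || chunk_bp < 1) stop_usage("chunk_bp must be >= 1")
  if (n_sites(table) == 0) return(list())
  win <- floor((table$position - 1) / chunk_bp)
  grp_key <- paste0(table$chrom, "\r", win)
  # rows are already sorted, so unique() preserves (chrom, window) order
  lapply(unique(grp_key), function(g) {
    keep <- grp_key == g
    freq_table(table$chrom[keep], table$position[keep],
               table$values[keep, , drop = FALSE])
  })
}
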