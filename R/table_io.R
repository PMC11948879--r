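# On-disk dialect and indexed retrieval.
#
# Canonical writer: header "chrom<TAB>position<TAB><sample>...", one row per
# position, frequencies with 4 decimal places, missing cells written as empty
# fields, block-gzip compressed, with an optional tabix index (sequence =
# column 1, begin = end = column 2, one header line skipped). The reader is
# liberal: "", "NA", "na", "nan" all mean missing, and rows may arrive
# unsorted.

MISSING_TOKENS <- c("", "NA", "na", "nan", "NaN", ".")

# strsplit drops trailing empty fields; a sentinel field keeps them
split_tsv <- function(lines) {
  lines <- as.character(lines)  # empty tabix results can surface as NULL
  if (!length(lines)) return(list())
  lapply(strsplit(paste0(lines, "\t\r"), "\t", fixed = TRUE),
         function(f) f[-length(f)])
}

# parse data rows (split fields) into a freq_table; `lineno` used in errors
parse_rows <- function(fields, samples, lineno) {
  n <- length(fields)
  ncol_expect <- length(samples) + 2L
  if (n == 0) {
    return(freq_table(values = matrix(numeric(), 0, length(samples),
                                      dimnames = list(NULL, samples))))
  }
  widths <- lengths(fields)
  if (any(widths != ncol_expect)) {
    i <- which(widths != ncol_expect)[1L]
    stop_data(sprintf("line %d: expected %d fields, found %d",
                      lineno[i], ncol_expect, widths[i]))
  }
  m <- matrix(unlist(fields, use.names = FALSE), nrow = n, byrow = TRUE)
  chrom <- m[, 1L]
  pos <- suppressWarnings(as.numeric(m[, 2L]))
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1L]
    stop_data(sprintf("line %d: non-numeric position '%s'", lineno[i],
                      m[i, 2L]))
  }
  raw <- m[, -(1:2), drop = FALSE]
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  vals[raw %in% MISSING_TOKENS] <- NA_real_
  bad <- which(is.na(vals) & !(raw %in% MISSING_TOKENS) & !is.na(raw))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% n) + 1L
    stop_data(sprintf("line %d: non-numeric frequency '%s'", lineno[i],
                      raw[bad[1L]]))
  }
  out <- which(!is.na(vals) & (vals < 0 | vals > 1))
  if (length(out)) {
    i <- ((out[1L] - 1L) %% n) + 1L
    stop_data(sprintf("line %d: frequency %s outside [0, 1]", lineno[i],
                      raw[out[1L]]))
  }
  colnames(vals) <- samples
  freq_table(chrom, pos, vals)
}

check_header <- function(header_line, path) {
  if (is.na(header_line) || !nzchar(header_line)) {
    stop_data(sprintf("%s: missing or empty header line", path))
  }
  h <- strsplit(header_line, "\t", fixed = TRUE)[[1L]]
  if (length(h) < 2L) {
    stop_data(sprintf(
      "%s: malformed header: need at least chrom and position columns", path))
  }
  samples <- h[-(1:2)]
  if (length(samples) && (any(!nzchar(samples)) || anyDuplicated(samples))) {
    stop_data(sprintf("%s: malformed header: empty or duplicate sample names",
                      path))
  }
  samples
}

#' Read a modification-frequency table from TSV
#'
#' Reads the tab-separated table dialect (`.tsv`, `.tsv.gz` or block-gzipped)
#' in which the first column is the chromosome, the second the 1-based
#' position and every further column an individual or haplotype. Empty
#' fields and NA/nan tokens are missing values. Rows may be unsorted on
#' disk; the result is always position-sorted.
#'
#' @param path Path to the table file.
#' @param region Optional `genomic_region` (or region string); rows outside
#'   it are excluded. Uses the tabix index when one is present, otherwise
#'   falls back to a full scan.
#' @return A `freq_table`.
#' @export
read_table <- function(path, region = NULL) {
  if (!file.exists(path)) stop_data(sprintf("no such file: %s", path))
  if (!is.null(region) && file.exists(paste0(path, ".tbi"))) {
    return(query_region(path, region))
  }
  con <- gzfile(path, "rt")  # reads plain, gzip and bgzf alike
  on.exit(close(con))
  lines <- readLines(con)
  samples <- check_header(lines[1L], path)
  body <- lines[-1L]
  tab <- parse_rows(split_tsv(body), samples,
                    lineno = seq_along(body) + 1L)
  if (!is.null(region)) tab <- subset_region(tab, region)
  tab
}

#' Write a modification-frequency table
#'
#' Writes the canonical on-disk dialect: a block-gzip-compressed TSV with a
#' single header line, frequencies rounded to 4 decimal places (sub-read
#' precision is meaningless and this keeps cohort-scale files compact), and
#' missing cells as empty fields. With `index = TRUE` a tabix index is
#' written alongside, enabling fast region retrieval with
#' [query_region()].
#'
#' @param table A `freq_table`.
#' @param path Destination path (conventionally `.tsv.gz`).
#' @param index Write a tabix index (`.tbi`) next to the file?
#' @return Invisibly, the index path (or `NULL` when `index = FALSE`).
#' @export
write_table <- function(table, path, index = TRUE) {
  stopifnot(inherits(table, "freq_table"))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  header <- paste(c("chrom", "position", table$samples), collapse = "\t")
  if (n_sites(table) > 0) {
    txt <- ifelse(is.na(table$values), "",
                  formatC(table$values, format = "f", digits = 4))
    dim(txt) <- dim(table$values)
    rows <- do.call(paste, c(list(table$chrom, as.integer(table$position)),
                             lapply(seq_len(ncol(txt)),
                                    function(j) txt[, j]),
                             sep = "\t"))
  } else {
    rows <- character()
  }
  writeLines(c(header, rows), tmp)
  dest <- Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
  if (!index) return(invisible(NULL))
  idx <- Rsamtools::indexTabix(dest, seq = 1L, start = 2L, end = 2L,
                               skip = 1L)
  invisible(idx)
}

#' Query an indexed table for a genomic region
#'
#' Retrieves exactly the rows with the region's chromosome and position
#' between its bounds (inclusive) from a tabix-indexed table written by
#' [write_table()], without scanning the whole file.
#'
#' @param path Path to an indexed `.tsv.gz` table (or an open
#'   `Rsamtools::TabixFile` for repeated queries).
#' @param region A `genomic_region` or region string.
#' @return A `freq_table` with the matching rows in ascending position order.
#' @export
query_region <- function(path, region) {
  region <- parse_region(region)
  if (inherits(path, "TabixFile")) {
    tbx <- path
    src <- tbx$path
  } else {
    src <- path
    if (!file.exists(paste0(path, ".tbi"))) {
      stop_data(sprintf(
        "%s has no tabix index; re-write it with write_table(index = TRUE)",
        path))
    }
    tbx <- Rsamtools::TabixFile(path)
    open(tbx)
    on.exit(close(tbx))
  }
  con <- gzfile(src, "rt")  # the header line is not part of the index
  header <- readLines(con, n = 1L)
  close(con)
  samples <- check_header(header[1L], src)
  if (!(region$chrom %in% Rsamtools::seqnamesTabix(tbx))) {
    return(parse_rows(list(), samples, integer()))
  }
  lines <- Rsamtools::scanTabix(tbx, param = region_granges(region))[[1L]]
  parse_rows(split_tsv(lines), samples,
             lineno = seq_along(lines))
}
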