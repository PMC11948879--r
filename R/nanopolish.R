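# Nanopolish methylation-caller input: per-read, per-CpG-group records with
# a log-likelihood ratio (methylated vs unmethylated). Groups of num_motifs
# nearby CpGs share one call; they are split back into per-site calls at the
# CG offsets of the local sequence context before counting.

NANOPOLISH_COLUMNS <- c("chromosome", "strand", "start", "end", "read_name",
                        "log_lik_ratio", "log_lik_methylated",
                        "log_lik_unmethylated", "num_calling_strands",
                        "num_motifs", "sequence")

#' Read a nanopolish methylation call file
#'
#' @param path Tab-separated output of the caller's CpG model (plain or
#'   gzipped), with its standard header.
#' @return data.frame with one row per call-group record and typed numeric
#'   columns.
#' @export
parse_nanopolish <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("no such file: %s", path))
  df <- utils::read.delim(gzfile(path), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(setdiff(NANOPOLISH_COLUMNS, "end"), names(df))
  if (length(missing_cols)) {
    stop_data(sprintf("%s: missing required column(s): %s", path,
                      paste(missing_cols, collapse = ", ")))
  }
  for (col in c("start", "end", "log_lik_ratio", "num_motifs")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Per-site counts from nanopolish call groups
#'
#' Discards weak calls (`|log_lik_ratio| < llr_cutoff`), splits each
#' surviving group of `num_motifs` CpGs into per-site calls at the CG
#' offsets found in its `sequence` context (each inheriting the group's
#' call: methylated when the ratio is positive), and tallies per-site
#' modified / valid counts. Site positions are
#' `start + (CG offset - first CG offset)`: the group anchor is the first
#' CpG, so off-by-one errors in the offset arithmetic surface immediately
#' in tests.
#'
#' @param records data.frame from [parse_nanopolish()].
#' @param llr_cutoff Positive log-likelihood-ratio magnitude below which a
#'   call is too ambiguous to count (default 2.0, the caller's conventional
#'   frequency cutoff).
#' @param sample Column name for the resulting counts (default `"sample"`).
#' @return data.frame of per-site counts as for [counts_to_table()].
#' @export
nanopolish_to_counts <- function(records, llr_cutoff = 2.0,
                                 sample = "sample") {
  if (!is.numeric(llr_cutoff) || llr_cutoff <= 0) {
    stop_usage("llr_cutoff must be > 0")
  }
  keep <- abs(records$log_lik_ratio) >= llr_cutoff
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) {
    return(data.frame(chrom = character(), position = integer(),
                      sample = character(), n_modified = integer(),
                      n_valid = integer()))
  }
  chroms <- list()
  positions <- list()
  meth <- list()
  for (i in seq_len(nrow(records))) {
    k <- as.integer(records$num_motifs[i])
    if (k == 1L) {
      pos <- records$start[i]
    } else {
      offs <- as.integer(gregexpr("CG", toupper(records$sequence[i]),
                                  fixed = TRUE)[[1L]])
      if (offs[1L] == -1L || length(offs) < k) {
        stop_data(sprintf(
          "record %d (%s:%d): num_motifs=%d but sequence has %d CG(s)",
          i, records$chromosome[i], as.integer(records$start[i]), k,
          if (offs[1L] == -1L) 0L else length(offs)))
      }
      offs <- offs[seq_len(k)]
      pos <- records$start[i] + (offs - offs[1L])
    }
    chroms[[i]] <- rep(records$chromosome[i], length(pos))
    positions[[i]] <- pos
    meth[[i]] <- rep(records$log_lik_ratio[i] > 0, length(pos))
  }
  chrom <- unlist(chroms, use.names = FALSE)
  pos <- as.integer(unlist(positions, use.names = FALSE))
  m <- unlist(meth, use.names = FALSE)
  key <- paste0(chrom, "\r", pos)
  u <- !duplicated(key)
  f <- factor(key, levels = key[u])
  data.frame(chrom = chrom[u], position = pos[u], sample = sample,
             n_modified = as.integer(tapply(m, f, sum)),
             n_valid = as.integer(table(f)), row.names = NULL)
}

#' Frequency table from nanopolish call files
#'
#' One column per input file.
#'
#' @param paths Nanopolish call file paths.
#' @param sample_names Column names; default file names without extension.
#' @param llr_cutoff See [nanopolish_to_counts()].
#' @param region Optional region restriction applied to the result.
#' @return A `freq_table`.
#' @export
nanopolish_to_table <- function(paths, sample_names = NULL, llr_cutoff = 2.0,
                                region = NULL) {
  if (is.null(sample_names)) {
    sample_names <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(paths))
  }
  if (length(sample_names) != length(paths)) {
    stop_usage("sample_names must match paths in length")
  }
  parts <- lapply(seq_along(paths), function(i) {
    counts_to_table(nanopolish_to_counts(parse_nanopolish(paths[i]),
                                         llr_cutoff = llr_cutoff,
                                         sample = sample_names[i]))
  })
  tab <- merge_tables(parts)
  if (!is.null(region)) tab <- subset_region(tab, region)
  tab
}
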