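# Genomic regions: 1-based, inclusive on both ends, matching the region
# strings users type ("chr20:58,839,718-58,911,192") and the convention of
# single-position tabix records.

#' Sentinel meaning "to the end of the chromosome"
#'
#' Largest representable coordinate; used as the `end` of a region parsed
#' from a bare chromosome name.
#' @export
REGION_END_MAX <- .Machine$integer.max

#' Construct a genomic region
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 1-based inclusive start coordinate.
#' @param end 1-based inclusive end coordinate, `>= start`.
#' @return An object of class `genomic_region` with fields `chrom`, `start`,
#'   `end`.
#' @examples
#' genomic_region("chr20", 58839718, 58911192)
#' @export
genomic_region <- function(chrom, start = 1L, end = REGION_END_MAX) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) ||
      !nzchar(chrom)) {
    stop_usage("region chromosome name must be a non-empty string")
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || start != floor(start) ||
      end != floor(end)) {
    stop_usage("region coordinates must be positive integers")
  }
  if (end < start) {
    stop_usage(sprintf("invalid region %s:%d-%d: start > end",
                       chrom, as.integer(start), as.integer(end)))
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_region")
}

#' Parse a region string
#'
#' Accepts `"chrom"`, `"chrom:start-end"` and the same with thousands
#' separators (commas, thin/narrow spaces) in the coordinates, as regions
#' are commonly printed (e.g. `"chr20:58,839,718-58,911,192"`). An en-dash
#' may stand in for the hyphen between coordinates. A bare chromosome name
#' means the whole chromosome (`start = 1`, `end = REGION_END_MAX`).
#'
#' @param text Region string.
#' @return A `genomic_region`.
#' @examples
#' parse_region("chr20:58,839,718-58,911,192")
#' parse_region("chr7")
#' @export
parse_region <- function(text) {
  if (inherits(text, "genomic_region")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop_usage("region must be a single string")
  }
  txt <- trimws(text)
  if (!nzchar(txt)) stop_usage("empty region string")
  if (!grepl(":", txt, fixed = TRUE)) {
    return(genomic_region(txt))
  }
  chrom <- sub(":[^:]*$", "", txt)
  range <- sub("^.*:", "", txt)
  if (!nzchar(chrom)) {
    stop_usage(sprintf("region '%s': empty chromosome name", text))
  }
  # strip thousands separators before splitting on the coordinate dash
  range <- gsub("[,\u202f\u2009 ]", "", range)
  range <- gsub("\u2013", "-", range)  # en-dash as printed in journals
  parts <- strsplit(range, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !all(nzchar(parts))) {
    stop_usage(sprintf("region '%s': expected chrom:start-end", text))
  }
  coords <- suppressWarnings(as.numeric(parts))
  if (anyNA(coords)) {
    bad <- parts[which(is.na(coords))[1L]]
    stop_usage(sprintf("region '%s': non-numeric coordinate '%s'", text, bad))
  }
  genomic_region(chrom, coords[1L], coords[2L])
}

#' @export
format.genomic_region <- function(x, ...) {
  if (x$start == 1 && x$end == REGION_END_MAX) return(x$chrom)
  sprintf("%s:%d-%d", x$chrom, as.integer(x$start), as.integer(x$end))
}

#' @export
print.genomic_region <- function(x, ...) {
  cat("<genomic_region> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.genomic_region <- function(x, ...) format(x)

# region -> GRanges (internal; all on-disk/tabix arithmetic stays here)
region_granges <- function(region) {
  GenomicRanges::GRanges(region$chrom,
                         IRanges::IRanges(region$start, region$end))
}
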