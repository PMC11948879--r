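# Shared internals: condition classes, chromosome ordering, logging.

# usage errors (bad arguments / malformed region strings) -> exit code 2;
# data errors (malformed files, empty results) -> exit code 1
stop_usage <- function(msg) {
  stop(structure(class = c("modfreqr_usage_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_data <- function(msg) {
  stop(structure(class = c("modfreqr_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @keywords internal
# Natural chromosome order: lexicographic on the non-numeric stem, numeric on
# a trailing integer, so chr2 < chr10 < chr22 < chrX.
chrom_order_key <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", chrom)))
  stem <- ifelse(is.na(num), chrom, sub("[0-9]+$", "", chrom))
  list(stem = stem, num = ifelse(is.na(num), -1L, num), raw = chrom)
}

order_sites <- function(chrom, position) {
  k <- chrom_order_key(chrom)
  order(k$stem, k$num, k$raw, position, method = "radix")
}

# structured log line on stderr: "[modfreqr] key=value key=value ..."
log_fields <- function(...) {
  kv <- list(...)
  stopifnot(!is.null(names(kv)), all(nzchar(names(kv))))
  vals <- vapply(kv, function(v) paste(format(v, trim = TRUE), collapse = ","),
                 character(1))
  message("[modfreqr] ", paste(names(kv), vals, sep = "=", collapse = " "))
}
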