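# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use different algorithms from the package code
# (per-base walks, linear scans) so agreement is meaningful.

# Brute-force MM/ML decoder: walks the sequenced read base by base,
# counting canonical-base occurrences against the skip list.
naive_decode <- function(seq, is_reverse, aligned_pairs, mm, ml,
                         read_id = "read") {
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  ref_of <- if (is_reverse) rev(aligned_pairs) else aligned_pairs
  runs <- strsplit(sub(";+$", "", mm), ";", fixed = TRUE)[[1L]]
  runs <- runs[nzchar(runs)]
  ml <- as.integer(ml)
  ml_i <- 0L
  rows <- list()
  for (run in runs) {
    parts <- strsplit(run, ",", fixed = TRUE)[[1L]]
    head <- parts[1L]
    deltas <- if (length(parts) > 1L) as.integer(parts[-1L]) else integer()
    B <- substr(head, 1L, 1L)
    run_strand <- substr(head, 2L, 2L)
    tail <- substring(head, 3L)
    flag <- "."
    if (grepl("[.?]$", tail)) {
      flag <- substring(tail, nchar(tail))
      tail <- substring(tail, 1L, nchar(tail) - 1L)
    }
    codes <- if (grepl("^[0-9]+$", tail)) tail
             else strsplit(tail, "", fixed = TRUE)[[1L]]
    strand <- if (xor(is_reverse, run_strand == "-")) "-" else "+"
    since <- 0L
    d_i <- 1L
    for (i in seq_along(bases)) {
      if (B != "N" && bases[i] != B) next
      if (d_i <= length(deltas) && since == deltas[d_i]) {
        for (code in codes) {
          ml_i <- ml_i + 1L
          rows[[length(rows) + 1L]] <- list(
            read_pos = i, ref_pos = ref_of[i], strand = strand,
            code = code, prob = (ml[ml_i] + 0.5) / 256, implied = FALSE)
        }
        since <- 0L
        d_i <- d_i + 1L
      } else {
        if (flag == ".") {
          for (code in codes) {
            rows[[length(rows) + 1L]] <- list(
              read_pos = i, ref_pos = ref_of[i], strand = strand,
              code = code, prob = 0, implied = TRUE)
          }
        }
        since <- since + 1L
      }
    }
    if (d_i <= length(deltas)) {
      stop("oracle: MM lists more calls than canonical bases available")
    }
  }
  if (ml_i != length(ml)) stop("oracle: ML length mismatch")
  df <- do.call(rbind, lapply(rows, as.data.frame))
  if (is.null(df)) {
    df <- data.frame(read_pos = integer(), ref_pos = integer(),
                     strand = character(), code = character(),
                     prob = numeric(), implied = logical())
  }
  df <- df[!is.na(df$ref_pos), , drop = FALSE]
  df$read_id <- rep(read_id, nrow(df))
  df <- df[order(df$read_pos, df$code),
           c("read_id", "read_pos", "ref_pos", "strand", "code", "prob",
             "implied")]
  rownames(df) <- NULL
  df
}

# Random read + MM/ML generator for decoder stress tests. Produces the
# stored-orientation alignment map (with soft clips and insertions) and an
# MM tag over the sequenced orientation.
random_mod_read <- function(id) {
  n <- sample(20:60, 1)
  stored <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
  clip5 <- sample(0:3, 1)
  clip3 <- sample(0:3, 1)
  pairs <- rep(NA_integer_, n)
  core <- setdiff(seq_len(n), c(seq_len(clip5), n - seq_len(clip3) + 1L))
  ins <- if (length(core) > 4) sort(sample(core, sample(0:2, 1))) else integer()
  aligned <- setdiff(core, ins)
  # strictly increasing reference map with occasional deletions
  pairs[aligned] <- 100L + seq_along(aligned) +
    cumsum(sample(0:1, length(aligned), replace = TRUE, prob = c(0.9, 0.1)))
  is_rev <- sample(c(TRUE, FALSE), 1)
  sequenced <- if (is_rev) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(stored, "", fixed = TRUE)[[1L]]), collapse = ""))
  } else stored
  B <- sample(c("C", "A", "G", "N"), 1, prob = c(0.6, 0.15, 0.15, 0.1))
  occ <- if (B == "N") seq_len(nchar(sequenced))
         else which(strsplit(sequenced, "", fixed = TRUE)[[1L]] == B)
  codes <- sample(c("m", "h", "mh"), 1, prob = c(0.6, 0.2, 0.2))
  ncodes <- nchar(codes)
  flag <- sample(c("?", "."), 1)
  listed <- if (length(occ)) sort(sample(seq_along(occ),
                                         sample(0:length(occ), 1)))
            else integer()
  deltas <- if (length(listed)) diff(c(0L, listed)) - 1L else integer()
  mm <- if (length(listed)) {
    sprintf("%s+%s%s,%s;", B, codes, flag, paste(deltas, collapse = ","))
  } else {
    sprintf("%s+%s%s;", B, codes, flag)
  }
  ml <- if (length(listed)) sample(0:255, length(listed) * ncodes,
                                   replace = TRUE) else integer()
  list(id = id, seq = sequenced, is_reverse = is_rev, pairs = pairs,
       mm = mm, ml = ml)
}

# linear-scan oracle for region retrieval
scan_oracle <- function(table, region) {
  region <- parse_region(region)
  keep <- table$chrom == region$chrom & table$position >= region$start &
    table$position <= region$end
  list(chrom = table$chrom[keep], position = table$position[keep],
       values = round(table$values[keep, , drop = FALSE], 4))
}

# pull the JSON data payload back out of a rendered HTML figure
extract_payload <- function(html_path) {
  doc <- paste(readLines(html_path), collapse = "\n")
  json <- regmatches(doc, regexpr('(?<=modfreqr-data">).*?(?=</script>)',
                                  doc, perl = TRUE))
  jsonlite::fromJSON(json, simplifyMatrix = TRUE)
}

# small literal table
tiny_table <- function(chrom = rep("chr1", 5),
                       position = c(100, 200, 300, 400, 500),
                       values = NULL, samples = c("S1", "S2")) {
  if (is.null(values)) {
    values <- matrix(seq(0, 1, length.out = length(position) *
                           length(samples)),
                     nrow = length(position),
                     dimnames = list(NULL, samples))
  }
  freq_table(chrom, position, values)
}

# two-gene annotation fixture spec
demo_genes <- function() {
  list(
    list(gene_id = "G1", name = "GENE1", chrom = "chr1", start = 900,
         end = 4000, strand = "+",
         transcripts = list(
           list(transcript_id = "T1a",
                exons = data.frame(start = c(950, 2000, 3500),
                                   end = c(1100, 2200, 3900))),
           list(transcript_id = "T1b",
                exons = data.frame(start = c(950, 3500),
                                   end = c(1200, 3900))))),
    list(gene_id = "G2", name = "GENE2", chrom = "chr1", start = 3600,
         end = 5200, strand = "-",
         transcripts = list(
           list(transcript_id = "T2a",
                exons = data.frame(start = c(3700, 5000),
                                   end = c(3800, 5100))))))
}
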