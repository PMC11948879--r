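# Decoding MM/ML modified-base tags and aggregating per-read calls into
# per-CpG-site modification frequencies, with haplotype partitioning on the
# HP tag.
#
# Conventions, stated once:
#  * `seq` passed to decode_read_mods is the read AS SEQUENCED (for a
#    reverse-strand alignment this is the reverse complement of the SEQ
#    stored in the BAM record). MM skip counts run over canonical-base
#    occurrences in this orientation, per the SAM optional-tag grammar.
#  * `aligned_pairs` is, for each sequenced-read base, the 1-based reference
#    coordinate it is aligned to, or NA for soft-clipped/inserted bases.
#  * 8-bit qualities q dequantize to the interval midpoint (q + 0.5)/256.
#  * A call from a reverse-strand read sits on the reference G of a CpG;
#    aggregate_cpg() folds it onto the forward-strand C (position - 1) so
#    both strands of a CpG count toward one site.

#' Reference coordinates of each base of a stored read
#'
#' Expands a CIGAR string into a per-base map from read coordinates (in the
#' orientation stored in the BAM record) to 1-based reference coordinates;
#' soft-clipped and inserted bases map to `NA`.
#'
#' @param cigar CIGAR string.
#' @param pos 1-based leftmost mapping position.
#' @return Integer vector with one entry per stored read base.
#' @export
cigar_ref_positions <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(ops) || paste(ops, collapse = "") != cigar) {
    stop_data(sprintf("malformed CIGAR '%s'", cigar))
  }
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- substring(ops, nchar(ops))
  out <- integer(0)
  ref <- as.integer(pos)
  for (i in seq_along(op)) {
    switch(op[i],
      "M" = , "=" = , "X" = {
        out <- c(out, seq.int(ref, length.out = len[i]))
        ref <- ref + len[i]
      },
      "I" = , "S" = out <- c(out, rep(NA_integer_, len[i])),
      "D" = , "N" = ref <- ref + len[i],
      "H" = , "P" = NULL)
  }
  out
}

revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# one MM run: "C+m?,0,2" -> list(base, strand, codes, flag, deltas)
parse_mm_run <- function(run, read_id) {
  head <- sub(",.*$", "", run)
  deltas_txt <- if (grepl(",", run, fixed = TRUE)) sub("^[^,]*,", "", run)
                else ""
  m <- regmatches(head,
                  regexec("^([ACGTUN])([-+])([a-z]+|[0-9]+)([.?]?)$", head))[[1L]]
  if (length(m) == 0) {
    stop_data(sprintf("read %s: malformed MM run '%s'", read_id, run))
  }
  codes <- if (grepl("^[0-9]+$", m[4L])) m[4L]
           else strsplit(m[4L], "", fixed = TRUE)[[1L]]
  deltas <- if (nzchar(deltas_txt)) {
    d <- suppressWarnings(as.integer(strsplit(deltas_txt, ",",
                                              fixed = TRUE)[[1L]]))
    if (anyNA(d) || any(d < 0)) {
      stop_data(sprintf("read %s: invalid MM skip count in run '%s'",
                        read_id, run))
    }
    d
  } else integer()
  list(base = m[2L], strand = m[3L], codes = codes,
       flag = if (nzchar(m[5L])) m[5L] else ".", deltas = deltas)
}

#' Decode the modified-base calls of one read
#'
#' Walks the MM tag's skip-count runs over the canonical-base occurrences of
#' the sequenced read, pairs each listed call with its 8-bit ML quality, and
#' places calls on reference coordinates through the alignment. Under the
#' `.` flag, canonical bases that the run skips (and any after its last
#' listed call) are implied unmodified calls with probability 0 for that
#' code; under `?` they yield no call. Calls on soft-clipped or inserted
#' bases are dropped.
#'
#' @param seq Read bases as sequenced (reverse-complement of the stored SEQ
#'   for reverse-strand alignments).
#' @param is_reverse Was the read aligned to the reverse strand?
#' @param aligned_pairs Integer vector mapping each *stored-orientation* read
#'   base to its 1-based reference coordinate (`NA` when unaligned), e.g.
#'   from [cigar_ref_positions()].
#' @param mm MM tag string (e.g. `"C+m?,0,2;"`).
#' @param ml Integer vector of 8-bit qualities (the ML tag), one per listed
#'   (position, code) pair across all runs.
#' @param read_id Read name, used in error messages and the output.
#' @return A data.frame with one row per call: `read_id`, `read_pos`
#'   (sequenced orientation), `ref_pos`, `strand` (alignment strand of the
#'   call), `code`, `prob`, `implied`.
#' @export
decode_read_mods <- function(seq, is_reverse, aligned_pairs, mm, ml,
                             read_id = "read") {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (length(aligned_pairs) != n) {
    stop_data(sprintf("read %s: aligned_pairs length %d != read length %d",
                      read_id, length(aligned_pairs), n))
  }
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  # reference coordinate of each sequenced-orientation base
  ref_of <- if (is_reverse) rev(aligned_pairs) else aligned_pairs
  mm <- sub(";$", "", mm)
  runs <- if (nzchar(mm)) strsplit(mm, ";", fixed = TRUE)[[1L]] else character()
  ml <- as.integer(ml)
  if (any(ml < 0 | ml > 255)) {
    stop_data(sprintf("read %s: ML quality outside 0..255", read_id))
  }
  out <- vector("list", length(runs))
  ml_used <- 0L
  for (ri in seq_along(runs)) {
    run <- parse_mm_run(runs[ri], read_id)
    occ <- if (run$base == "N") seq_len(n) else which(bases == run$base)
    ncodes <- length(run$codes)
    nlisted <- length(run$deltas)
    need <- nlisted * ncodes
    if (ml_used + need > length(ml)) {
      stop_data(sprintf(
        "read %s: ML tag too short (run '%s' needs %d more values)",
        read_id, runs[ri], ml_used + need - length(ml)))
    }
    probs <- matrix(ml[ml_used + seq_len(need)], nrow = ncodes)
    ml_used <- ml_used + need
    listed_idx <- integer(nlisted)
    cursor <- 0L
    for (k in seq_len(nlisted)) {
      cursor <- cursor + run$deltas[k] + 1L
      if (cursor > length(occ)) {
        stop_data(sprintf(
          "read %s: MM run '%s' skips past the end of the read",
          read_id, runs[ri]))
      }
      listed_idx[k] <- occ[cursor]
    }
    strand <- call_strand(is_reverse, run$strand)
    rows <- list()
    if (nlisted > 0) {
      for (ci in seq_len(ncodes)) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = read_id, read_pos = listed_idx,
          ref_pos = ref_of[listed_idx], strand = strand,
          code = run$codes[ci], prob = (probs[ci, ] + 0.5) / 256,
          implied = FALSE, stringsAsFactors = FALSE)
      }
    }
    if (run$flag == ".") {
      skipped <- setdiff(occ, listed_idx)
      if (length(skipped)) {
        for (ci in seq_len(ncodes)) {
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = read_id, read_pos = skipped,
            ref_pos = ref_of[skipped], strand = strand,
            code = run$codes[ci], prob = 0, implied = TRUE,
            stringsAsFactors = FALSE)
        }
      }
    }
    out[[ri]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  if (ml_used != length(ml)) {
    stop_data(sprintf("read %s: ML has %d values but MM lists %d calls",
                      read_id, length(ml), ml_used))
  }
  calls <- do.call(rbind, c(out, list(empty_calls())))
  calls <- calls[!is.na(calls$ref_pos), , drop = FALSE]
  calls <- calls[order(calls$read_pos, calls$code), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(read_id = character(), read_pos = integer(),
             ref_pos = integer(), strand = character(), code = character(),
             prob = numeric(), implied = logical(), stringsAsFactors = FALSE)
}

# alignment strand carrying the call: MM '+' means the sequenced strand
call_strand <- function(is_reverse, run_strand) {
  plus <- xor(is_reverse, run_strand == "-")
  if (plus) "-" else "+"
}

#' Partition reads by haplotype tag
#'
#' Groups read identifiers by the integer value of a phasing tag (HP by
#' convention): value v goes to group `<prefix>v`, untagged reads to
#' `"ungrouped"`. Groups are disjoint and cover the input.
#'
#' @param read_ids Character vector of read names.
#' @param tag_values Integer vector of haplotype-tag values (`NA` =
#'   untagged), parallel to `read_ids`.
#' @param prefix Group-name prefix (default `"H"`, giving H1/H2).
#' @return Named list of character vectors of read ids.
#' @export
partition_reads <- function(read_ids, tag_values, prefix = "H") {
  stopifnot(length(read_ids) == length(tag_values))
  label <- ifelse(is.na(tag_values), "ungrouped",
                  paste0(prefix, as.integer(tag_values)))
  split(read_ids, factor(label, levels = unique(label)))
}

#' CpG positions of a reference sequence
#'
#' 1-based positions of the C of every CG dinucleotide on the forward
#' strand (the reverse-strand mirror CpG is folded onto the same position by
#' [aggregate_cpg()]).
#'
#' @param reference_seq Character scalar (or DNAString) over ACGTN,
#'   case-insensitive.
#' @return Strictly increasing integer vector of positions.
#' @export
cpg_sites <- function(reference_seq) {
  s <- toupper(as.character(reference_seq))
  if (!nzchar(s)) return(integer())
  hits <- gregexpr("CG", s, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer() else as.integer(hits)
}

#' Aggregate per-read calls into per-site counts
#'
#' Combines strands — a reverse-strand call on the G of a CpG is remapped to
#' the paired forward C one base to the left — then counts, per CpG site,
#' the calls confident enough to use (`max(p, 1-p) >= min_confidence`) and
#' among those the modified ones (`p >= mod_threshold`; a call exactly at
#' the threshold counts as modified). Calls at non-CpG positions are
#' ignored. Sites with no valid call emit no record (they are missing, not
#' zero).
#'
#' @param calls data.frame of calls from [decode_read_mods()] (one sample or
#'   haplotype group, one contig).
#' @param sites Integer vector of CpG positions from [cpg_sites()].
#' @param mod_code Modification code to count (default `"m"`, 5mCG; `"h"`
#'   selects 5hmCG).
#' @param mod_threshold Probability at or above which a call is modified.
#' @param min_confidence Calls with `max(p, 1-p)` below this are dropped
#'   from coverage entirely (default 0 keeps every call).
#' @return data.frame with columns `position`, `n_modified`, `n_valid`,
#'   `frequency`, sorted by position.
#' @export
aggregate_cpg <- function(calls, sites, mod_code = "m", mod_threshold = 0.5,
                          min_confidence = 0) {
  calls <- calls[calls$code == mod_code, , drop = FALSE]
  if (nrow(calls) == 0) {
    return(data.frame(position = integer(), n_modified = integer(),
                      n_valid = integer(), frequency = numeric()))
  }
  pos <- ifelse(calls$strand == "-", calls$ref_pos - 1L, calls$ref_pos)
  keep <- pos %in% sites
  pos <- pos[keep]
  p <- calls$prob[keep]
  valid <- pmax(p, 1 - p) >= min_confidence
  pos <- pos[valid]
  p <- p[valid]
  if (!length(pos)) {
    return(data.frame(position = integer(), n_modified = integer(),
                      n_valid = integer(), frequency = numeric()))
  }
  f <- factor(pos, levels = sort(unique(pos)))
  n_valid <- as.integer(table(f))
  n_mod <- as.integer(tapply(p >= mod_threshold, f, sum))
  data.frame(position = as.integer(levels(f)), n_modified = n_mod,
             n_valid = n_valid, frequency = n_mod / n_valid)
}

# ---- BAM -> frequency table -------------------------------------------------

scan_modbam <- function(path, region = NULL) {
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  tags <- c("MM", "ML", "HP", "Mm", "Ml")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what, tag = tags)
  } else {
    Rsamtools::ScanBamParam(what = what, tag = tags,
                            which = region_granges(region))
  }
  res <- Rsamtools::scanBam(path, param = param)
  # with a `which`, results come back per range; flatten
  if (length(res) > 1) {
    merged <- res[[1L]]
    for (r in res[-1L]) {
      for (w in what) merged[[w]] <- c(merged[[w]], r[[w]])
      for (t in names(merged$tag)) {
        merged$tag[[t]] <- c(merged$tag[[t]], r$tag[[t]])
      }
    }
    res <- list(merged)
  }
  res[[1L]]
}

# per-read records worth keeping: primary, mapped, mapq >= 1, not duplicate
modbam_reads <- function(path, region = NULL) {
  b <- scan_modbam(path, region)
  mm <- b$tag$MM
  ml <- b$tag$ML
  if (is.null(mm)) mm <- b$tag$Mm
  if (is.null(ml)) ml <- b$tag$Ml
  n <- length(b$qname)
  if (n == 0 || is.null(mm) || all(is.na(mm))) {
    stop_data(sprintf("%s: no modification (MM/ML) tags found", path))
  }
  flag <- b$flag
  keep <- !bitwAnd(flag, 0x4) & !bitwAnd(flag, 0x100) &
    !bitwAnd(flag, 0x800) & !bitwAnd(flag, 0x400) & b$mapq >= 1L & !is.na(mm)
  hp <- if (is.null(b$tag$HP)) rep(NA_integer_, n) else b$tag$HP
  list(qname = b$qname[keep], flag = flag[keep],
       rname = as.character(b$rname)[keep], pos = b$pos[keep],
       cigar = b$cigar[keep], seq = as.character(b$seq)[keep],
       mm = mm[keep], ml = ml[keep], hp = hp[keep])
}

# decode + aggregate one file into per-(contig, haplotype-group) counts
modbam_counts <- function(path, sites_by_contig, region = NULL,
                          partition = FALSE, prefix = "H",
                          include_ungrouped = FALSE, mod_code = "m",
                          mod_threshold = 0.5, min_confidence = 0) {
  rd <- modbam_reads(path, region)
  n <- length(rd$qname)
  group <- if (partition) {
    ifelse(is.na(rd$hp), "ungrouped", paste0(prefix, rd$hp))
  } else {
    rep("all", n)
  }
  calls_by <- list()
  for (i in seq_len(n)) {
    if (partition && !include_ungrouped && group[i] == "ungrouped") next
    is_rev <- bitwAnd(rd$flag[i], 0x10) > 0
    seq_stored <- rd$seq[i]
    seq_sequenced <- if (is_rev) revcomp(seq_stored) else seq_stored
    pairs <- cigar_ref_positions(rd$cigar[i], rd$pos[i])
    calls <- decode_read_mods(seq_sequenced, is_rev, pairs, rd$mm[i],
                              rd$ml[[i]], read_id = rd$qname[i])
    if (nrow(calls) == 0) next
    key <- paste0(rd$rname[i], "\r", group[i])
    calls_by[[key]] <- c(calls_by[[key]], list(calls))
  }
  out <- list()
  for (key in names(calls_by)) {
    contig <- sub("\r.*$", "", key)
    grp <- sub("^.*\r", "", key)
    sites <- sites_by_contig[[contig]]
    if (is.null(sites)) next
    calls <- do.call(rbind, calls_by[[key]])
    cnt <- aggregate_cpg(calls, sites, mod_code = mod_code,
                         mod_threshold = mod_threshold,
                         min_confidence = min_confidence)
    if (nrow(cnt) == 0) next
    cnt$chrom <- contig
    cnt$group <- grp
    out[[key]] <- cnt
  }
  do.call(rbind, c(out, list(data.frame(position = integer(),
                                        n_modified = integer(),
                                        n_valid = integer(),
                                        frequency = numeric(),
                                        chrom = character(),
                                        group = character()))))
}

#' Build a frequency table from modified-base-tagged alignments
#'
#' The multithreaded BAM-to-table computation: decodes MM/ML calls from each
#' file, restricts to CpG sites of the reference, optionally partitions
#' reads by haplotype tag (HP), combines CpG strands, and assembles one
#' frequency column per file (or per file x haplotype, suffixed `_H1`/`_H2`,
#' when `partition = TRUE`). Output is identical for any thread count.
#'
#' @param paths Character vector of BAM file paths (indexed when `region`
#'   is used).
#' @param reference Path to the reference FASTA (used to locate CpG sites),
#'   or a named list of per-contig CpG position vectors.
#' @param sample_names Column base names; defaults to file names without
#'   extension.
#' @param region Optional `genomic_region` restricting the scan.
#' @param partition Split each sample into per-haplotype columns?
#' @param include_ungrouped With `partition`, also emit an `_ungrouped`
#'   column for untagged reads (default: excluded).
#' @param mod_code Modification code (`"m"` or `"h"`).
#' @param mod_threshold,min_confidence Call thresholds, see
#'   [aggregate_cpg()].
#' @param prefix Haplotype column prefix (default `"H"`).
#' @param threads Number of worker processes for per-file decoding.
#' @return A `freq_table`.
#' @export
bam_to_table <- function(paths, reference, sample_names = NULL,
                         region = NULL, partition = FALSE,
                         include_ungrouped = FALSE, mod_code = "m",
                         mod_threshold = 0.5, min_confidence = 0,
                         prefix = "H", threads = 1L) {
  if (is.null(sample_names)) {
    sample_names <- sub("\\.(bam|cram|sam)$", "", basename(paths),
                        ignore.case = TRUE)
  }
  if (length(sample_names) != length(paths)) {
    stop_usage("sample_names must match paths in length")
  }
  if (anyDuplicated(sample_names)) stop_usage("sample names must be unique")
  sites_by_contig <- reference_cpg_sites(reference)
  if (!is.null(region)) region <- parse_region(region)
  worker <- function(i) {
    modbam_counts(paths[i], sites_by_contig, region = region,
                  partition = partition, prefix = prefix,
                  include_ungrouped = include_ungrouped,
                  mod_code = mod_code, mod_threshold = mod_threshold,
                  min_confidence = min_confidence)
  }
  idx <- seq_along(paths)
  counts <- if (threads > 1L) {
    res <- parallel::mclapply(idx, worker, mc.cores = threads,
                              mc.preschedule = TRUE)
    for (r in res) {
      if (inherits(r, "try-error")) stop(attr(r, "condition"))
    }
    res
  } else {
    lapply(idx, worker)
  }
  parts <- vector("list", length(paths))
  for (i in idx) {
    cnt <- counts[[i]]
    col_of <- function(g) if (g == "all") sample_names[i]
                          else paste0(sample_names[i], "_", g)
    cnt$sample <- vapply(cnt$group, col_of, character(1))
    parts[[i]] <- counts_to_table(cnt)
  }
  tab <- merge_tables(parts)
  if (!is.null(region)) tab <- subset_region(tab, region)
  tab
}

#' Assemble per-site counts into a frequency table
#'
#' @param counts data.frame with columns `chrom`, `position`, `sample`,
#'   `n_modified`, `n_valid` (rows with `n_valid = 0` are dropped: zero
#'   coverage is missing, not zero frequency).
#' @return A `freq_table` with `frequency = n_modified / n_valid`.
#' @export
counts_to_table <- function(counts) {
  counts <- counts[counts$n_valid > 0, , drop = FALSE]
  if (nrow(counts) == 0) return(freq_table())
  if (any(counts$n_modified > counts$n_valid) || any(counts$n_modified < 0)) {
    stop_data("invalid counts: need 0 <= n_modified <= n_valid")
  }
  keys <- paste0(counts$chrom, "\r", as.integer(counts$position))
  u <- !duplicated(keys)
  u_keys <- keys[u]
  samples <- unique(counts$sample)
  vals <- matrix(NA_real_, sum(u), length(samples),
                 dimnames = list(NULL, samples))
  ij <- cbind(match(keys, u_keys), match(counts$sample, samples))
  if (anyDuplicated(ij)) {
    stop_data("duplicate (site, sample) count records")
  }
  vals[ij] <- counts$n_modified / counts$n_valid
  freq_table(counts$chrom[u], counts$position[u], vals)
}

# reference FASTA path -> named list of CpG position vectors per contig
reference_cpg_sites <- function(reference) {
  if (is.list(reference)) return(reference)
  if (!file.exists(reference)) {
    stop_data(sprintf("reference FASTA not found: %s", reference))
  }
  seqs <- read_fasta(reference)
  lapply(seqs, cpg_sites)
}

# minimal FASTA reader (plain or gzip); sequences as character strings
read_fasta <- function(path) {
  lines <- readLines(gzfile(path))
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_data(sprintf("%s: not a FASTA file", path))
  id <- sub("^>([^ \t]+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  names(seqs) <- id[as.integer(names(seqs))]
  as.list(seqs)
}
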