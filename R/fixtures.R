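# Synthetic-data generators. Everything the toolchain consumes — reference
# FASTA, modified-base-tagged BAMs with HP haplotype tags, nanopolish call
# files, GFF3 gene models, cohort frequency tables — can be generated here
# with known ground truth, so downstream assertions are exact count
# arithmetic, not statistics. All generators are deterministic for a fixed
# seed.
#
# The default cohort emulates a haplotype-partitioned imprinted locus:
# maternal/paternal haplotype columns with high (~0.85) vs low (~0.10) mean
# methylation, the pattern that makes H1 and H2 separate at the root of the
# dendrogram.

#' Generate a reference sequence with CpGs at known positions
#'
#' Builds a random sequence whose CG dinucleotides occur exactly at the
#' returned positions: background bases are drawn from ACGT, every
#' accidental CG is broken, then CpGs are planted `spacing` apart.
#'
#' @param n_cpg Number of CpG sites (>= 1).
#' @param spacing Distance between consecutive CpG C positions (>= 2).
#' @param seed RNG seed.
#' @param chrom Contig name to associate with the sequence.
#' @param flank Bases before the first and after the last CpG.
#' @return List with `chrom`, `seq` (character scalar) and `positions`
#'   (1-based C positions of the CpGs).
#' @export
make_reference <- function(n_cpg, spacing = 10L, seed = 1L, chrom = "chr1",
                           flank = 10L) {
  stopifnot(n_cpg >= 1, spacing >= 2)
  set.seed(seed)
  len <- 2L * flank + (n_cpg - 1L) * spacing + 2L
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  # break accidental CGs: replace the G of every CG with T
  repeat {
    cg <- which(bases[-len] == "C" & bases[-1L] == "G")
    if (!length(cg)) break
    bases[cg + 1L] <- "T"
  }
  positions <- flank + 1L + (seq_len(n_cpg) - 1L) * spacing
  bases[positions] <- "C"
  bases[positions + 1L] <- "G"
  # planting must not create extra CpGs at the edges of each plant
  bases[positions - 1L][bases[positions - 1L] == "C"] <- "A"
  seq <- paste(bases, collapse = "")
  stopifnot(identical(cpg_sites(seq), as.integer(positions)))
  list(chrom = chrom, seq = seq, positions = as.integer(positions))
}

#' Write sequences as FASTA
#'
#' @param seqs Named list/character vector of sequences.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), as.character(seqs[[nm]])), con)
  }
  invisible(path)
}

# ---- modified-base BAM simulation ------------------------------------------

# build one read record: stored seq, cigar, MM/ML and truth rows
build_sim_read <- function(read_id, ref, s, e, hap, site_prob, is_rev,
                           flag_style, soft_clip, insert_mid) {
  refseq <- substr(ref$seq, s, e)
  sites <- ref$positions
  counted <- sites[sites >= s & (sites + 1L) <= e]
  meth <- if (length(counted)) {
    stats::rbinom(length(counted), 1L, site_prob[match(counted, sites)]) == 1L
  } else logical()

  # stored-orientation segments: [soft clip] match [insertion 'A'] match [clip]
  core_len <- e - s + 1L
  stored <- refseq
  cigar_parts <- c()
  pairs <- seq.int(s, e)
  if (insert_mid && core_len >= 4L) {
    at <- core_len %/% 2L  # insertion after stored base `at`
    stored <- paste0(substr(refseq, 1L, at), "A",
                     substr(refseq, at + 1L, core_len))
    cigar_parts <- c(sprintf("%dM", at), "1I", sprintf("%dM", core_len - at))
    pairs <- c(seq.int(s, s + at - 1L), NA_integer_, seq.int(s + at, e))
  } else {
    cigar_parts <- sprintf("%dM", core_len)
  }
  if (soft_clip) {
    clip <- "AAA"
    stored <- paste0(clip, stored, clip)
    cigar_parts <- c("3S", cigar_parts, "3S")
    pairs <- c(rep(NA_integer_, 3L), pairs, rep(NA_integer_, 3L))
  }
  cigar <- paste(cigar_parts, collapse = "")

  sequenced <- if (is_rev) revcomp(stored) else stored
  ref_of <- if (is_rev) rev(pairs) else pairs
  c_idx <- which(strsplit(sequenced, "", fixed = TRUE)[[1L]] == "C")
  # reference anchor of each sequenced C: the C itself (fwd) / the paired G (rev)
  anchor <- if (is_rev) ref_of[c_idx] - 1L else ref_of[c_idx]
  site_of_c <- match(anchor, counted)

  if (flag_style == "?") {
    listed <- which(!is.na(site_of_c))
  } else {
    listed <- which(!is.na(site_of_c) & meth[site_of_c])
  }
  q <- if (length(listed)) ifelse(meth[site_of_c[listed]], 230L, 10L)
       else integer()
  deltas <- if (length(listed)) diff(c(0L, listed)) - 1L else integer()
  mm <- if (length(listed)) {
    sprintf("C+m%s,%s;", flag_style, paste(deltas, collapse = ","))
  } else {
    sprintf("C+m%s;", flag_style)
  }

  truth <- if (length(counted)) {
    data.frame(position = counted, modified = meth)
  } else {
    data.frame(position = integer(), modified = logical())
  }
  list(read_id = read_id, flag = if (is_rev) 16L else 0L, pos = s,
       cigar = cigar, seq = stored, mm = mm, ml = q, hap = hap,
       truth = truth)
}

#' Simulate a modified-base-tagged BAM cohort with known counts
#'
#' Writes one coordinate-sorted, indexed BAM per sample. Reads carry MM/ML
#' tags (high quality q=230 for modified, q=10 for canonical calls) and HP
#' haplotype tags; half of each sample's reads come from haplotype 1 and
#' half from haplotype 2, with per-haplotype per-site methylation
#' probabilities. The generator mixes forward/reverse alignments, `?` and
#' `.` MM flag styles, soft-clipped and insertion-bearing reads, and
#' records exact per-site (modified, valid) truth counts so table
#' frequencies can be asserted as integer ratios.
#'
#' @param dir Output directory (created if needed).
#' @param reference A reference from [make_reference()].
#' @param samples Character vector of sample names.
#' @param depth Reads per haplotype per sample.
#' @param h1_prob,h2_prob Per-site methylation probability for haplotype
#'   1 / 2; scalar or vector over the reference's CpG sites.
#' @param untagged Additional untagged reads per sample (drawn like H1).
#' @param read_span Read length in reference bp; default covers the whole
#'   contig.
#' @param seed RNG seed.
#' @return List with `bams` (named vector of BAM paths), `fasta` (reference
#'   FASTA path), `truth` (data.frame: sample, group, chrom, position,
#'   n_modified, n_valid) and `reference`.
#' @export
simulate_modbam <- function(dir, reference, samples = "S1", depth = 10L,
                            h1_prob = 0.85, h2_prob = 0.10, untagged = 0L,
                            read_span = NULL, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  L <- nchar(reference$seq)
  nsite <- length(reference$positions)
  p_h1 <- rep_len(h1_prob, nsite)
  p_h2 <- rep_len(h2_prob, nsite)
  span <- if (is.null(read_span)) L else min(read_span, L)
  fasta <- file.path(dir, "reference.fa")
  write_fasta(stats::setNames(list(reference$seq), reference$chrom), fasta)

  bam_paths <- character(0)
  truth_rows <- list()
  for (sm in samples) {
    plan <- data.frame(
      hap = c(rep(1L, depth), rep(2L, depth), rep(NA_integer_, untagged)))
    n <- nrow(plan)
    reads <- vector("list", n)
    for (i in seq_len(n)) {
      s <- if (span >= L) 1L else sample.int(L - span + 1L, 1L)
      e <- min(L, s + span - 1L)
      # keep half-covered CpGs out of the read so '.'-flag implied calls
      # cannot create phantom coverage at a site
      if ((s - 1L) %in% reference$positions) s <- s + 1L
      if (e %in% reference$positions) e <- e - 1L
      hap <- plan$hap[i]
      prob <- if (is.na(hap) || hap == 1L) p_h1 else p_h2
      reads[[i]] <- build_sim_read(
        read_id = sprintf("%s_r%03d", sm, i), ref = reference,
        s = s, e = e, hap = hap, site_prob = prob,
        is_rev = i %% 2L == 0L,
        flag_style = if ((i %% 4L) %in% c(0L, 1L)) "?" else ".",
        soft_clip = i %% 3L == 0L,
        insert_mid = i %% 5L == 0L)
    }
    # truth bookkeeping per haplotype group
    for (grp in c("H1", "H2", "ungrouped")) {
      sel <- switch(grp,
                    H1 = which(!is.na(plan$hap) & plan$hap == 1L),
                    H2 = which(!is.na(plan$hap) & plan$hap == 2L),
                    ungrouped = which(is.na(plan$hap)))
      if (!length(sel)) next
      tr <- do.call(rbind, lapply(reads[sel], `[[`, "truth"))
      if (is.null(tr) || nrow(tr) == 0) next
      agg_n <- tapply(tr$modified, tr$position, length)
      agg_m <- tapply(tr$modified, tr$position, sum)
      truth_rows[[paste(sm, grp)]] <- data.frame(
        sample = sm, group = grp, chrom = reference$chrom,
        position = as.integer(names(agg_n)),
        n_modified = as.integer(agg_m), n_valid = as.integer(agg_n))
    }
    sam <- file.path(dir, paste0(sm, ".sam"))
    write_sim_sam(reads, reference, sam)
    bam <- Rsamtools::asBam(sam, file.path(dir, sm), overwrite = TRUE,
                            indexDestination = TRUE)
    unlink(sam)
    bam_paths[sm] <- bam
  }
  truth <- do.call(rbind, c(truth_rows, list(data.frame(
    sample = character(), group = character(), chrom = character(),
    position = integer(), n_modified = integer(), n_valid = integer()))))
  rownames(truth) <- NULL
  truth <- truth[order(truth$sample, truth$group, truth$position), ]
  rownames(truth) <- NULL
  list(bams = bam_paths, fasta = fasta, truth = truth,
       reference = reference)
}

write_sim_sam <- function(reads, reference, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", reference$chrom,
                       nchar(reference$seq))), con)
  for (r in reads) {
    ml <- if (length(r$ml)) sprintf("\tML:B:C,%s",
                                    paste(r$ml, collapse = ",")) else
      "\tML:B:C"
    hp <- if (!is.na(r$hap)) sprintf("\tHP:i:%d", r$hap) else ""
    writeLines(sprintf(
      "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tMM:Z:%s%s%s",
      r$read_id, r$flag, reference$chrom, r$pos, r$cigar, r$seq,
      strrep("F", nchar(r$seq)), r$mm, ml, hp), con)
  }
  invisible(path)
}

# ---- cohort frequency table -------------------------------------------------

#' Simulate a haplotype-partitioned cohort frequency table
#'
#' Desk-scale analogue of a consortium cohort table over an imprinted
#' locus: `2 * n_individuals` haplotype columns named `<ID>_H1` / `<ID>_H2`,
#' per-column per-site frequencies drawn as binomial count ratios around a
#' haplotype-specific mean (H1 high, H2 low by default), and cells masked
#' missing at a per-column rate.
#'
#' @param n_individuals Number of individuals (columns = twice this).
#' @param n_sites Number of CpG positions.
#' @param spacing Distance between positions.
#' @param h1_mean,h2_mean Mean methylation frequency of the two haplotype
#'   groups.
#' @param concentration Beta concentration of per-site probabilities around
#'   the group mean (larger = tighter).
#' @param depth Read depth behind each cell (frequencies are exact
#'   `k / depth` ratios).
#' @param missingness Per-column missing-cell rate; scalar or vector
#'   recycled over columns.
#' @param chrom Chromosome name.
#' @param seed RNG seed.
#' @return List with `table` (a `freq_table`) and `labels` (named character
#'   vector, `"H1"`/`"H2"` per column).
#' @export
simulate_cohort_table <- function(n_individuals = 20L, n_sites = 200L,
                                  spacing = 100L, h1_mean = 0.85,
                                  h2_mean = 0.10, concentration = 30,
                                  depth = 20L, missingness = 0,
                                  chrom = "chr1", seed = 1L) {
  stopifnot(n_individuals >= 1, n_sites >= 1)
  set.seed(seed)
  ids <- sprintf("I%03d", seq_len(n_individuals))
  cols <- as.vector(rbind(paste0(ids, "_H1"), paste0(ids, "_H2")))
  labels <- stats::setNames(rep(c("H1", "H2"), n_individuals), cols)
  positions <- 1000L + (seq_len(n_sites) - 1L) * spacing
  miss <- rep_len(missingness, length(cols))
  vals <- matrix(NA_real_, n_sites, length(cols),
                 dimnames = list(NULL, cols))
  for (j in seq_along(cols)) {
    mu <- if (labels[j] == "H1") h1_mean else h2_mean
    p <- stats::rbeta(n_sites, mu * concentration, (1 - mu) * concentration)
    k <- stats::rbinom(n_sites, depth, p)
    v <- k / depth
    drop <- stats::runif(n_sites) < miss[j]
    v[drop] <- NA_real_
    vals[, j] <- v
  }
  list(table = freq_table(rep(chrom, n_sites), positions, vals),
       labels = labels)
}

# ---- nanopolish call files --------------------------------------------------

#' Simulate a nanopolish methylation call file with known counts
#'
#' Generates per-read call-group records at the reference's CpG sites:
#' methylated reads get positive log-likelihood ratios (~ +5), unmethylated
#' negative, and a controllable fraction of ambiguous calls falls inside
#' the cutoff band. Adjacent site pairs can be emitted as `num_motifs = 2`
#' groups sharing one call. Truth counts apply the same cutoff/splitting
#' rule as [nanopolish_to_counts()] but are tallied directly from the
#' generated states.
#'
#' @param path Output TSV path.
#' @param reference Reference from [make_reference()].
#' @param depth Reads per site.
#' @param meth_prob Per-site methylation probability (scalar or vector).
#' @param ambiguous_frac Fraction of calls with `|LLR| < 2`.
#' @param group_pairs Emit every other adjacent site pair as a two-motif
#'   group?
#' @param llr_cutoff Cutoff used for the truth counts.
#' @param seed RNG seed.
#' @return List with `path`, `records` (the written data.frame) and `truth`
#'   (per-site counts data.frame).
#' @export
simulate_nanopolish <- function(path, reference, depth = 10L,
                                meth_prob = 0.5, ambiguous_frac = 0.1,
                                group_pairs = FALSE, llr_cutoff = 2.0,
                                seed = 1L) {
  set.seed(seed)
  sites <- reference$positions
  prob <- rep_len(meth_prob, length(sites))
  recs <- list()
  truth_n <- stats::setNames(integer(length(sites)), sites)
  truth_m <- stats::setNames(integer(length(sites)), sites)
  groups <- if (group_pairs && length(sites) >= 2) {
    c(lapply(seq(1, length(sites) - 1, by = 2), function(i) c(i, i + 1)),
      if (length(sites) %% 2 == 1) list(length(sites)))
  } else {
    lapply(seq_along(sites), identity)
  }
  rid <- 0L
  for (g in groups) {
    p0 <- sites[g[1L]]
    ctx_lo <- p0 - 5L
    ctx_hi <- sites[g[length(g)]] + 6L
    ctx <- substr(reference$seq, max(1L, ctx_lo), min(nchar(reference$seq),
                                                      ctx_hi))
    for (d in seq_len(depth)) {
      rid <- rid + 1L
      meth <- stats::runif(1) < prob[g[1L]]
      ambiguous <- stats::runif(1) < ambiguous_frac
      mag <- if (ambiguous) stats::runif(1, 0.1, 1.9)
             else stats::runif(1, 2.5, 8)
      llr <- if (meth) mag else -mag
      recs[[rid]] <- data.frame(
        chromosome = reference$chrom, strand = "+", start = p0,
        end = sites[g[length(g)]], read_name = sprintf("np_r%05d", rid),
        log_lik_ratio = round(llr, 2),
        log_lik_methylated = round(llr / 2, 2),
        log_lik_unmethylated = round(-llr / 2, 2),
        num_calling_strands = 1L, num_motifs = length(g), sequence = ctx)
      if (abs(round(llr, 2)) >= llr_cutoff) {
        truth_n[g] <- truth_n[g] + 1L
        if (round(llr, 2) > 0) truth_m[g] <- truth_m[g] + 1L
      }
    }
  }
  records <- do.call(rbind, recs)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  keep <- truth_n > 0
  truth <- data.frame(chrom = reference$chrom,
                      position = sites[keep],
                      n_modified = as.integer(truth_m[keep]),
                      n_valid = as.integer(truth_n[keep]))
  list(path = path, records = records, truth = truth)
}

# ---- GFF3 -------------------------------------------------------------------

#' Write a synthetic GENCODE-style GFF3 file
#'
#' @param genes List of gene specs: each a list with `gene_id`, `name`,
#'   `chrom`, `start`, `end`, `strand` and `transcripts`, itself a list of
#'   lists with `transcript_id` and an `exons` data.frame (`start`, `end`).
#' @param path Destination (`.gff3`, or `.gz`/`.bgz` for compressed).
#' @return `path`, invisibly.
#' @export
make_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, sprintf(
      "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      g$chrom, g$start, g$end, g$strand, g$gene_id, g$name))
    for (tx in g$transcripts) {
      tx_start <- if (!is.null(tx$start)) tx$start else min(tx$exons$start)
      tx_end <- if (!is.null(tx$end)) tx$end else max(tx$exons$end)
      lines <- c(lines, sprintf(
        "%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$chrom, tx_start, tx_end, g$strand, tx$transcript_id, g$gene_id))
      if (nrow(tx$exons)) {
        lines <- c(lines, sprintf(
          "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          g$chrom, tx$exons$start, tx$exons$end, g$strand,
          tx$transcript_id, seq_len(nrow(tx$exons)), tx$transcript_id))
      }
    }
  }
  if (grepl("\\.(gz|bgz)$", path)) {
    tmp <- tempfile(fileext = ".gff3")
    writeLines(lines, tmp)
    Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
    unlink(tmp)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}
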