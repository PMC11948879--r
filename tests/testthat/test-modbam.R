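test_that("MM/ML decoding matches the tag grammar on a hand-decoded read", {
  # forward read ACGTCG: Cs at 1-based positions 2 and 5; "C+m?,0,0" lists
  # both with qualities 230 and 10
  calls <- decode_read_mods("ACGTCG", FALSE, aligned_pairs = 11:16,
                            mm = "C+m?,0,0;", ml = c(230L, 10L))
  expect_equal(calls$read_pos, c(2L, 5L))
  expect_equal(calls$ref_pos, c(12L, 15L))
  expect_equal(calls$prob, c(230.5, 10.5) / 256)
  expect_equal(calls$strand, c("+", "+"))

  # empty run decodes to zero calls
  expect_equal(nrow(decode_read_mods("ACGTCG", FALSE, 11:16, "C+m?;",
                                     integer())), 0L)

  # '.' flag: the skipped C becomes an implied unmodified call
  dot <- decode_read_mods("ACGTCG", FALSE, 11:16, "C+m.,1;", 200L)
  expect_equal(dot$read_pos, c(2L, 5L))
  expect_equal(dot$implied, c(TRUE, FALSE))
  expect_equal(dot$prob, c(0, 200.5 / 256))

  # calls on soft-clipped bases are dropped via the NA alignment map
  clip <- decode_read_mods("ACGTCG", FALSE, c(NA, NA, 13:16),
                           "C+m?,0,0;", c(230L, 10L))
  expect_equal(clip$read_pos, 5L)

  # malformed tags are rejected with the read named
  expect_error(decode_read_mods("ACGTCG", FALSE, 11:16, "C+m?,0,0;", 230L,
                                read_id = "r9"),
               "r9.*ML")
  expect_error(decode_read_mods("ACGTCG", FALSE, 11:16, "Z+m?,0;", 230L),
               "malformed MM run")
  expect_error(decode_read_mods("ACGTCG", FALSE, 11:16, "C+m?,-1;", 230L),
               "skip count")
})

test_that("decoder agrees with a per-base walking oracle on random reads", {
  set.seed(1234)
  for (i in seq_len(300)) {
    rd <- random_mod_read(sprintf("r%04d", i))
    got <- decode_read_mods(rd$seq, rd$is_reverse, rd$pairs, rd$mm, rd$ml,
                            read_id = rd$id)
    want <- naive_decode(rd$seq, rd$is_reverse, rd$pairs, rd$mm, rd$ml,
                         read_id = rd$id)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("reverse-strand CpG calls land on the reference G", {
  # reference ...C G... at 21,22; reverse read stored = "CG" context
  # stored CGAT (ref 20..23), sequenced = revcomp = ATCG; sequenced C (pos 3)
  # maps to stored position 2 = ref 21
  calls <- decode_read_mods("ATCG", TRUE, aligned_pairs = 20:23,
                            mm = "C+m?,0;", ml = 250L)
  expect_equal(calls$ref_pos, 21L)
  expect_equal(calls$strand, "-")
})

test_that("cpg_sites finds forward-strand Cs of CG dinucleotides", {
  expect_equal(cpg_sites("ACGTCGA"), c(2L, 5L))
  expect_equal(cpg_sites("CCCC"), integer())
  expect_equal(cpg_sites("cgCG"), c(1L, 3L))
  set.seed(77)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE),
               collapse = "")
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    oracle <- which(ch[-length(ch)] == "C" & ch[-1L] == "G")
    expect_equal(cpg_sites(s), as.integer(oracle))
  }
})

test_that("aggregate_cpg combines strands and applies thresholds", {
  sites <- c(10L, 50L)
  calls <- data.frame(
    read_id = sprintf("r%d", 1:4), read_pos = 1L,
    ref_pos = c(10L, 10L, 11L, 10L),        # one reverse call on the G
    strand = c("+", "+", "-", "+"), code = "m",
    prob = c(0.9, 0.9, 0.9, 0.1), implied = FALSE)
  cnt <- aggregate_cpg(calls, sites)
  expect_equal(cnt$position, 10L)
  expect_equal(cnt$n_modified, 3L)
  expect_equal(cnt$n_valid, 4L)
  expect_equal(cnt$frequency, 0.75)

  # p exactly at the threshold counts as modified
  border <- data.frame(read_id = "r", read_pos = 1L, ref_pos = 10L,
                       strand = "+", code = "m", prob = 0.5, implied = FALSE)
  expect_equal(aggregate_cpg(border, sites)$n_modified, 1L)

  # confidence band drops ambiguous calls from coverage
  amb <- data.frame(read_id = c("a", "b", "c"), read_pos = 1L, ref_pos = 10L,
                    strand = "+", code = "m", prob = c(0.9, 0.5, 0.1),
                    implied = FALSE)
  cnt2 <- aggregate_cpg(amb, sites, min_confidence = 0.8)
  expect_equal(cnt2$n_valid, 2L)
  expect_equal(cnt2$n_modified, 1L)

  # non-CpG calls are ignored, other codes filtered
  off <- data.frame(read_id = "x", read_pos = 1L, ref_pos = 33L,
                    strand = "+", code = "m", prob = 0.99, implied = FALSE)
  expect_equal(nrow(aggregate_cpg(off, sites)), 0L)
  hm <- data.frame(read_id = "x", read_pos = 1L, ref_pos = 10L,
                   strand = "+", code = c("m", "h"), prob = c(0.9, 0.8),
                   implied = FALSE)
  expect_equal(aggregate_cpg(hm, sites, mod_code = "h")$n_valid, 1L)
})

test_that("partition_reads groups by tag value and covers the input", {
  g <- partition_reads(c("a", "b", "c", "d"), c(1L, 1L, 2L, NA))
  expect_equal(lengths(g)[c("H1", "H2", "ungrouped")],
               c(H1 = 2L, H2 = 1L, ungrouped = 1L))
  g2 <- partition_reads(c("a", "b"), c(NA, NA))
  expect_equal(names(g2), "ungrouped")
  set.seed(5)
  for (i in 1:10) {
    ids <- sprintf("r%d", 1:40)
    tags <- sample(c(1L, 2L, NA), 40, replace = TRUE)
    parts <- partition_reads(ids, tags)
    expect_equal(sort(unlist(parts, use.names = FALSE)), sort(ids))
    expect_equal(sum(lengths(parts)), 40L)
  }
})

test_that("bam_to_table frequencies equal the generator's count ratios", {
  ref <- make_reference(25, spacing = 9, seed = 21)
  sim <- simulate_modbam(file.path(tempdir(), "mb1"), ref,
                         samples = c("A", "B"), depth = 12, untagged = 3,
                         seed = 22)
  tab <- bam_to_table(sim$bams, reference = sim$fasta, partition = TRUE)
  expect_equal(tab$samples, c("A_H1", "A_H2", "B_H1", "B_H2"))
  tr <- sim$truth[sim$truth$group != "ungrouped", ]
  for (i in seq_len(nrow(tr))) {
    col <- paste0(tr$sample[i], "_", tr$group[i])
    row <- which(tab$position == tr$position[i])
    expect_identical(unname(tab$values[row, col]),
                     tr$n_modified[i] / tr$n_valid[i])
  }
  # every non-missing cell is accounted for by the truth table
  expect_equal(sum(!is.na(tab$values)), nrow(tr))

  # thread-count invariance, bit for bit
  t4 <- bam_to_table(sim$bams, reference = sim$fasta, partition = TRUE,
                     threads = 4)
  expect_identical(tab, t4)

  # unpartitioned: one column per file, ungrouped reads included
  flat <- bam_to_table(sim$bams, reference = sim$fasta)
  expect_equal(flat$samples, c("A", "B"))
  allr <- sim$truth
  agg <- stats::aggregate(cbind(n_modified, n_valid) ~ sample + position,
                          allr, sum)
  for (i in seq_len(nrow(agg))) {
    row <- which(flat$position == agg$position[i])
    expect_identical(unname(flat$values[row, agg$sample[i]]),
                     agg$n_modified[i] / agg$n_valid[i])
  }

  # include_ungrouped adds the third column per sample
  withu <- bam_to_table(sim$bams, reference = sim$fasta, partition = TRUE,
                        include_ungrouped = TRUE)
  expect_true(all(c("A_ungrouped", "B_ungrouped") %in% withu$samples))
})

test_that("region-restricted scans only need the region's reads", {
  ref <- make_reference(30, spacing = 15, seed = 31)
  sim <- simulate_modbam(file.path(tempdir(), "mb2"), ref, samples = "S",
                         depth = 6, read_span = 120, seed = 32)
  reg <- genomic_region(ref$chrom, ref$positions[5], ref$positions[12])
  tab <- bam_to_table(sim$bams, reference = sim$fasta, region = reg,
                      partition = TRUE)
  expect_true(all(tab$position >= reg$start & tab$position <= reg$end))
  full <- bam_to_table(sim$bams, reference = sim$fasta, partition = TRUE)
  expect_equal(tab$values, subset_region(full, reg)$values)
})

test_that("files without modification tags are rejected by name", {
  dir <- tempfile("nomod")
  dir.create(dir)
  sam <- file.path(dir, "x.sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100",
               "r1\t0\tchr1\t10\t60\t4M\t*\t0\t0\tACGT\tFFFF"), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "x"), overwrite = TRUE)
  expect_error(bam_to_table(bam, reference = list(chr1 = c(2L, 5L))),
               "no modification \\(MM/ML\\) tags")
})
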