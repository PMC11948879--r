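test_that("tables sort sites, reject duplicates and out-of-range values", {
  # shuffled input rows come back position-sorted
  tab <- freq_table(rep("chr1", 4), c(400, 100, 300, 200),
                    matrix(c(0.4, 0.1, 0.3, 0.2), 4,
                           dimnames = list(NULL, "S1")))
  expect_equal(tab$position, c(100, 200, 300, 400))
  expect_equal(tab$values[, 1], c(0.1, 0.2, 0.3, 0.4))
  # natural chromosome ordering: chr2 before chr10
  t2 <- freq_table(c("chr10", "chr2"), c(5, 9),
                   matrix(c(0.5, 0.9), 2, dimnames = list(NULL, "S1")))
  expect_equal(t2$chrom, c("chr2", "chr10"))

  expect_error(freq_table(rep("chr1", 2), c(7, 7),
                          matrix(0.5, 2, 1, dimnames = list(NULL, "S1"))),
               "duplicate site")
  expect_error(freq_table("chr1", 10,
                          matrix(1.2, 1, 1, dimnames = list(NULL, "S1"))),
               "outside \\[0, 1\\]")
  expect_error(freq_table("chr1", 10,
                          matrix(0.5, 1, 2,
                                 dimnames = list(NULL, c("A", "A")))),
               "duplicate sample")
})

test_that("missing_fraction counts missing cells per column exactly", {
  v <- matrix(c(NA, NA, 0.1, 0.2, 0.3,
                0.1, 0.2, 0.3, 0.4, 0.5), 5,
              dimnames = list(NULL, c("A", "B")))
  tab <- freq_table(rep("chr1", 5), 1:5 * 10, v)
  expect_equal(missing_fraction(tab), c(A = 0.4, B = 0))
  expect_error(missing_fraction(freq_table()), "no sites")

  # random masks at several rates recover as exact count ratios
  set.seed(42)
  for (rate in seq(0.1, 0.9, by = 0.2)) {
    mask <- runif(50) < rate
    vv <- matrix(runif(50), 50, dimnames = list(NULL, "S"))
    vv[mask] <- NA
    tt <- freq_table(rep("chr1", 50), seq_len(50) * 3, vv)
    expect_identical(unname(missing_fraction(tt)), sum(mask) / 50)
  }
})

test_that("write/read round-trips values as written and subsets by region", {
  sim <- simulate_cohort_table(n_individuals = 4, n_sites = 30,
                               missingness = c(0, 0.3), seed = 11)
  p <- tempfile(fileext = ".tsv.gz")
  write_table(sim$table, p, index = TRUE)
  back <- read_table(p)
  expect_equal(back$values, round(sim$table$values, 4))
  expect_equal(back$position, sim$table$position)
  expect_equal(back$samples, sim$table$samples)

  # region subset equals in-memory filter
  reg <- genomic_region("chr1", 1500, 2600)
  expect_equal(unclass(read_table(p, reg))[c("chrom", "position")],
               scan_oracle(sim$table, reg)[c("chrom", "position")])

  # empty cell dialect: "" and NA both read as missing
  raw <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tS1\tS2",
               "chr1\t100\t\t0.5",
               "chr1\t200\tNA\t0.25"), raw)
  t3 <- read_table(raw)
  expect_true(all(is.na(t3$values[, "S1"])))
  expect_equal(t3$values[, "S2"], c(0.5, 0.25))
})

test_that("reader errors carry line numbers", {
  raw <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tS1", "chr1\t100\t0.5", "chr1\t200\tx"), raw)
  expect_error(read_table(raw), "line 3: non-numeric frequency 'x'")
  writeLines(c("chrom\tposition\tS1", "chr1\t100\t1.5"), raw)
  expect_error(read_table(raw), "line 2: frequency 1.5 outside")
  writeLines(c("justonecolumn", "chr1\t100\t0.5"), raw)
  expect_error(read_table(raw), "malformed header")
})

test_that("empty tables write a header-only file with a valid index", {
  p <- tempfile(fileext = ".tsv.gz")
  write_table(freq_table(values = matrix(numeric(), 0, 2,
                                         dimnames = list(NULL,
                                                         c("A", "B")))),
              p, index = TRUE)
  expect_true(file.exists(paste0(p, ".tbi")))
  q <- query_region(p, "chr1:1-1000")
  expect_equal(dim(q), c(0L, 2L))
  expect_equal(q$samples, c("A", "B"))
})

test_that("indexed queries agree with a linear-scan oracle", {
  sim <- simulate_cohort_table(n_individuals = 3, n_sites = 120,
                               missingness = 0.15, seed = 5)
  p <- tempfile(fileext = ".tsv.gz")
  write_table(sim$table, p, index = TRUE)
  tbx <- Rsamtools::TabixFile(p)
  open(tbx)
  on.exit(close(tbx))
  set.seed(99)
  span <- range(sim$table$position)
  for (i in seq_len(400)) {
    a <- sample(seq(span[1] - 200, span[2] + 200), 1)
    b <- a + sample(0:3000, 1)
    reg <- genomic_region("chr1", max(1, a), b)
    got <- query_region(tbx, reg)
    want <- scan_oracle(sim$table, reg)
    expect_equal(got$position, want$position)
    expect_equal(got$values, want$values)
  }
  # region left of all rows and exact full span
  expect_equal(n_sites(query_region(p, "chr1:1-10")), 0L)
  full <- query_region(p, sprintf("chr1:%d-%d", span[1], span[2]))
  expect_equal(n_sites(full), n_sites(sim$table))
  # missing chromosome is empty, missing index is an instructive error
  expect_equal(n_sites(query_region(p, "chrZ:1-100")), 0L)
  p2 <- tempfile(fileext = ".tsv.gz")
  write_table(sim$table, p2, index = FALSE)
  expect_error(query_region(p2, "chr1:1-10"), "index")
})

test_that("adjacent region queries compose", {
  sim <- simulate_cohort_table(n_individuals = 2, n_sites = 60, seed = 8)
  p <- tempfile(fileext = ".tsv.gz")
  write_table(sim$table, p)
  a <- query_region(p, "chr1:1-3000")
  b <- query_region(p, "chr1:3001-10000")
  ab <- query_region(p, "chr1:1-10000")
  expect_equal(merge_tables(list(a, b))$position, ab$position)
  expect_equal(merge_tables(list(a, b))$values, ab$values)
})

test_that("merge unions sites and columns and flags conflicts", {
  h1 <- freq_table(rep("chr1", 3), c(10, 20, 30),
                   matrix(c(0.9, 0.8, 0.7), 3, dimnames = list(NULL, "I1_H1")))
  h2 <- freq_table(rep("chr1", 3), c(10, 20, 30),
                   matrix(c(0.1, 0.2, 0.3), 3, dimnames = list(NULL, "I1_H2")))
  m <- merge_tables(list(h1, h2))
  expect_equal(m$samples, c("I1_H1", "I1_H2"))
  expect_equal(m$values[, "I1_H1"], c(0.9, 0.8, 0.7))
  expect_equal(m$values[, "I1_H2"], c(0.1, 0.2, 0.3))

  # identity with empty
  expect_equal(merge_tables(list(h1, freq_table()))$values, h1$values)

  # cells absent from all parts stay missing
  part <- freq_table("chr1", 40, matrix(0.5, 1, 1,
                                        dimnames = list(NULL, "I1_H2")))
  m2 <- merge_tables(list(h1, part))
  expect_true(is.na(m2$values[4, "I1_H1"]))
  expect_true(all(is.na(m2$values[1:3, "I1_H2"])))

  conflict <- freq_table("chr1", 10, matrix(0.5, 1, 1,
                                            dimnames = list(NULL, "I1_H1")))
  expect_error(merge_tables(list(h1, conflict)),
               "merge conflict at chr1:10 sample I1_H1")
})

test_that("split/merge is a faithful partition at fixed windows", {
  set.seed(3)
  pos <- sort(sample(1:60e6, 300))
  tab <- freq_table(rep("chr1", 300), pos,
                    matrix(runif(300), 300, dimnames = list(NULL, "S")))
  chunks <- split_table(tab)  # default 25 Mb windows
  # windows are fixed [k*25e6+1, (k+1)*25e6]: window arithmetic oracle
  expect_equal(length(chunks), length(unique((pos - 1) %/% 25e6)))
  for (ch in chunks) {
    expect_lt(max(ch$position) - min(ch$position), 25e6)
    expect_equal(length(unique((ch$position - 1) %/% 25e6)), 1L)
  }
  expect_equal(merge_tables(chunks)$position, tab$position)
  expect_equal(merge_tables(chunks)$values, tab$values)

  # table within one window comes back unchanged as a single chunk
  small <- freq_table(rep("chr1", 3), c(5, 10, 15),
                      matrix(0.5, 3, 1, dimnames = list(NULL, "S")))
  expect_equal(split_table(small), list(small))
})
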