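---
title: "Cohort-scale methylation maps: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-scale methylation maps: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modfreqr)
```

## The problem

Nanopore and SMRT sequencing call base modifications (5mC, 5hmC) per read,
and phasing assigns reads to parental haplotypes. Summarised per CpG site
and per haplotype, this yields a *modification frequency table*: one row
per genomic position, one column per individual or haplotype, each cell
the fraction of reads called modified. At cohort scale — hundreds of
haplotype columns over an epigenome-wide row set — the practical problems
are (i) building that table from heterogeneous per-read inputs, (ii)
retrieving an arbitrary region of it quickly, and (iii) drawing it so
patterns such as parent-of-origin imprinting (alternating high/low columns
between haplotypes, as at the *GNAS* locus) are visible at a glance.
modfreqr implements that toolchain.

## The table model and its on-disk dialect

A `freq_table` holds sites sorted by (chromosome, position) — natural
chromosome ordering, so chr2 precedes chr10 — with unique sample columns
and values in [0, 1] or missing. Duplicate positions are rejected rather
than merged: in a chunked cohort pipeline a duplicate row is a bug signal,
not data.

On disk the table is a block-gzip-compressed TSV: header
`chrom<TAB>position<TAB><sample>...`, frequencies with 4 decimal places
(precision beyond read-count resolution carries no information and the
rounding keeps cohort files compact), missing cells as empty fields. The
reader is deliberately liberal: `""`, `NA`, `na`, `nan`, `.` all read as
missing, and unsorted rows are re-sorted. A tabix index over columns 1–2
(single-position records, one header line skipped) gives region queries
without a full scan; coordinates are 1-based inclusive everywhere a user
sees them, and any half-open arithmetic stays internal to the index layer.

Cohort assembly follows a split/merge discipline: per-sample tables are
cut at fixed 25,000,000 bp windows (`[k·25e6 + 1, (k+1)·25e6]` per
chromosome), written as intermediates, then merged and re-sorted. Fixed
window boundaries make chunking deterministic and make
`merge(split(t)) = t` an exact identity, which the tests exercise. A merge
conflict — two non-missing, unequal values for one (site, sample) cell —
is an error; equal duplicates are tolerated so that re-merging overlapping
intermediates stays idempotent.

## Decoding modified-base tags

`decode_read_mods()` implements the SAM MM/ML grammar: per run, skip
counts are consumed over occurrences of the canonical base *in the
sequenced orientation* (for a reverse-strand alignment that is the reverse
complement of the stored SEQ), then each listed call is projected through
the alignment onto reference coordinates; calls on soft-clipped or
inserted bases are dropped. The two skip-flag dialects differ in what an
unlisted canonical base means, and the distinction matters for coverage:

* `?` — unlisted bases carry no information: no call, no coverage;
* `.` — unlisted bases are implicitly canonical: they become probability-0
  calls and *do* count toward valid coverage.

8-bit qualities dequantize as the interval midpoint `(q + 0.5)/256`. Any
convention inside `[q/256, (q+1)/256)` would be defensible; the midpoint
is symmetric and keeps the two boundary codes (0, 255) away from exact
0/1.

Call thresholds are fixed and documented rather than adaptive: a call is
*modified* when `p >= 0.5` (a call exactly at 0.5 counts as modified) and
a `min_confidence` band (default 0, i.e. keep everything) can drop
ambiguous calls from coverage entirely. Adaptive percentile filtering, as
some pileup tools apply, is intentionally out of scope: a fixed rule is
reproducible and testable against exact counts.

CpG strands are combined: a reverse-strand call sits on the G of a CpG and
is remapped to the paired forward C one base left, so both strands of a
site accumulate into one record. Sites with zero valid coverage emit
nothing — zero coverage is missing, not frequency 0. Haplotype
partitioning groups reads by the integer HP tag into `H1`/`H2` columns;
untagged reads are excluded from haplotype columns by default (an
`include_ungrouped` switch adds a third column per sample). Only primary
alignments with mapping quality at least 1 are used.

For nanopolish-style call tables, a group of `num_motifs` CpGs sharing one
log-likelihood-ratio call is split into per-site calls at the CG offsets
of its sequence context, anchored so the first CG sits at the record's
start coordinate (the classic off-by-one trap, pinned by tests). Calls
with `|LLR| < 2` are discarded from coverage by default — the caller's
conventional frequency cutoff — and the cutoff is a parameter. Nanopolish
reports group coordinates on the forward strand already, so no G-to-C
shift is applied to these records.

## The pre-clustering missing-data protocol

Clustering runs on a fixed four-step protocol, in this order:

1. **Missingness filter.** Columns with 40% or more missing sites are
   removed (the boundary is inclusive). Incomplete columns otherwise
   distort every distance they participate in.
2. **Position-weighted linear interpolation.** Methylation at nearby CpGs
   is strongly co-regulated, so an interior gap is filled from its nearest
   observed neighbours, weighted by genomic distance:
   `v = v0 + (v1 - v0)·(p - p0)/(p1 - p0)`. Weighting by position rather
   than row rank matters whenever CpG spacing is uneven, which is always.
   Leading and trailing gaps have no bracketing pair and are *not*
   extrapolated.
3. **Residual removal.** Columns still containing missing cells (edge
   gaps) are dropped, leaving a complete matrix.
4. **Agglomerative clustering.** Euclidean distance between column
   vectors, complete linkage, via `stats::hclust`. Frequencies already
   share the [0, 1] scale, so no standardisation is applied.

The heatmap then displays the *imputed* matrix in dendrogram leaf order.
Dendrogram drawing helpers differ in how they orient each merge, so the
leaf order is pinned deterministically here: at every merge the subtree
containing the lexicographically smallest original sample name goes left.
This makes the output invariant to input column order, which is also
tested.

`impute_linear()` is idempotent, never moves an observed cell, and its
fills are bounded by the bracketing observations; on columns whose
observed values are affine in position it reproduces the line to machine
precision — these properties are the module's test surface.

## Annotation and figure composition

`read_gff3()` accepts GENCODE/Ensembl-style GFF3 (plain or
bgzip-compressed) and resolves gene → transcript → exon links through
ID/Parent attributes; the middle tier accepts `transcript`, `mRNA`,
common ncRNA types, and any feature whose Parent is a gene, because the
two dialects disagree. Features are filtered to the viewed region but keep
their true coordinates (clipping is a display concern); exons with
unresolvable parents are dropped with a warning. Genes are laid out into
display rows by greedy interval coloring over (start, gene_id) order:
overlapping genes never share a row, disjoint genes may.

The figure document puts genomic positions on the vertical axis
(ascending top to bottom), samples on the horizontal, the annotation panel
at the left and the dendrogram above. The color ramp is a perceptually
uniform purple-to-yellow scale (viridis) with the domain fixed to [0, 1]
regardless of the data range, so figures are comparable across regions;
missing cells are light gray, outside the ramp, and are only ever shown
imputed when clustering (which displays the imputed matrix) is on.
Rendering writes a single self-contained HTML file: an SVG with per-cell
hover text (`chrom:position`, sample, frequency) plus the full matrix as
an embedded JSON payload. Nothing is binned or resampled at these sizes,
so the payload equals the input matrix cell for cell — which is how the
tests verify the figure. Rendering the same figure twice is
byte-identical. In the annotation panel, gene coordinates are mapped into
row space through the displayed site positions (rank interpolation), so
the panel stays aligned with heatmap rows even though CpG spacing is
uneven.

## Synthetic data: what it emulates and what it does not

The generators produce every input format the toolchain consumes, with
exact bookkeeping, so downstream assertions are integer count ratios
rather than statistical tolerances:

* `make_reference()` — sequences whose CG dinucleotides sit exactly at
  requested positions;
* `simulate_modbam()` — coordinate-sorted indexed BAMs whose reads mix
  forward/reverse alignments, `?` and `.` MM dialects, soft clips and
  insertions, with HP tags and per-haplotype methylation probabilities
  (modified calls encoded q = 230, canonical q = 10), plus a truth table
  of per-site (modified, valid) counts;
* `simulate_nanopolish()` — call files with controlled ambiguous-call
  rates and multi-motif groups;
* `simulate_cohort_table()` — an imprinted-locus cohort: `<ID>_H1`
  columns around mean 0.85 and `<ID>_H2` around 0.10 (binomial count
  ratios at a given depth, beta-distributed per-site probabilities,
  concentration 30), with per-column missingness masks. These defaults
  emulate the alternating haplotype pattern of an imprinted region at
  desk scale; the consortium-shaped 226-individual/452-haplotype table is
  generated at depth 1 where only the column arithmetic matters.

What the generators do **not** emulate: basecalling error models,
mapping artefacts, copy-number effects, CpG-density variation, or
modification co-occurrence structure beyond the haplotype means. Passing
tests therefore demonstrate that the *bookkeeping* — decoding, counting,
strand combining, indexing, the missing-data protocol — is exact, not
that biological signal of any particular strength will cluster cleanly in
real data.

Problem sizes used by the test-suite and the acceptance script (chosen to
keep runs in the minutes range while still exercising every code path):
1,000 randomized reads for the decoder cross-check, 10,000 random regions
against the retrieval oracle, a 2,000-row/60 Mb table for chunking, a
20-individual × 200-site cohort at depth 20 for clustering, and a
4-sample end-to-end pipeline.

## Numerical and degenerate-input choices

* Frequencies serialize at 4 decimal places; comparisons after a disk
  round trip are made at that precision.
* `p >= 0.5` modified (boundary inclusive); missingness filter `>= 40%`
  (boundary inclusive, matching "40% or more"); LLR cutoff `|llr| >= 2`
  retained.
* Empty tables write a header-only file with a valid index; querying a
  chromosome absent from the index returns an empty table, not an error;
  a region string with inverted bounds is a usage error.
* An all-columns-removed clustering input fails with "nothing to
  cluster" rather than producing a degenerate dendrogram; clustering
  needs at least two complete columns.
* Ties in leaf ordering are broken by smallest original label; ties in
  gene-row assignment by (start, gene_id) order.

## Known limitations

* One modification code per table (`m` or `h`); no combined-code mode.
* No GTF annotation input; no per-strand (uncombined) site records.
* The adaptive call filtering of pileup tools is not reproduced — the
  fixed threshold is a deliberate simplification.
* Hierarchical clustering is the only grouping offered (no k-means, no
  row clustering, no bootstrap support values).
* The HTML export is a static document with hover text; it does not
  re-query the table interactively.
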