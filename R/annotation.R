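# GFF3 gene annotation: the gene -> transcript -> exon hierarchy drawn
# beside the heatmap. Parsing goes through rtracklayer; this module only
# resolves ID/Parent links, filters to the viewed region, and lays genes
# out into non-overlapping display rows.

# middle-tier feature types accepted between gene and exon; anything whose
# Parent is a gene is also accepted (GENCODE and Ensembl dialects differ)
TRANSCRIPT_TYPES <- c("transcript", "mRNA", "ncRNA", "lnc_RNA", "miRNA",
                      "snRNA", "snoRNA", "rRNA", "tRNA", "pseudogenic_transcript")

#' Read a GFF3 gene-annotation track for a region
#'
#' Loads gene/transcript/exon features overlapping a region from a GFF3
#' file (plain or bgzip/gzip-compressed), resolving the hierarchy through
#' ID/Parent attributes. Display names come from the `Name` attribute,
#' falling back to the feature ID. Features partially overlapping the
#' region keep their true coordinates (clipping is a display concern).
#' Exons whose Parent cannot be resolved are dropped with a warning.
#'
#' @param path GFF3 file path.
#' @param region A `genomic_region` or region string.
#' @return An object of class `gene_track`: a list of genes, each with
#'   `gene_id`, `name`, `chrom`, `start`, `end`, `strand` and a list of
#'   `transcripts` (`transcript_id`, `start`, `end`, and an `exons`
#'   data.frame with `start`/`end`).
#' @export
read_gff3 <- function(path, region) {
  region <- parse_region(region)
  if (!file.exists(path)) stop_data(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  ids <- as.character(md$ID)
  parents <- md$Parent  # CharacterList; empty for top-level features
  parent1 <- vapply(seq_along(gr), function(i) {
    p <- parents[[i]]
    if (length(p)) as.character(p[[1L]]) else NA_character_
  }, character(1))
  type <- as.character(md$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  names <- if ("Name" %in% colnames(md)) as.character(md$Name)
           else rep(NA_character_, length(gr))

  overlaps <- chrom == region$chrom & starts <= region$end &
    ends >= region$start

  is_gene <- type == "gene" | grepl("_gene$", type)
  gene_idx <- which(is_gene & overlaps)
  gene_ids <- ids[gene_idx]

  is_tx <- (type %in% TRANSCRIPT_TYPES | parent1 %in% ids[is_gene]) &
    !is_gene & type != "exon"
  tx_idx <- which(is_tx & overlaps & parent1 %in% gene_ids)
  tx_ids <- ids[tx_idx]

  exon_idx <- which(type == "exon" & overlaps)
  exon_parent <- parent1[exon_idx]
  orphan <- is.na(exon_parent) | !(exon_parent %in% ids[is_tx])
  dropped_in_view <- sum(orphan & !(exon_parent %in% ids))
  if (dropped_in_view > 0) {
    warning(sprintf("read_gff3: dropped %d exon(s) with unresolvable Parent",
                    dropped_in_view))
  }
  exon_idx <- exon_idx[!orphan]
  exon_parent <- exon_parent[!orphan]

  genes <- lapply(order(starts[gene_idx], gene_ids), function(k) {
    gi <- gene_idx[k]
    gid <- ids[gi]
    my_tx <- tx_idx[parent1[tx_idx] == gid]
    transcripts <- lapply(my_tx, function(ti) {
      tid <- ids[ti]
      my_ex <- exon_idx[exon_parent == tid]
      ex <- data.frame(start = starts[my_ex], end = ends[my_ex])
      ex <- ex[order(ex$start), , drop = FALSE]
      rownames(ex) <- NULL
      list(transcript_id = tid, start = starts[ti], end = ends[ti],
           exons = ex)
    })
    list(gene_id = gid,
         name = if (!is.na(names[gi]) && nzchar(names[gi])) names[gi] else gid,
         chrom = chrom[gi], start = starts[gi], end = ends[gi],
         strand = strands[gi], transcripts = transcripts)
  })
  structure(list(genes = genes, region = region), class = "gene_track")
}

#' @export
print.gene_track <- function(x, ...) {
  n_tx <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  cat(sprintf("<gene_track> %s: %d gene(s), %d transcript(s)\n",
              format(x$region), length(x$genes), n_tx))
  for (g in utils::head(x$genes, 8)) {
    cat(sprintf("  %s (%s) %s:%d-%d [%d transcripts]\n", g$name, g$strand,
                g$chrom, g$start, g$end, length(g$transcripts)))
  }
  invisible(x)
}

#' Assign genes to display rows
#'
#' Greedy interval-graph coloring over genes sorted by (start, gene_id):
#' each gene takes the lowest row on which it overlaps nothing already
#' placed, so overlapping genes land on distinct rows and disjoint genes
#' can share one. Deterministic for a given track.
#'
#' @param track A `gene_track`.
#' @return Named integer vector mapping `gene_id` to a 0-based row index.
#' @export
assign_rows <- function(track) {
  genes <- track$genes
  if (length(genes) == 0) return(stats::setNames(integer(), character()))
  starts <- vapply(genes, `[[`, numeric(1), "start")
  ends <- vapply(genes, `[[`, numeric(1), "end")
  gids <- vapply(genes, `[[`, character(1), "gene_id")
  ord <- order(starts, gids)
  row_end <- numeric()  # rightmost occupied coordinate per row
  rows <- integer(length(genes))
  for (i in ord) {
    free <- which(row_end < starts[i])
    r <- if (length(free)) free[1L] else length(row_end) + 1L
    row_end[r] <- ends[i]
    rows[i] <- r - 1L
  }
  stats::setNames(rows, gids)
}
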