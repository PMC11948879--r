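# Figure composition and HTML export.
#
# The figure document is a plain data object (matrix + panels); rendering
# writes a self-contained HTML file with a hand-built SVG: heatmap cells
# with per-cell hover text, an optional dendrogram above the columns, an
# optional gene-annotation panel at the left, and the full data matrix
# embedded as a JSON payload so the rendered figure can be checked cell by
# cell against its input.

#' Compose a region heatmap figure
#'
#' Rows are genomic positions ascending top to bottom, columns are samples.
#' The color ramp runs purple (frequency 0) to yellow (frequency 1) with
#' the domain fixed to [0, 1] regardless of the data range; missing cells
#' get a neutral light gray outside the ramp. When a `cluster` result is
#' supplied, the heatmap shows the imputed matrix with columns in
#' dendrogram leaf order and the dendrogram is drawn above.
#'
#' @param table A `freq_table` (non-empty).
#' @param track Optional `gene_track` for the left-hand annotation panel.
#' @param cluster Optional `cluster_result` from [cluster_table()] /
#'   [cluster_samples()]; its columns must all come from `table`.
#' @param title Figure title.
#' @return An object of class `figure_doc`.
#' @export
build_figure <- function(table, track = NULL, cluster = NULL, title = "") {
  stopifnot(inherits(table, "freq_table"))
  if (n_sites(table) == 0 || length(table$samples) == 0) {
    stop_data("cannot build a figure from an empty table")
  }
  if (!is.null(cluster)) {
    stopifnot(inherits(cluster, "cluster_result"))
    if (!all(cluster$kept_samples %in% table$samples)) {
      stop_data("cluster result refers to samples absent from the table")
    }
    display <- cluster$imputed
    dendro <- list(merge = cluster$merge, height = cluster$height,
                   labels = cluster$labels,
                   leaf_order = cluster$kept_samples)
  } else {
    display <- table
    dendro <- NULL
  }
  structure(list(
    chrom = display$chrom,
    positions = as.integer(display$position),
    samples = display$samples,
    matrix = display$values,
    track = track,
    dendro = dendro,
    title = title),
    class = "figure_doc")
}

#' @export
print.figure_doc <- function(x, ...) {
  cat(sprintf("<figure_doc> '%s': %d position(s) x %d sample(s)%s%s\n",
              x$title, length(x$positions), length(x$samples),
              if (!is.null(x$dendro)) " + dendrogram" else "",
              if (!is.null(x$track)) " + annotation track" else ""))
  invisible(x)
}

# fixed 256-level purple->yellow ramp over [0,1]; missing = light gray
MISSING_COLOR <- "#D3D3D3"
heat_palette <- function() grDevices::hcl.colors(256, "viridis")

heat_color <- function(v, palette = heat_palette()) {
  out <- rep(MISSING_COLOR, length(v))
  ok <- !is.na(v)
  out[ok] <- palette[1L + pmin(255L, as.integer(floor(v[ok] * 256)))]
  out
}

fmt_px <- function(x) formatC(x, format = "f", digits = 2)

#' Render a figure document to self-contained HTML
#'
#' Writes a single HTML file embedding (i) an SVG drawing of the heatmap
#' (hover text `chrom:position`, sample, frequency on every cell), the
#' dendrogram and the annotation panel, and (ii) the full figure data as a
#' JSON payload in a `<script type="application/json">` element. Output is
#' byte-identical across renders of the same figure. No cell is ever
#' dropped or binned: the payload matrix equals the input matrix.
#'
#' @param fig A `figure_doc`.
#' @param path Destination `.html` path.
#' @return `path`, invisibly.
#' @export
render_html <- function(fig, path) {
  stopifnot(inherits(fig, "figure_doc"))
  nr <- length(fig$positions)
  nc <- length(fig$samples)
  cell_w <- 13
  cell_h <- max(2, min(14, round(620 / nr, 2)))
  pad <- 6
  label_h <- 110                       # room for slanted column labels
  dendro_h <- if (!is.null(fig$dendro)) 90 else 0
  track_w <- if (!is.null(fig$track)) 150 else 0
  axis_w <- 86                         # position labels at the right
  hm_x <- track_w + pad
  hm_y <- dendro_h + pad
  hm_w <- nc * cell_w
  hm_h <- nr * cell_h
  width <- hm_x + hm_w + axis_w + pad
  height <- hm_y + hm_h + label_h + pad

  pal <- heat_palette()
  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="sans-serif">',
    ceiling(width), ceiling(height)))

  # heatmap cells
  for (j in seq_len(nc)) {
    col <- heat_color(fig$matrix[, j], pal)
    x <- hm_x + (j - 1) * cell_w
    for (i in seq_len(nr)) {
      v <- fig$matrix[i, j]
      svg <- c(svg, sprintf(
        '<rect x="%s" y="%s" width="%d" height="%s" fill="%s"><title>%s:%d %s %s</title></rect>',
        fmt_px(x), fmt_px(hm_y + (i - 1) * cell_h), cell_w, fmt_px(cell_h),
        col[i], fig$chrom[i], fig$positions[i], fig$samples[j],
        if (is.na(v)) "missing" else formatC(v, format = "f", digits = 4)))
    }
  }

  # column labels
  for (j in seq_len(nc)) {
    svg <- c(svg, sprintf(
      '<text x="%s" y="%s" font-size="9" transform="rotate(65 %s %s)">%s</text>',
      fmt_px(hm_x + (j - 0.5) * cell_w), fmt_px(hm_y + hm_h + 10),
      fmt_px(hm_x + (j - 0.5) * cell_w), fmt_px(hm_y + hm_h + 10),
      fig$samples[j]))
  }
  # sparse position labels on the right
  lab_rows <- unique(round(seq(1, nr, length.out = min(nr, 12))))
  for (i in lab_rows) {
    svg <- c(svg, sprintf(
      '<text x="%s" y="%s" font-size="9">%s:%d</text>',
      fmt_px(hm_x + hm_w + 4), fmt_px(hm_y + (i - 0.5) * cell_h + 3),
      fig$chrom[i], fig$positions[i]))
  }

  if (!is.null(fig$dendro)) {
    svg <- c(svg, dendro_svg(fig$dendro, hm_x, dendro_h, cell_w, pad))
  }
  if (!is.null(fig$track)) {
    svg <- c(svg, track_svg(fig$track, fig$positions, hm_y, cell_h, track_w))
  }
  svg <- c(svg, "</svg>")

  payload <- jsonlite::toJSON(list(
    title = fig$title,
    chrom = fig$chrom,
    positions = fig$positions,
    samples = fig$samples,
    matrix = unname(apply(fig$matrix, 1, as.numeric, simplify = FALSE))),
    na = "null", digits = NA, auto_unbox = FALSE)

  html <- c(
    "<!DOCTYPE html>",
    '<html><head><meta charset="utf-8"/>',
    sprintf("<title>%s</title>", html_escape(fig$title)),
    "<style>body{font-family:sans-serif;margin:12px}</style>",
    "</head><body>",
    sprintf("<h2>%s</h2>", html_escape(fig$title)),
    svg,
    sprintf('<script type="application/json" id="modfreqr-data">%s</script>',
            payload),
    "</body></html>")
  writeLines(html, path)
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# dendrogram above the columns: leaves at column centers, merge heights
# scaled into the panel
dendro_svg <- function(dendro, hm_x, dendro_h, cell_w, pad) {
  merge <- dendro$merge
  hts <- dendro$height
  leaf_x <- stats::setNames(
    hm_x + (match(dendro$labels, dendro$leaf_order) - 0.5) * cell_w,
    dendro$labels)
  max_h <- max(hts, 1e-9)
  ybase <- dendro_h - 2
  scale_y <- function(h) ybase - (h / max_h) * (dendro_h - 10)
  n_merge <- nrow(merge)
  node_x <- numeric(n_merge)
  node_y <- numeric(n_merge)
  seg <- character()
  for (k in seq_len(n_merge)) {
    child_xy <- lapply(merge[k, ], function(ch) {
      if (ch < 0) c(leaf_x[[-ch]], ybase) else c(node_x[ch], node_y[ch])
    })
    y <- scale_y(hts[k])
    xs <- vapply(child_xy, `[`, numeric(1), 1L)
    for (c_i in 1:2) {
      seg <- c(seg, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#555"/>',
        fmt_px(xs[c_i]), fmt_px(child_xy[[c_i]][2L]), fmt_px(xs[c_i]),
        fmt_px(y)))
    }
    seg <- c(seg, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#555"/>',
      fmt_px(min(xs)), fmt_px(y), fmt_px(max(xs)), fmt_px(y)))
    node_x[k] <- mean(xs)
    node_y[k] <- y
  }
  seg
}

# gene-annotation panel at the left; genomic coordinates are mapped into
# row space through the displayed site positions, clipped to the view
track_svg <- function(track, positions, hm_y, cell_h, track_w) {
  genes <- track$genes
  if (length(genes) == 0) return(character())
  rows <- assign_rows(track)
  n_rows <- max(rows) + 1L
  lane_w <- max(10, (track_w - 60) / n_rows)
  nr <- length(positions)
  pos_to_y <- function(p) {
    p <- pmin(max(positions), pmax(min(positions), p))
    idx <- stats::approx(positions, seq_len(nr), xout = p, rule = 2)$y
    hm_y + (idx - 0.5) * cell_h
  }
  out <- character()
  for (g in genes) {
    x <- 40 + rows[[g$gene_id]] * lane_w
    y0 <- pos_to_y(g$start)
    y1 <- pos_to_y(g$end)
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333" stroke-width="1.5"><title>%s (%s)</title></line>',
      fmt_px(x), fmt_px(min(y0, y1)), fmt_px(x), fmt_px(max(y0, y1)),
      html_escape(g$name), g$strand))
    for (tx in g$transcripts) {
      ex <- tx$exons
      if (!nrow(ex)) next
      for (e_i in seq_len(nrow(ex))) {
        ey0 <- pos_to_y(ex$start[e_i])
        ey1 <- pos_to_y(ex$end[e_i])
        out <- c(out, sprintf(
          '<rect x="%s" y="%s" width="6" height="%s" fill="#333"><title>%s exon</title></rect>',
          fmt_px(x - 3), fmt_px(min(ey0, ey1)),
          fmt_px(max(0.8, abs(ey1 - ey0))), html_escape(tx$transcript_id)))
      }
    }
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="9" font-style="italic">%s</text>',
      fmt_px(2), fmt_px(min(y0, y1) - 2), html_escape(g$name)))
  }
  out
}
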