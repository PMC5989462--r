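# Deterministic SVG rendering: a Circos-style circular overview of all
# syntenic relationships and a linear per-chromosome browser view.  SVG is
# the contract (byte-identical for identical inputs); raster formats are
# produced only through a user-supplied rasterizer hook.  Stable CSS class
# names (chrom-arc, cytoband, ribbon, quad, bowtie, gene, gene-marker) let
# downstream code count and style elements.

fmt_num <- function(x) sprintf("%.3f", x)

svg_el <- function(tag, attrs = list(), children = character(0)) {
  a <- if (length(attrs)) {
    paste0(" ", paste(sprintf('%s="%s"', names(attrs),
                              vapply(attrs, as.character, "")),
                      collapse = " "))
  } else ""
  if (length(children) == 0L) {
    sprintf("<%s%s/>", tag, a)
  } else {
    sprintf("<%s%s>%s</%s>", tag, a, paste(children, collapse = ""), tag)
  }
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# fixed categorical palette keyed by chromosome index (color choice is a
# package convention, deterministic by design)
.palette <- c("#4e79a7", "#f28e2b", "#e15759", "#76b7b2", "#59a14f",
              "#edc948", "#b07aa1", "#ff9da7", "#9c755f", "#bab0ac",
              "#1f77b4", "#2ca02c")
palette_color <- function(i) .palette[1L + (i - 1L) %% length(.palette)]

.stain_fill <- c(gneg = "#ffffff", gpos25 = "#c8c8c8", gpos50 = "#969696",
                 gpos75 = "#646464", gpos100 = "#323232", acen = "#cc4444",
                 gvar = "#c8c8e6", stalk = "#6464a0")
stain_color <- function(stain) {
  ifelse(stain %in% names(.stain_fill), unname(.stain_fill[stain]),
         "#dddddd")
}

#' Plot options
#'
#' @param show_cytobands Draw cytoband sub-arcs on the reference ideogram.
#' @param highlight_chrom Render ribbons not touching this chromosome at
#'   reduced opacity.
#' @param highlight_gene Gene name to mark with a red triangle in linear
#'   plots.
#' @param ribbon_color_by `"reference-chrom"` or `"target-chrom"`.
#' @param image_formats Subset of `c("SVG","PNG","JPEG","PDF")`; SVG is
#'   always produced, the others need a rasterizer (see [save_plot()]).
#' @param width,height Pixel dimensions.
#' @return List of class `"plot_options"`.
#' @export
plot_options <- function(show_cytobands = FALSE, highlight_chrom = NULL,
                         highlight_gene = NULL,
                         ribbon_color_by = c("reference-chrom",
                                             "target-chrom"),
                         image_formats = "SVG", width = 800, height = 800) {
  ribbon_color_by <- match.arg(ribbon_color_by)
  if (!all(image_formats %in% c("SVG", "PNG", "JPEG", "PDF"))) {
    stop("image_formats must be a subset of SVG/PNG/JPEG/PDF")
  }
  structure(list(show_cytobands = show_cytobands,
                 highlight_chrom = highlight_chrom,
                 highlight_gene = highlight_gene,
                 ribbon_color_by = ribbon_color_by,
                 image_formats = unique(c("SVG", image_formats)),
                 width = width, height = height),
            class = "plot_options")
}

#' Angular layout of a Circos plot
#'
#' Arc sweep is proportional to chromosome length with a fixed gap angle
#' between chromosomes; the reference genome's chromosomes come first,
#' then each target genome's, in the given order.
#'
#' @param karyotypes List of [karyotype()]s, reference first.
#' @param gap_deg Gap angle between adjacent chromosomes (degrees).
#' @return Data frame: `genome`, `chrom`, `length`, `start_deg`,
#'   `end_deg`, `sweep_deg`.
#' @export
circos_layout <- function(karyotypes, gap_deg = 2) {
  rows <- do.call(rbind, lapply(karyotypes, function(k) {
    data.frame(genome = attr(k, "genome"), chrom = k$chrom,
               length = k$length, stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  avail <- 360 - n * gap_deg
  if (avail <= 0) stop("too many chromosomes for the gap angle")
  sweep <- rows$length / sum(rows$length) * avail
  start <- cumsum(c(0, utils::head(sweep, -1) + gap_deg))
  cbind(rows, data.frame(start_deg = start, end_deg = start + sweep,
                         sweep_deg = sweep))
}

# clockwise from 12 o'clock
polar_xy <- function(cx, cy, r, deg) {
  th <- deg * pi / 180
  c(cx + r * sin(th), cy - r * cos(th))
}

arc_path <- function(cx, cy, r_out, r_in, a1, a2) {
  large <- if (a2 - a1 > 180) 1 else 0
  p1 <- polar_xy(cx, cy, r_out, a1); p2 <- polar_xy(cx, cy, r_out, a2)
  p3 <- polar_xy(cx, cy, r_in, a2); p4 <- polar_xy(cx, cy, r_in, a1)
  sprintf("M %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
          fmt_num(p1[1]), fmt_num(p1[2]), fmt_num(r_out), fmt_num(r_out),
          large, fmt_num(p2[1]), fmt_num(p2[2]), fmt_num(p3[1]),
          fmt_num(p3[2]), fmt_num(r_in), fmt_num(r_in), large,
          fmt_num(p4[1]), fmt_num(p4[2]))
}

ribbon_path <- function(cx, cy, r, a1, a2, b1, b2) {
  p1 <- polar_xy(cx, cy, r, a1); p2 <- polar_xy(cx, cy, r, a2)
  q1 <- polar_xy(cx, cy, r, b1); q2 <- polar_xy(cx, cy, r, b2)
  large_a <- if (a2 - a1 > 180) 1 else 0
  large_b <- if (b2 - b1 > 180) 1 else 0
  sprintf(paste("M %s %s A %s %s 0 %d 1 %s %s Q %s %s %s %s",
                "A %s %s 0 %d 1 %s %s Q %s %s %s %s Z"),
          fmt_num(p1[1]), fmt_num(p1[2]), fmt_num(r), fmt_num(r), large_a,
          fmt_num(p2[1]), fmt_num(p2[2]), fmt_num(cx), fmt_num(cy),
          fmt_num(q1[1]), fmt_num(q1[2]), fmt_num(r), fmt_num(r), large_b,
          fmt_num(q2[1]), fmt_num(q2[2]), fmt_num(cx), fmt_num(cy),
          fmt_num(p1[1]), fmt_num(p1[2]))
}

#' Render a Circos-style synteny plot as SVG
#'
#' One ribbon per (block, target placement) connects the reference sub-arc
#' to the target sub-arc.  With `highlight_chrom` set, ribbons not
#' incident to that chromosome are drawn at reduced opacity.
#'
#' @param map A [synteny_map()] (must contain at least one block).
#' @param ref_karyotype Reference [karyotype()].
#' @param tgt_karyotypes Named list of target karyotypes (names = target
#'   genome names), or a single [karyotype()] for one-target maps.
#' @param cytobands Optional [cytoband_table()] for the reference genome,
#'   drawn when `options$show_cytobands` is `TRUE`.
#' @param options [plot_options()].
#' @return SVG document as a single character string.
#' @export
render_circos <- function(map, ref_karyotype, tgt_karyotypes,
                          cytobands = NULL, options = plot_options()) {
  if (nrow(map$blocks) == 0L) stop("cannot render an empty synteny map")
  if (inherits(tgt_karyotypes, "karyotype")) {
    tgt_karyotypes <- stats::setNames(list(tgt_karyotypes),
                                      attr(tgt_karyotypes, "genome"))
  }
  miss <- setdiff(map$targets, names(tgt_karyotypes))
  if (length(miss)) stop("missing target karyotype(s): ",
                         paste(miss, collapse = ", "))
  kts <- c(list(ref_karyotype), unname(tgt_karyotypes[map$targets]))
  layout <- circos_layout(kts)
  all_chroms <- layout$chrom
  hl <- options$highlight_chrom
  if (!is.null(hl) && !hl %in% all_chroms) {
    stop("highlight chromosome '", hl, "' not in any karyotype")
  }
  w <- options$width; h <- options$height
  cx <- w / 2; cy <- h / 2
  r_out <- 0.46 * min(w, h); r_in <- 0.42 * min(w, h)
  row_of <- function(genome, chrom) {
    layout[layout$genome == genome & layout$chrom == chrom, , drop = FALSE]
  }
  ang <- function(rw, pos) {
    rw$start_deg + pos / rw$length * (rw$end_deg - rw$start_deg)
  }
  arcs <- character(0)
  for (i in seq_len(nrow(layout))) {
    rw <- layout[i, ]
    arcs <- c(arcs, svg_el("path", list(
      class = "chrom-arc", d = arc_path(cx, cy, r_out, r_in, rw$start_deg,
                                        rw$end_deg),
      fill = palette_color(i), stroke = "#333333", `stroke-width` = "0.5",
      `data-genome` = rw$genome, `data-chrom` = rw$chrom,
      `data-sweep` = fmt_num(rw$sweep_deg))))
    lp <- polar_xy(cx, cy, r_out + 14, (rw$start_deg + rw$end_deg) / 2)
    arcs <- c(arcs, svg_el("text", list(
      class = "label", x = fmt_num(lp[1]), y = fmt_num(lp[2]),
      `text-anchor` = "middle", `font-size` = "9"),
      xml_escape(rw$chrom)))
  }
  bands <- character(0)
  if (isTRUE(options$show_cytobands) && !is.null(cytobands) &&
      nrow(cytobands)) {
    ref_genome <- attr(ref_karyotype, "genome")
    for (i in seq_len(nrow(cytobands))) {
      cb <- cytobands[i, ]
      rw <- row_of(ref_genome, cb$chrom)
      if (nrow(rw) != 1L) next
      bands <- c(bands, svg_el("path", list(
        class = "cytoband", d = arc_path(cx, cy, r_out - 1, r_in + 1,
                                         ang(rw, cb$start),
                                         ang(rw, cb$end)),
        fill = stain_color(cb$stain), `data-band` = cb$band,
        `data-stain` = cb$stain)))
    }
  }
  ref_genome <- attr(ref_karyotype, "genome")
  ribbons <- character(0)
  pl <- map$placements
  b <- map$blocks
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, ]
    bb <- b[b$block_id == p$block_id, ]
    rwa <- row_of(ref_genome, bb$ref_chrom)
    rwb <- row_of(p$target, p$tgt_chrom)
    if (nrow(rwa) != 1L || nrow(rwb) != 1L) {
      stop("block chromosome missing from karyotype: ",
           bb$ref_chrom, " / ", p$tgt_chrom)
    }
    dim_ribbon <- !is.null(hl) && !(bb$ref_chrom == hl || p$tgt_chrom == hl)
    color_idx <- if (options$ribbon_color_by == "reference-chrom") {
      match(bb$ref_chrom, ref_karyotype$chrom)
    } else {
      match(p$tgt_chrom, tgt_karyotypes[[p$target]]$chrom)
    }
    ribbons <- c(ribbons, svg_el("path", list(
      class = "ribbon", d = ribbon_path(
        cx, cy, r_in, ang(rwa, bb$ref_start), ang(rwa, bb$ref_end),
        ang(rwb, p$tgt_start), ang(rwb, p$tgt_end)),
      fill = palette_color(color_idx),
      `fill-opacity` = if (dim_ribbon) "0.12" else "0.60",
      `data-block` = bb$block_id, `data-target` = p$target)))
  }
  svg_el("svg", list(xmlns = "http://www.w3.org/2000/svg",
                     width = w, height = h,
                     viewBox = sprintf("0 0 %s %s", w, h)),
         c(svg_el("g", list(class = "chroms"), arcs),
           if (length(bands)) svg_el("g", list(class = "cytobands"), bands),
           svg_el("g", list(class = "ribbons"), ribbons)))
}

#' Render a linear synteny browser view as SVG
#'
#' Top track: the reference chromosome scaled to the plot width; one lower
#' track per partner target chromosome.  Each block is a quadrilateral
#' from its reference span to its target span, crossed ("bow-tie") for
#' inverted blocks; a `<title>` child carries the block's coordinates.
#' Genes are drawn as rectangles colored by strand (blue `+`, green `-`);
#' `options$highlight_gene` adds a red triangle at the gene midpoint.
#'
#' @param map A [synteny_map()].
#' @param ref_chrom Reference chromosome (needs >= 1 block for `target`).
#' @param target Target genome name.
#' @param genes Optional [gene_table()] on reference coordinates.
#' @param options [plot_options()].
#' @param ref_karyotype,tgt_karyotype Optional karyotypes for true
#'   chromosome lengths (defaults: extent of the drawn blocks).
#' @return SVG document as a single character string.
#' @export
render_linear <- function(map, ref_chrom, target, genes = NULL,
                          options = plot_options(), ref_karyotype = NULL,
                          tgt_karyotype = NULL) {
  pw <- pairwise_blocks(map, target)
  pw <- pw[pw$ref_chrom == ref_chrom, , drop = FALSE]
  if (nrow(pw) == 0L) {
    stop("no blocks for ", ref_chrom, " against target '", target, "'")
  }
  w <- options$width; margin <- 50
  track_w <- w - 2 * margin
  ref_len <- if (!is.null(ref_karyotype)) {
    ref_karyotype$length[match(ref_chrom, ref_karyotype$chrom)]
  } else max(pw$ref_end)
  xr <- function(pos) margin + pos / ref_len * track_w
  partner <- sort(unique(pw$tgt_chrom))
  if (!is.null(tgt_karyotype)) {
    partner <- partner[order(match(partner, tgt_karyotype$chrom))]
  }
  tlen <- vapply(partner, function(cc) {
    if (!is.null(tgt_karyotype) && cc %in% tgt_karyotype$chrom) {
      tgt_karyotype$length[match(cc, tgt_karyotype$chrom)]
    } else max(pw$tgt_end[pw$tgt_chrom == cc])
  }, 0)
  has_genes <- !is.null(genes) && nrow(genes) > 0
  y_ref <- 50; track_h <- 14
  y_gene <- y_ref + track_h + 8
  y0 <- y_ref + track_h + (if (has_genes) 40 else 30)
  spacing <- 90
  els <- character(0)
  els <- c(els, svg_el("rect", list(class = "chrom-track", x = fmt_num(margin),
    y = y_ref, width = fmt_num(track_w), height = track_h,
    fill = "#e8e8e8", stroke = "#333333",
    `data-genome` = map$reference, `data-chrom` = ref_chrom)))
  els <- c(els, svg_el("text", list(class = "label", x = fmt_num(margin),
    y = y_ref - 6, `font-size` = "11"),
    xml_escape(sprintf("%s.%s", map$reference, ref_chrom))))
  y_of <- stats::setNames(y0 + (seq_along(partner) - 1L) * spacing, partner)
  for (cc in partner) {
    els <- c(els, svg_el("rect", list(class = "chrom-track",
      x = fmt_num(margin), y = fmt_num(y_of[[cc]]),
      width = fmt_num(track_w), height = track_h, fill = "#e8e8e8",
      stroke = "#333333", `data-genome` = target, `data-chrom` = cc)))
    els <- c(els, svg_el("text", list(class = "label", x = fmt_num(margin),
      y = fmt_num(y_of[[cc]] - 6), `font-size` = "11"),
      xml_escape(sprintf("%s.%s", target, cc))))
  }
  quads <- character(0)
  for (i in seq_len(nrow(pw))) {
    bb <- pw[i, ]
    xt <- function(pos) margin + pos / tlen[[bb$tgt_chrom]] * track_w
    y1 <- y_ref + track_h; y2 <- y_of[[bb$tgt_chrom]]
    x1r <- xr(bb$ref_start); x2r <- xr(bb$ref_end)
    x1t <- xt(bb$tgt_start); x2t <- xt(bb$tgt_end)
    inv <- bb$orientation == "-"
    pts <- if (inv) {
      sprintf("%s,%s %s,%s %s,%s %s,%s", fmt_num(x1r), fmt_num(y1),
              fmt_num(x2r), fmt_num(y1), fmt_num(x1t), fmt_num(y2),
              fmt_num(x2t), fmt_num(y2))
    } else {
      sprintf("%s,%s %s,%s %s,%s %s,%s", fmt_num(x1r), fmt_num(y1),
              fmt_num(x2r), fmt_num(y1), fmt_num(x2t), fmt_num(y2),
              fmt_num(x1t), fmt_num(y2))
    }
    coord_txt <- sprintf("block %s: %s.%s:%s-%s <-> %s.%s:%s-%s (%s)",
                         fmt_bp(bb$block_id), map$reference, bb$ref_chrom,
                         fmt_bp(bb$ref_start + 1), fmt_bp(bb$ref_end),
                         target, bb$tgt_chrom, fmt_bp(bb$tgt_start + 1),
                         fmt_bp(bb$tgt_end), bb$orientation)
    quads <- c(quads, svg_el("polygon", list(
      class = if (inv) "quad bowtie" else "quad", points = pts,
      fill = palette_color(match(bb$tgt_chrom, partner)),
      `fill-opacity` = "0.55", stroke = "#555555", `stroke-width` = "0.4",
      `data-block` = bb$block_id),
      svg_el("title", list(), xml_escape(coord_txt))))
  }
  gene_els <- character(0)
  if (has_genes) {
    g <- genes[genes$chrom == ref_chrom, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      gg <- g[i, ]
      plus <- gg$strand == "+"
      gene_els <- c(gene_els, svg_el("rect", list(
        class = if (plus) "gene gene-plus" else "gene gene-minus",
        x = fmt_num(xr(gg$start)), y = y_gene,
        width = fmt_num(max(1, xr(gg$end) - xr(gg$start))), height = 8,
        fill = if (plus) "#2c5aa0" else "#2ca05a",
        `data-gene` = xml_escape(gg$name)),
        svg_el("title", list(), xml_escape(
          sprintf("%s %s:%s-%s (%s)", gg$name, gg$chrom,
                  fmt_bp(gg$start + 1), fmt_bp(gg$end), gg$strand)))))
    }
    hg <- options$highlight_gene
    if (!is.null(hg)) {
      gg <- g[g$name == hg, , drop = FALSE]
      if (nrow(gg)) {
        xm <- xr((gg$start[1] + gg$end[1]) / 2)
        gene_els <- c(gene_els, svg_el("polygon", list(
          class = "gene-marker",
          points = sprintf("%s,%s %s,%s %s,%s", fmt_num(xm - 6),
                           fmt_num(y_ref - 14), fmt_num(xm + 6),
                           fmt_num(y_ref - 14), fmt_num(xm),
                           fmt_num(y_ref - 2)),
          fill = "#d62728", `data-gene` = xml_escape(hg))))
      }
    }
  }
  h <- y0 + length(partner) * spacing
  svg_el("svg", list(xmlns = "http://www.w3.org/2000/svg", width = w,
                     height = h, viewBox = sprintf("0 0 %s %s", w, h)),
         c(svg_el("g", list(class = "tracks"), els),
           svg_el("g", list(class = "block-layer"), quads),
           if (length(gene_els)) svg_el("g", list(class = "genes"),
                                        gene_els)))
}

#' Write an SVG document to disk (bytewise, newline-stable)
#' @param svg SVG string from [render_circos()] or [render_linear()].
#' @param path Output path.
#' @export
write_svg <- function(svg, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(svg, con, sep = "\n")
  invisible(path)
}

#' Save a plot in one or more formats
#'
#' SVG is always written.  PNG/JPEG/PDF are produced by the `rasterizer`
#' hook, a `function(svg_path, out_path, format)`; requesting them without
#' one is an error, keeping the core output bit-exact and dependency-free.
#'
#' @param svg SVG string.
#' @param path_base Output path without extension.
#' @param formats Subset of `c("SVG","PNG","JPEG","PDF")`.
#' @param rasterizer Optional conversion hook.
#' @return Character vector of written paths.
#' @export
save_plot <- function(svg, path_base, formats = "SVG", rasterizer = NULL) {
  formats <- unique(c("SVG", toupper(formats)))
  svg_path <- paste0(path_base, ".svg")
  write_svg(svg, svg_path)
  out <- svg_path
  for (f in setdiff(formats, "SVG")) {
    if (is.null(rasterizer)) {
      stop("format ", f, " needs a rasterizer hook; SVG was written")
    }
    op <- paste0(path_base, ".", tolower(f))
    rasterizer(svg_path, op, f)
    out <- c(out, op)
  }
  out
}
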