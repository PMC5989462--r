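library(xml2)

viz_fixture <- function(seed = 51, n_ops = 6) {
  rk <- simulate_karyotype(3, c(1e6, 1.5e6), seed = seed)
  truth <- simulate_rearrangements(rk, n_ops = n_ops, seed = seed)
  list(rk = rk, tk = truth$tgt_karyotype, map = truth$map)
}

test_that("circos SVG is well-formed with one ribbon per placement", {
  fx <- viz_fixture()
  svg <- render_circos(fx$map, fx$rk, fx$tk)
  doc <- read_svg(svg) # errors on malformed XML
  ribbons <- xml_find_all(doc, "//*[@class='ribbon']")
  expect_equal(length(ribbons), nrow(fx$map$placements))
  arcs <- xml_find_all(doc, "//*[@class='chrom-arc']")
  expect_equal(length(arcs), nrow(fx$rk) + nrow(fx$tk))
})

test_that("arc sweep is proportional to chromosome length", {
  k1 <- karyotype(c("a", "b"), c(2e8, 1e8), genome = "g1")
  k2 <- karyotype("c", 1e8, genome = "g2")
  lay <- circos_layout(list(k1, k2), gap_deg = 2)
  expect_equal(lay$sweep_deg[1] / lay$sweep_deg[2], 2)
  expect_equal(lay$sweep_deg[2], lay$sweep_deg[3])
  expect_equal(sum(lay$sweep_deg) + 3 * 2, 360)
})

test_that("highlighting a chromosome dims non-incident ribbons", {
  fx <- viz_fixture()
  hl <- fx$map$blocks$ref_chrom[1]
  svg <- render_circos(fx$map, fx$rk, fx$tk,
                       options = plot_options(highlight_chrom = hl))
  doc <- read_svg(svg)
  ribbons <- xml_find_all(doc, "//*[@class='ribbon']")
  op <- xml_attr(ribbons, "fill-opacity")
  pw <- pairwise_blocks(fx$map, "tgt")
  incident <- pw$ref_chrom == hl | pw$tgt_chrom == hl
  expect_equal(op == "0.60", incident[order(pw$block_id)])
  expect_error(render_circos(fx$map, fx$rk, fx$tk,
                             options = plot_options(
                               highlight_chrom = "nope")),
               "highlight")
})

test_that("an empty map cannot be rendered", {
  m <- synteny_map("ref", "tgt", data.frame(), data.frame())
  fx <- viz_fixture()
  expect_error(render_circos(m, fx$rk, fx$tk), "empty")
})

test_that("cytobands appear as stain-shaded sub-arcs when enabled", {
  fx <- viz_fixture()
  cb <- cytoband_table(c("chr1", "chr1"), c(0, 4e5), c(4e5, 8e5),
                       c("p1", "q1"), c("gneg", "acen"))
  svg <- render_circos(fx$map, fx$rk, fx$tk, cytobands = cb,
                       options = plot_options(show_cytobands = TRUE))
  doc <- read_svg(svg)
  bands <- xml_find_all(doc, "//*[@class='cytoband']")
  expect_equal(length(bands), 2)
  expect_true("acen" %in% xml_attr(bands, "data-stain"))
  # disabled: no band elements
  svg2 <- render_circos(fx$map, fx$rk, fx$tk, cytobands = cb)
  expect_equal(length(xml_find_all(read_svg(svg2),
                                   "//*[@class='cytoband']")), 0)
})

test_that("linear plot draws one quad per block, bow-tie when inverted", {
  fx <- viz_fixture()
  pw <- pairwise_blocks(fx$map, "tgt")
  cc <- names(which.max(table(pw$ref_chrom)))
  here <- pw[pw$ref_chrom == cc, ]
  svg <- render_linear(fx$map, cc, "tgt", ref_karyotype = fx$rk,
                       tgt_karyotype = fx$tk)
  doc <- read_svg(svg)
  quads <- xml_find_all(doc, "//*[contains(@class,'quad')]")
  expect_equal(length(quads), nrow(here))
  bowties <- xml_find_all(doc, "//*[contains(@class,'bowtie')]")
  expect_equal(length(bowties), sum(here$orientation == "-"))
  # every quad carries its coordinates as a <title> text child
  titles <- xml_find_all(doc, "//*[contains(@class,'quad')]/title")
  expect_equal(length(titles), nrow(here))
  expect_match(xml_text(titles[[1]]), "block \\d+: ref\\.")
  expect_error(render_linear(fx$map, cc, "tgt2"), "unknown target")
})

test_that("rendered span widths are proportional to block spans", {
  fx <- viz_fixture()
  pw <- pairwise_blocks(fx$map, "tgt")
  cc <- pw$ref_chrom[1]
  here <- pw[pw$ref_chrom == cc, ]
  svg <- render_linear(fx$map, cc, "tgt", ref_karyotype = fx$rk,
                       tgt_karyotype = fx$tk)
  doc <- read_svg(svg)
  track <- xml_find_first(doc, "//*[@class='chrom-track']")
  track_w <- as.numeric(xml_attr(track, "width"))
  quads <- xml_find_all(doc, "//*[contains(@class,'quad')]")
  ref_len <- fx$rk$length[match(cc, fx$rk$chrom)]
  for (i in seq_along(quads)) {
    pts <- xml_attr(quads[[i]], "points")
    xy <- do.call(rbind, lapply(strsplit(strsplit(pts, " ")[[1]], ","),
                                as.numeric))
    drawn_w <- abs(xy[2, 1] - xy[1, 1]) # top edge = reference span
    bid <- as.numeric(xml_attr(quads[[i]], "data-block"))
    b <- here[here$block_id == bid, ]
    want <- (b$ref_end - b$ref_start) / ref_len * track_w
    expect_lt(abs(drawn_w - want) / want, 0.005)
  }
})

test_that("genes color by strand and the highlight marker is placed once", {
  fx <- viz_fixture()
  cc <- fx$map$blocks$ref_chrom[1]
  b <- fx$map$blocks[fx$map$blocks$ref_chrom == cc, ][1, ]
  genes <- gene_table(c(cc, cc), c(b$ref_start + 10, b$ref_start + 5000),
                      c(b$ref_start + 2000, b$ref_start + 8000),
                      c("GPLUS", "GMINUS"), c("+", "-"))
  svg <- render_linear(fx$map, cc, "tgt", genes = genes,
                       options = plot_options(highlight_gene = "GMINUS"),
                       ref_karyotype = fx$rk, tgt_karyotype = fx$tk)
  doc <- read_svg(svg)
  plus <- xml_find_all(doc, "//*[contains(@class,'gene-plus')]")
  minus <- xml_find_all(doc, "//*[contains(@class,'gene-minus')]")
  expect_equal(length(plus), 1)
  expect_equal(length(minus), 1)
  expect_equal(xml_attr(plus[[1]], "fill"), "#2c5aa0")  # blue = + strand
  expect_equal(xml_attr(minus[[1]], "fill"), "#2ca05a") # green = - strand
  markers <- xml_find_all(doc, "//*[@class='gene-marker']")
  expect_equal(length(markers), 1)
  expect_equal(xml_attr(markers[[1]], "fill"), "#d62728")
})

test_that("site export writes the full deterministic page set", {
  fx <- viz_fixture()
  karyos <- list(ref = fx$rk, tgt = fx$tk)
  d1 <- withr::local_tempdir()
  export_site(fx$map, karyos, out_dir = d1)
  pages <- list.files(d1)
  # 1 index + 1 circos + (#ref chroms x #targets) browser pages
  expect_equal(length(pages), 1 + 1 + nrow(fx$rk) * length(fx$map$targets))
  expect_true(all(c("index.html", "circos.html") %in% pages))
  expect_true(check_site_links(d1))
  # regeneration is byte-identical
  before <- vapply(pages, function(p) unname(tools::md5sum(
    file.path(d1, p))), "")
  export_site(fx$map, karyos, out_dir = d1)
  after <- vapply(pages, function(p) unname(tools::md5sum(
    file.path(d1, p))), "")
  expect_identical(before, after)
})

test_that("re-rendering the same map is byte-identical", {
  fx <- viz_fixture()
  s1 <- render_circos(fx$map, fx$rk, fx$tk)
  s2 <- render_circos(fx$map, fx$rk, fx$tk)
  expect_identical(s1, s2)
})

test_that("raster formats demand a rasterizer hook", {
  fx <- viz_fixture()
  svg <- render_circos(fx$map, fx$rk, fx$tk)
  d <- withr::local_tempdir()
  expect_error(save_plot(svg, file.path(d, "p"), formats = "PNG"),
               "rasterizer")
  expect_true(file.exists(file.path(d, "p.svg"))) # SVG written regardless
  called <- FALSE
  fake <- function(svg_path, out_path, format) {
    called <<- TRUE
    writeLines("raster", out_path)
  }
  paths <- save_plot(svg, file.path(d, "q"), formats = "PNG",
                     rasterizer = fake)
  expect_true(called)
  expect_true(file.exists(file.path(d, "q.png")))
})
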