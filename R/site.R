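# Static HTML export: an index page, one circular-overview page, and one
# linear browser page per (reference chromosome x target).  Pages embed
# the SVGs inline and carry no timestamps, so regeneration into the same
# directory is byte-identical.

html_page <- function(title, body) {
  paste0("<!DOCTYPE html>\n<html lang=\"en\">\n<head>\n",
         "<meta charset=\"utf-8\"/>\n<title>", xml_escape(title),
         "</title>\n",
         "<style>body{font-family:sans-serif;margin:2em}",
         "nav a{margin-right:1em}</style>\n</head>\n<body>\n",
         body, "\n</body>\n</html>\n")
}

write_text <- function(txt, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "")
  invisible(path)
}

#' Export a static HTML site for a synteny map
#'
#' Produces `index.html`, `circos.html` and one
#' `browser_<refchrom>_<target>.html` per (reference chromosome, target)
#' pair, embedding the SVG plots.  Page names and contents are
#' deterministic; all internal links resolve (see [check_site_links()]).
#'
#' @param map A [synteny_map()] with at least one block.
#' @param karyotypes Named list of [karyotype()]s covering the reference
#'   and every target genome.
#' @param genes Optional [gene_table()] for the reference genome.
#' @param cytobands Optional [cytoband_table()] for the reference genome.
#' @param out_dir Output directory (created if needed).
#' @param options [plot_options()].
#' @return `out_dir`, invisibly; attribute `"pages"` lists written files.
#' @export
export_site <- function(map, karyotypes, genes = NULL, cytobands = NULL,
                        out_dir, options = plot_options()) {
  if (nrow(map$blocks) == 0L) stop("cannot export a site for an empty map")
  need <- c(map$reference, map$targets)
  miss <- setdiff(need, names(karyotypes))
  if (length(miss)) stop("missing karyotype(s): ", paste(miss, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref_k <- karyotypes[[map$reference]]
  tgt_ks <- karyotypes[map$targets]
  pages <- character(0)
  circos_svg <- render_circos(map, ref_k, tgt_ks, cytobands, options)
  browser_links <- character(0)
  for (cc in ref_k$chrom) {
    for (t in map$targets) {
      fname <- sprintf("browser_%s_%s.html", cc, t)
      pw <- pairwise_blocks(map, t)
      n_here <- sum(pw$ref_chrom == cc)
      body <- if (n_here > 0) {
        svg <- render_linear(map, cc, t, genes = genes, options = options,
                             ref_karyotype = ref_k,
                             tgt_karyotype = tgt_ks[[t]])
        paste0("<nav><a href=\"index.html\">index</a>",
               "<a href=\"circos.html\">circos</a></nav>\n",
               "<h1>", xml_escape(sprintf("%s %s vs %s", map$reference, cc,
                                          t)), "</h1>\n", svg)
      } else {
        paste0("<nav><a href=\"index.html\">index</a>",
               "<a href=\"circos.html\">circos</a></nav>\n",
               "<h1>", xml_escape(sprintf("%s %s vs %s", map$reference, cc,
                                          t)),
               "</h1>\n<p>No synteny blocks for this chromosome.</p>")
      }
      write_text(html_page(sprintf("SynBrowser %s vs %s", cc, t), body),
                 file.path(out_dir, fname))
      pages <- c(pages, fname)
      browser_links <- c(browser_links,
                         sprintf("<li><a href=\"%s\">%s vs %s</a></li>",
                                 fname, xml_escape(cc), xml_escape(t)))
    }
  }
  write_text(html_page("SynCircos",
                       paste0("<nav><a href=\"index.html\">index</a></nav>\n",
                              "<h1>Circular synteny overview</h1>\n",
                              circos_svg)),
             file.path(out_dir, "circos.html"))
  pages <- c(pages, "circos.html")
  idx <- paste0("<h1>Synteny site: ", xml_escape(map$reference), " vs ",
                xml_escape(paste(map$targets, collapse = ", ")), "</h1>\n",
                "<p><a href=\"circos.html\">Circular overview</a></p>\n",
                "<ul>\n", paste(browser_links, collapse = "\n"), "\n</ul>")
  write_text(html_page("Synteny site", idx), file.path(out_dir, "index.html"))
  pages <- c(pages, "index.html")
  out <- out_dir
  attr(out, "pages") <- pages
  invisible(out)
}

#' Check that all internal links of an exported site resolve
#'
#' @param dir Directory written by [export_site()].
#' @return `TRUE` when every relative `href` in every HTML page points to
#'   an existing file; otherwise an error naming the broken link.
#' @export
check_site_links <- function(dir) {
  pages <- list.files(dir, pattern = "\\.html$")
  for (p in pages) {
    txt <- paste(readLines(file.path(dir, p), warn = FALSE), collapse = "\n")
    hrefs <- regmatches(txt, gregexpr('href="[^"]+"', txt))[[1]]
    hrefs <- sub('^href="', "", sub('"$', "", hrefs))
    hrefs <- hrefs[!grepl("^[a-z]+:", hrefs)] # skip absolute URLs
    for (h in hrefs) {
      if (!file.exists(file.path(dir, h))) {
        stop("broken link in ", p, ": ", h)
      }
    }
  }
  TRUE
}
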