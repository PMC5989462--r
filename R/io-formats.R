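# Readers for the simple tabular formats: chrom.sizes, generic anchor TSVs
# with column-map dialects, BED6 genes, UCSC cytoBandIdeo tables.
# All TSV readers skip blank lines and lines starting with '#'.

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
}

#' Read a chrom.sizes file into a karyotype
#'
#' @param path Two-column whitespace-separated file: chromosome name, length.
#' @param genome Genome label for the karyotype (default: file name without
#'   extension).
#' @return A [karyotype()].
#' @export
read_chrom_sizes <- function(path, genome = NULL) {
  if (is.null(genome)) genome <- sub("\\.[^.]*$", "", basename(path))
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) stop("empty chrom.sizes file: ", path)
  parts <- strsplit(lines, "\\s+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) stop("malformed chrom.sizes line: ", lines[bad[1]])
  chrom <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (any(is.na(len)) || any(len != floor(len))) {
    stop("non-integer chromosome length in ", path)
  }
  if (any(len <= 0)) stop("non-positive chromosome length in ", path)
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome name in ", path, ": ",
         chrom[duplicated(chrom)][1])
  }
  karyotype(chrom, len, genome = genome)
}

#' Write a karyotype as a chrom.sizes file
#' @param k A [karyotype()].
#' @param path Output path.
#' @export
write_chrom_sizes <- function(k, path) {
  writeLines(paste(k$chrom, fmt_bp(k$length), sep = "\t"), path)
  invisible(path)
}

#' Describe the column layout of a third-party synteny / anchor table
#'
#' A dialect maps column roles to (1-based) column indices, states the
#' file's coordinate convention, and maps orientation tokens to `+`/`-`.
#' Presets for the supported third-party tools are available through
#' [dialect_preset()]; all presets can be overridden because those tools'
#' exact layouts vary between versions.
#'
#' @param name Label for the dialect.
#' @param column_map Named integer vector mapping roles (`ref_chrom`,
#'   `ref_start`, `ref_end`, `tgt_chrom`, `tgt_start`, `tgt_end`,
#'   `orientation`; optional `score`, `block_id`) to 1-based column indices.
#' @param coords `"0-based-half-open"` or `"1-based-inclusive"`.
#' @param orientation_tokens Named character vector mapping file tokens to
#'   `"+"` / `"-"`.
#' @return List of class `"table_dialect"`.
#' @export
table_dialect <- function(name, column_map,
                          coords = c("0-based-half-open", "1-based-inclusive"),
                          orientation_tokens = c("+" = "+", "-" = "-")) {
  coords <- match.arg(coords)
  req <- c("ref_chrom", "ref_start", "ref_end",
           "tgt_chrom", "tgt_start", "tgt_end", "orientation")
  miss <- setdiff(req, names(column_map))
  if (length(miss)) stop("dialect missing roles: ", paste(miss, collapse = ", "))
  if (anyDuplicated(column_map)) stop("dialect maps two roles to one column")
  if (!all(orientation_tokens %in% c("+", "-"))) {
    stop("orientation_tokens values must be '+' or '-'")
  }
  structure(list(name = name, column_map = column_map, coords = coords,
                 orientation_tokens = orientation_tokens),
            class = "table_dialect")
}

#' Built-in table dialects
#'
#' * `generic`: ref_chrom ref_start ref_end tgt_chrom tgt_start tgt_end
#'   orientation \[score\], 0-based half-open.
#' * `satsuma`: 8 columns, target intervals first
#'   (tgt_chrom tgt_start tgt_end ref_chrom ref_start ref_end score strand),
#'   0-based half-open.
#' * `cinteny`: block table block_id ref_chrom ref_start ref_end tgt_chrom
#'   tgt_start tgt_end orientation, 1-based inclusive.
#' * `syntenytracker`: block table ref_chrom ref_start ref_end tgt_chrom
#'   tgt_start tgt_end block_id orientation, 1-based inclusive.
#'
#' @param name One of `"generic"`, `"satsuma"`, `"cinteny"`,
#'   `"syntenytracker"`.
#' @return A [table_dialect()].
#' @export
dialect_preset <- function(name) {
  switch(name,
    generic = table_dialect("generic",
      c(ref_chrom = 1L, ref_start = 2L, ref_end = 3L,
        tgt_chrom = 4L, tgt_start = 5L, tgt_end = 6L,
        orientation = 7L, score = 8L),
      coords = "0-based-half-open"),
    satsuma = table_dialect("satsuma",
      c(tgt_chrom = 1L, tgt_start = 2L, tgt_end = 3L,
        ref_chrom = 4L, ref_start = 5L, ref_end = 6L,
        score = 7L, orientation = 8L),
      coords = "0-based-half-open"),
    cinteny = table_dialect("cinteny",
      c(block_id = 1L, ref_chrom = 2L, ref_start = 3L, ref_end = 4L,
        tgt_chrom = 5L, tgt_start = 6L, tgt_end = 7L, orientation = 8L),
      coords = "1-based-inclusive",
      orientation_tokens = c("+" = "+", "-" = "-", "1" = "+", "-1" = "-")),
    syntenytracker = table_dialect("syntenytracker",
      c(ref_chrom = 1L, ref_start = 2L, ref_end = 3L,
        tgt_chrom = 4L, tgt_start = 5L, tgt_end = 6L,
        block_id = 7L, orientation = 8L),
      coords = "1-based-inclusive"),
    stop("unknown dialect '", name, "'; presets: generic, satsuma, ",
         "cinteny, syntenytracker")
  )
}

# parse one table according to a dialect; returns a data frame with internal
# coordinates plus optional block_id/score columns
read_dialect_table <- function(path, dialect) {
  if (is.character(dialect)) dialect <- dialect_preset(dialect)
  lines <- read_tsv_lines(path)
  cm <- dialect$column_map
  ncol_needed <- max(cm[setdiff(names(cm), c("score"))])
  rows <- strsplit(lines, "\\s+")
  n <- length(rows)
  get_col <- function(role) {
    if (!role %in% names(cm)) return(NULL)
    j <- cm[[role]]
    vapply(rows, function(r) if (length(r) >= j) r[[j]] else NA_character_, "")
  }
  if (n == 0L) {
    return(data.frame(ref_chrom = character(), ref_start = numeric(),
                      ref_end = numeric(), tgt_chrom = character(),
                      tgt_start = numeric(), tgt_end = numeric(),
                      orientation = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  short <- which(vapply(rows, length, 1L) < ncol_needed)
  if (length(short)) stop("row with too few columns for dialect '",
                          dialect$name, "': ", lines[short[1]])
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v))) stop("non-numeric ", what, " in ", path)
    v
  }
  out <- data.frame(
    ref_chrom = get_col("ref_chrom"),
    ref_start = num(get_col("ref_start"), "ref_start"),
    ref_end = num(get_col("ref_end"), "ref_end"),
    tgt_chrom = get_col("tgt_chrom"),
    tgt_start = num(get_col("tgt_start"), "tgt_start"),
    tgt_end = num(get_col("tgt_end"), "tgt_end"),
    stringsAsFactors = FALSE
  )
  tok <- get_col("orientation")
  unknown <- setdiff(unique(tok), names(dialect$orientation_tokens))
  if (length(unknown)) {
    stop("unmapped orientation token(s): ", paste(unknown, collapse = ", "))
  }
  out$orientation <- unname(dialect$orientation_tokens[tok])
  sc <- get_col("score")
  out$score <- if (is.null(sc) || anyNA(sc)) 0 else {
    v <- suppressWarnings(as.numeric(sc)); ifelse(is.na(v), 0, v)
  }
  bid <- get_col("block_id")
  if (!is.null(bid)) out$block_id <- num(bid, "block_id")
  if (dialect$coords == "1-based-inclusive") {
    out$ref_start <- out$ref_start - 1
    out$tgt_start <- out$tgt_start - 1
  }
  if (any(out$ref_end <= out$ref_start) || any(out$tgt_end <= out$tgt_start)) {
    stop("row with empty interval after coordinate normalization in ", path)
  }
  out
}

#' Read pairwise alignment anchors from a generic TSV
#'
#' @param path Whitespace-separated table.
#' @param dialect A [table_dialect()] or preset name (default `"generic"`).
#' @return An [anchor_table()] in internal coordinates.
#' @export
read_anchors_tsv <- function(path, dialect = "generic") {
  tab <- read_dialect_table(path, dialect)
  validate_anchors(tab[, c("ref_chrom", "ref_start", "ref_end", "tgt_chrom",
                           "tgt_start", "tgt_end", "orientation", "score")])
}

#' Write anchors as a generic TSV
#' @param anchors An [anchor_table()].
#' @param path Output path.
#' @export
write_anchors_tsv <- function(anchors, path) {
  lines <- paste(anchors$ref_chrom, fmt_bp(anchors$ref_start),
                 fmt_bp(anchors$ref_end), anchors$tgt_chrom,
                 fmt_bp(anchors$tgt_start), fmt_bp(anchors$tgt_end),
                 anchors$orientation, sprintf("%g", anchors$score),
                 sep = "\t")
  writeLines(c("# ref_chrom ref_start ref_end tgt_chrom tgt_start tgt_end strand score",
               lines), path)
  invisible(path)
}

#' Read gene annotations from a BED6 file
#'
#' Strand is required (`+` or `-`): the gene track colors rectangles by
#' strand, so strandless records are rejected.  The BED score column is
#' ignored.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return A [gene_table()].
#' @export
read_bed_genes <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) {
    return(gene_table(character(), numeric(), numeric(), character(),
                      character()))
  }
  rows <- strsplit(lines, "\\s+")
  if (any(vapply(rows, length, 1L) < 6L)) {
    stop("BED6 requires 6 columns (chrom start end name score strand): ", path)
  }
  strand <- vapply(rows, `[[`, "", 6L)
  if (!all(strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-' in ", path)
  }
  gene_table(vapply(rows, `[[`, "", 1L),
             as.numeric(vapply(rows, `[[`, "", 2L)),
             as.numeric(vapply(rows, `[[`, "", 3L)),
             vapply(rows, `[[`, "", 4L), strand)
}

#' Write genes as BED6
#' @param genes A [gene_table()].
#' @param path Output path.
#' @export
write_bed_genes <- function(genes, path) {
  writeLines(paste(genes$chrom, fmt_bp(genes$start), fmt_bp(genes$end),
                   genes$name, "0", genes$strand, sep = "\t"), path)
  invisible(path)
}

#' Read a UCSC cytoBandIdeo table
#'
#' @param path TSV: chrom, start (0-based), end, band name, stain.
#' @return A [cytoband_table()]; overlapping bands on one chromosome are an
#'   error.
#' @export
read_cytoband <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) {
    return(cytoband_table(character(), numeric(), numeric(), character(),
                          character()))
  }
  rows <- strsplit(lines, "\\s+")
  if (any(vapply(rows, length, 1L) < 5L)) {
    stop("cytoband table requires 5 columns: ", path)
  }
  cytoband_table(vapply(rows, `[[`, "", 1L),
                 as.numeric(vapply(rows, `[[`, "", 2L)),
                 as.numeric(vapply(rows, `[[`, "", 3L)),
                 vapply(rows, `[[`, "", 4L),
                 vapply(rows, `[[`, "", 5L))
}
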