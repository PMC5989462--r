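# The unified synteny block definition format.
#
# One record per block:
#   >block_id
#   refgenome.chrom:start-end +        (1-based inclusive; reference first,
#   tgtgenome.chrom:start-end strand    strand always "+")
#   ...one line per target placement, in map target order...
# with a blank line between records.  A single leading comment line
#   # syntenic unified blocks; reference=REF; targets=T1,T2; resolution=N
# preserves the map's metadata (target order, resolution) so that reading a
# written file reconstructs the map exactly; comment lines are skipped by
# all readers.  Inversion is expressed only on target placements: the
# reference strand column is always "+".

format_placement <- function(genome, chrom, start, end, strand) {
  fc_start <- start + 1 # internal 0-based half-open -> 1-based inclusive
  sprintf("%s.%s:%s-%s %s", genome, chrom, fmt_bp(fc_start), fmt_bp(end),
          strand)
}

parse_placement <- function(line) {
  m <- regmatches(line,
    regexec("^([^.[:space:]]+)\\.(\\S+):([0-9]+)-([0-9]+) ([+-])$", line))[[1]]
  if (length(m) != 6L) stop("unparseable placement line: '", line, "'")
  start1 <- as.numeric(m[4]); end1 <- as.numeric(m[5])
  if (start1 < 1 || start1 > end1) {
    stop("invalid coordinates in placement line: '", line, "'")
  }
  list(genome = m[2], chrom = m[3], start = start1 - 1, end = end1,
       strand = m[6])
}

#' Write a synteny map in the unified block format
#'
#' The writer is deterministic: identical maps produce byte-identical files.
#'
#' @param map A [synteny_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_unified()]
#' @export
write_unified <- function(map, path) {
  header <- sprintf("# syntenic unified blocks; reference=%s; targets=%s; resolution=%s",
                    map$reference, paste(map$targets, collapse = ","),
                    fmt_bp(map$resolution))
  recs <- character(nrow(map$blocks))
  for (i in seq_len(nrow(map$blocks))) {
    b <- map$blocks[i, ]
    lines <- c(paste0(">", b$block_id),
               format_placement(map$reference, b$ref_chrom, b$ref_start,
                                b$ref_end, "+"))
    pl <- map$placements[map$placements$block_id == b$block_id, , drop = FALSE]
    for (t in map$targets) {
      p <- pl[pl$target == t, , drop = FALSE]
      if (nrow(p) == 1L) {
        lines <- c(lines, format_placement(t, p$tgt_chrom, p$tgt_start,
                                           p$tgt_end, p$orientation))
      }
    }
    recs[i] <- paste(lines, collapse = "\n")
  }
  con <- file(path, "wb") # bytewise: no platform newline translation
  on.exit(close(con))
  writeLines(c(header, if (length(recs)) paste(recs, collapse = "\n\n")),
             con, sep = "\n")
  invisible(path)
}

#' Read a unified synteny block definition file
#'
#' @param path File written by [write_unified()] (or by a converter).
#' @return A [synteny_map()]; `read_unified(write_unified(m))` reproduces
#'   `m` exactly.
#' @export
read_unified <- function(path) {
  raw <- readLines(path, warn = FALSE)
  reference <- NULL; targets <- NULL; resolution <- 0
  hm <- grep("^# syntenic unified blocks;", raw, value = TRUE)
  if (length(hm)) {
    g <- function(key) {
      m <- regmatches(hm[1], regexec(paste0(key, "=([^;]*)"), hm[1]))[[1]]
      if (length(m) == 2L) m[2] else NULL
    }
    reference <- g("reference")
    tg <- g("targets")
    if (!is.null(tg) && nzchar(tg)) targets <- strsplit(tg, ",")[[1]]
    rs <- g("resolution")
    if (!is.null(rs)) resolution <- as.numeric(rs)
  }
  lines <- raw[!grepl("^\\s*#", raw)]
  lines <- lines[cumsum(nzchar(lines)) > 0] # tolerate leading blanks
  # split into records at '>' headers
  hdr <- grep("^>", lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && (length(hdr) == 0L || nonblank[1] < hdr[1])) {
    stop("unified file must start records with '>': ", path)
  }
  blocks <- list(); placements <- list()
  seen_ids <- numeric(0)
  for (r in seq_along(hdr)) {
    from <- hdr[r]
    to <- if (r < length(hdr)) hdr[r + 1L] - 1L else length(lines)
    id <- suppressWarnings(as.numeric(sub("^>", "", trimws(lines[from]))))
    if (is.na(id)) stop("unparseable block header: '", lines[from], "'")
    if (id %in% seen_ids) stop("duplicate block_id ", fmt_bp(id), " in ", path)
    seen_ids <- c(seen_ids, id)
    body <- lines[(from + 1L):to]
    body <- body[nzchar(trimws(body))]
    if (length(body) < 2L) {
      stop("block ", fmt_bp(id), " needs a reference and >= 1 placement line")
    }
    pls <- lapply(body, parse_placement)
    refp <- pls[[1]]
    if (is.null(reference)) reference <- refp$genome
    if (refp$genome != reference) {
      stop("first placement of block ", fmt_bp(id), " is for '", refp$genome,
           "', expected reference '", reference, "'")
    }
    blocks[[r]] <- data.frame(block_id = id, ref_chrom = refp$chrom,
                              ref_start = refp$start, ref_end = refp$end,
                              stringsAsFactors = FALSE)
    tp <- pls[-1]
    placements[[r]] <- data.frame(
      block_id = id,
      target = vapply(tp, `[[`, "", "genome"),
      tgt_chrom = vapply(tp, `[[`, "", "chrom"),
      tgt_start = vapply(tp, function(p) p$start, 0),
      tgt_end = vapply(tp, function(p) p$end, 0),
      orientation = vapply(tp, `[[`, "", "strand"),
      stringsAsFactors = FALSE
    )
  }
  blocks <- do.call(rbind, blocks)
  placements <- do.call(rbind, placements)
  if (is.null(blocks)) {
    blocks <- data.frame(); placements <- data.frame()
  }
  if (is.null(targets)) {
    targets <- unique(placements$target)
  }
  if (is.null(reference)) reference <- "reference"
  synteny_map(reference, targets, blocks, placements, resolution = resolution)
}

#' Convert a third-party synteny block table to a synteny map
#'
#' Rows sharing a `block_id` (when the dialect maps one) are merged to the
#' enclosing span per genome with majority orientation (ties go to `"+"`).
#' Without a `block_id` column each row is its own block, numbered in
#' reference-sorted order.  The resulting map has resolution 0 (imported).
#'
#' @param path Table file.
#' @param dialect A [table_dialect()] or preset name (`"satsuma"`,
#'   `"cinteny"`, `"syntenytracker"`, `"generic"`).
#' @param reference,target Genome names for the two sides.
#' @param chrom_order Optional reference chromosome order for sorting.
#' @return A [synteny_map()] with one target.
#' @export
convert_third_party <- function(path, dialect, reference, target,
                                chrom_order = NULL) {
  tab <- read_dialect_table(path, dialect)
  if (nrow(tab) == 0L) {
    return(synteny_map(reference, target, data.frame(), data.frame(),
                       resolution = 0, chrom_order = chrom_order))
  }
  if (!"block_id" %in% names(tab)) {
    ord <- order(if (is.null(chrom_order)) tab$ref_chrom
                 else match(tab$ref_chrom, chrom_order), tab$ref_start)
    tab <- tab[ord, , drop = FALSE]
    tab$block_id <- seq_len(nrow(tab))
  }
  merged <- lapply(split(tab, tab$block_id), function(g) {
    if (length(unique(g$ref_chrom)) > 1L || length(unique(g$tgt_chrom)) > 1L) {
      stop("rows of block_id ", g$block_id[1],
           " lie on different chromosomes")
    }
    strand <- names(which.max(table(factor(g$orientation, c("+", "-")))))
    data.frame(block_id = g$block_id[1], ref_chrom = g$ref_chrom[1],
               ref_start = min(g$ref_start), ref_end = max(g$ref_end),
               tgt_chrom = g$tgt_chrom[1], tgt_start = min(g$tgt_start),
               tgt_end = max(g$tgt_end), orientation = strand,
               stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, merged)
  ord <- order(if (is.null(chrom_order)) merged$ref_chrom
               else match(merged$ref_chrom, chrom_order), merged$ref_start)
  merged <- merged[ord, , drop = FALSE]
  # overlapping reference spans after merge are a data error, not trimmable
  same <- which(merged$ref_chrom[-1] == merged$ref_chrom[-nrow(merged)])
  if (length(same) && any(merged$ref_start[same + 1L] < merged$ref_end[same])) {
    stop("overlapping reference spans after block merge in ", path)
  }
  synteny_map(
    reference, target,
    blocks = merged[, c("block_id", "ref_chrom", "ref_start", "ref_end")],
    placements = data.frame(block_id = merged$block_id, target = target,
                            tgt_chrom = merged$tgt_chrom,
                            tgt_start = merged$tgt_start,
                            tgt_end = merged$tgt_end,
                            orientation = merged$orientation,
                            stringsAsFactors = FALSE),
    resolution = 0, chrom_order = chrom_order
  )
}
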