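# Core domain types and interval arithmetic.
#
# Internal coordinate convention, used by every function in the package:
# 0-based half-open [start, end).  Each on-disk format states its own
# convention and is converted at the I/O boundary (see io-* files).

#' Create a karyotype
#'
#' A karyotype is the ordered set of chromosomes (names and lengths in base
#' pairs) of one genome assembly.  The order given here is the canonical
#' order used for sorting blocks and laying out plots.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Numeric vector of chromosome lengths in bp (> 0).
#' @param genome Short label for the assembly (e.g. `"hg38"`).  Must not
#'   contain a `"."`, which separates genome from chromosome in the unified
#'   block format.
#' @return A data frame of class `"karyotype"` with columns `chrom` and
#'   `length`, and attribute `genome`.
#' @examples
#' karyotype(c("chr1", "chr2"), c(2e6, 1.5e6), genome = "toy")
#' @export
karyotype <- function(chrom, length, genome = "genome") {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("karyotype must have at least one chromosome")
  if (length(chrom) != base::length(length)) {
    stop("chrom and length must have equal length")
  }
  if (anyDuplicated(chrom)) stop("duplicate chromosome name in karyotype")
  if (any(!is.finite(length)) || any(length < 1)) {
    stop("chromosome lengths must be positive")
  }
  if (grepl(".", genome, fixed = TRUE)) {
    stop("genome label must not contain '.'")
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  attr(out, "genome") <- genome
  class(out) <- c("karyotype", "data.frame")
  out
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("karyotype '%s': %d chromosomes, %s bp total\n",
              attr(x, "genome"), nrow(x), format(sum(x$length), big.mark = ",")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Genomic interval
#'
#' Constructs a single 0-based half-open genomic interval.  Used where a
#' scalar interval (rather than a table of them) is the natural argument.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `0 <= start < end`.
#' @return A list of class `"gi"` with elements `chrom`, `start`, `end`.
#' @export
gi <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end) {
    stop("invalid interval: need 0 <= start < end")
  }
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "gi")
}

#' @export
print.gi <- function(x, ...) {
  cat(sprintf("%s:[%s,%s)\n", x$chrom, fmt_bp(x$start), fmt_bp(x$end)))
  invisible(x)
}

#' Overlap length of two intervals
#'
#' @param a,b Intervals created with [gi()].
#' @return Overlap in bp (0 when on different chromosomes or disjoint;
#'   half-open intervals that merely abut do not overlap).
#' @export
overlap_len <- function(a, b) {
  if (!identical(a$chrom, b$chrom)) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

# vectorized overlap of [s1,e1) vs [s2,e2) on equal chroms (callers check)
.ovl <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Convert an interval to 1-based inclusive file coordinates
#'
#' The unified block format (and several third-party tables) print 1-based
#' inclusive coordinates; internally everything is 0-based half-open.
#'
#' @param iv Interval from [gi()].
#' @return List with `chrom`, `start` (1-based), `end` (inclusive).
#' @seealso [from_file_coords()]
#' @export
to_file_coords <- function(iv) {
  list(chrom = iv$chrom, start = iv$start + 1, end = iv$end)
}

#' Convert 1-based inclusive file coordinates to an internal interval
#'
#' @param chrom Chromosome name.
#' @param start 1-based inclusive start (>= 1).
#' @param end Inclusive end (>= start).
#' @return Interval of class `"gi"`.
#' @export
from_file_coords <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 1 || start > end) {
    stop(sprintf("invalid 1-based coordinates %s:%s-%s", chrom,
                 format(start), format(end)))
  }
  gi(chrom, start - 1, end)
}

# bp formatter: exact integers, never scientific notation
fmt_bp <- function(x) sprintf("%.0f", x)

#' Build an anchor table
#'
#' An anchor is one (near-)ungapped pairwise alignment match: an interval on
#' the reference genome, an interval on the target genome (always stored on
#' the target's forward strand), and an orientation: `"+"` when the match is
#' co-directional, `"-"` when the target segment is inverted relative to the
#' reference.
#'
#' @param ref_chrom,ref_start,ref_end Reference interval (0-based half-open).
#' @param tgt_chrom,tgt_start,tgt_end Target interval (forward strand).
#' @param orientation `"+"` or `"-"`, recycled.
#' @param score Optional nonnegative score, recycled (default 0).
#' @return A data frame of class `"anchors"`.
#' @export
anchor_table <- function(ref_chrom, ref_start, ref_end,
                         tgt_chrom, tgt_start, tgt_end,
                         orientation = "+", score = 0) {
  n <- length(ref_chrom)
  out <- data.frame(
    ref_chrom = as.character(ref_chrom),
    ref_start = as.numeric(ref_start), ref_end = as.numeric(ref_end),
    tgt_chrom = as.character(tgt_chrom),
    tgt_start = as.numeric(tgt_start), tgt_end = as.numeric(tgt_end),
    orientation = rep_len(as.character(orientation), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  validate_anchors(out)
}

#' Validate an anchor table
#'
#' @param x Data frame with the columns of [anchor_table()].
#' @return `x`, classed `"anchors"`, invisibly checked.
#' @export
validate_anchors <- function(x) {
  req <- c("ref_chrom", "ref_start", "ref_end",
           "tgt_chrom", "tgt_start", "tgt_end", "orientation")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("anchor table missing columns: ", paste(miss, collapse = ", "))
  if (!"score" %in% names(x)) x$score <- 0
  if (nrow(x)) {
    if (any(x$ref_start < 0 | x$ref_end <= x$ref_start)) {
      stop("anchor with empty or negative reference span")
    }
    if (any(x$tgt_start < 0 | x$tgt_end <= x$tgt_start)) {
      stop("anchor with empty or negative target span")
    }
    if (!all(x$orientation %in% c("+", "-"))) {
      stop("anchor orientation must be '+' or '-'")
    }
    if (any(x$score < 0)) stop("anchor score must be nonnegative")
  }
  class(x) <- unique(c("anchors", class(x)))
  x
}

#' Build parameters for synteny block construction
#'
#' @param resolution Minimum block span in bp, enforced on the reference AND
#'   on each target placement.  Smaller values give more, finer blocks.
#' @param max_gap Maximum joinable gap in bp on either genome when chaining
#'   anchors (default: equal to `resolution`).
#' @param min_anchor Anchors whose reference or target span is below this are
#'   discarded before chaining; also the tolerated overlap between
#'   consecutive anchors in a run (default 100 bp).
#' @return List of class `"build_params"`.
#' @export
build_params <- function(resolution, max_gap = resolution, min_anchor = 100) {
  resolution <- as.numeric(resolution)
  max_gap <- as.numeric(max_gap)
  min_anchor <- as.numeric(min_anchor)
  if (!is.finite(resolution) || resolution <= 0) stop("resolution must be > 0")
  if (!is.finite(max_gap) || max_gap <= 0) stop("max_gap must be > 0")
  if (!is.finite(min_anchor) || min_anchor < 0) stop("min_anchor must be >= 0")
  if (max_gap < min_anchor) stop("max_gap must be >= min_anchor")
  structure(list(resolution = resolution, max_gap = max_gap,
                 min_anchor = min_anchor),
            class = "build_params")
}

#' Construct a synteny map
#'
#' A synteny map holds the ordered synteny blocks of one reference genome
#' against one or more target genomes.  `blocks` carries the reference
#' intervals, `placements` one row per (block, target) placement.
#'
#' @param reference Reference genome name.
#' @param targets Character vector of target genome names (order is the
#'   canonical target order in the unified file and in plots).
#' @param blocks Data frame with columns `block_id`, `ref_chrom`,
#'   `ref_start`, `ref_end`.
#' @param placements Data frame with columns `block_id`, `target`,
#'   `tgt_chrom`, `tgt_start`, `tgt_end`, `orientation`.
#' @param resolution Build resolution in bp; 0 for imported maps.
#' @param chrom_order Optional character vector giving the reference
#'   chromosome order (normally the reference karyotype order).  Defaults to
#'   order of first appearance in `blocks`.
#' @return Object of class `"synteny_map"`.
#' @export
synteny_map <- function(reference, targets, blocks, placements,
                        resolution = 0, chrom_order = NULL) {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  placements <- as.data.frame(placements, stringsAsFactors = FALSE)
  if (nrow(blocks) == 0L) {
    blocks <- data.frame(block_id = integer(), ref_chrom = character(),
                         ref_start = numeric(), ref_end = numeric(),
                         stringsAsFactors = FALSE)
    placements <- data.frame(block_id = integer(), target = character(),
                             tgt_chrom = character(), tgt_start = numeric(),
                             tgt_end = numeric(), orientation = character(),
                             stringsAsFactors = FALSE)
  }
  if (is.null(chrom_order)) chrom_order <- unique(blocks$ref_chrom)
  m <- structure(list(reference = as.character(reference),
                      targets = as.character(targets),
                      blocks = blocks, placements = placements,
                      resolution = as.numeric(resolution),
                      chrom_order = as.character(chrom_order)),
                 class = "synteny_map")
  validate_synteny_map(m)
}

#' Validate a synteny map against its invariants
#'
#' Checks: positive spans, unique block ids, placements refer to known
#' blocks and declared targets, every block has at least one placement,
#' reference intervals on one chromosome are pairwise non-overlapping, and
#' blocks are sorted by (chromosome order, start).  Sorting is repaired
#' rather than rejected; genuine invariant violations raise errors.
#'
#' @param m A `"synteny_map"`.
#' @return The validated (possibly re-sorted) map.
#' @export
validate_synteny_map <- function(m) {
  b <- m$blocks; p <- m$placements
  if (nrow(b) == 0L) return(m)
  if (anyDuplicated(b$block_id)) stop("duplicate block_id in synteny map")
  if (any(b$ref_end <= b$ref_start)) stop("block with empty reference span")
  if (any(p$tgt_end <= p$tgt_start)) stop("placement with empty target span")
  if (!all(p$orientation %in% c("+", "-"))) {
    stop("placement orientation must be '+' or '-'")
  }
  if (!all(p$target %in% m$targets)) {
    stop("placement target not among declared targets")
  }
  if (!all(p$block_id %in% b$block_id)) stop("placement for unknown block_id")
  if (!all(b$block_id %in% p$block_id)) {
    stop("block without any target placement")
  }
  co <- m$chrom_order
  extra <- setdiff(unique(b$ref_chrom), co)
  if (length(extra)) co <- c(co, extra)
  ord <- order(match(b$ref_chrom, co), b$ref_start, b$ref_end)
  b <- b[ord, , drop = FALSE]
  rownames(b) <- NULL
  # non-overlap per reference chromosome (blocks now sorted)
  same <- which(b$ref_chrom[-1] == b$ref_chrom[-nrow(b)])
  if (length(same) && any(b$ref_start[same + 1L] < b$ref_end[same])) {
    stop("overlapping reference intervals in synteny map")
  }
  m$blocks <- b
  m$chrom_order <- co
  m
}

#' @export
print.synteny_map <- function(x, ...) {
  cat(sprintf("synteny map: reference '%s' vs %s\n", x$reference,
              paste(sprintf("'%s'", x$targets), collapse = ", ")))
  cat(sprintf("  %d blocks on %d reference chromosomes; resolution %s bp%s\n",
              nrow(x$blocks), length(unique(x$blocks$ref_chrom)),
              fmt_bp(x$resolution),
              if (x$resolution == 0) " (imported)" else ""))
  invisible(x)
}

#' @export
summary.synteny_map <- function(object, ...) {
  b <- object$blocks
  p <- object$placements
  cat(sprintf("synteny map '%s' -> {%s}\n", object$reference,
              paste(object$targets, collapse = ", ")))
  if (nrow(b) == 0L) { cat("  (empty)\n"); return(invisible(object)) }
  span <- b$ref_end - b$ref_start
  cat(sprintf("  blocks: %d; reference bp covered: %s\n", nrow(b),
              fmt_bp(sum(span))))
  cat(sprintf("  block span: min %s / median %s / max %s bp\n",
              fmt_bp(min(span)), fmt_bp(stats::median(span)), fmt_bp(max(span))))
  inv <- tapply(p$orientation == "-", p$target, mean)
  for (t in object$targets) {
    if (t %in% names(inv)) {
      cat(sprintf("  %s: %.1f%% of placements inverted\n", t, 100 * inv[[t]]))
    }
  }
  invisible(object)
}

#' Gene annotation table
#'
#' @param chrom,start,end Gene location on the reference genome (0-based
#'   half-open).
#' @param name Gene names (nonempty).
#' @param strand `"+"` or `"-"` per gene.
#' @return Data frame of class `"genes"`.
#' @export
gene_table <- function(chrom, start, end, name, strand) {
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), name = as.character(name),
                    strand = as.character(strand), stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (any(out$end <= out$start)) stop("gene with empty span")
    if (any(!nzchar(out$name))) stop("gene with empty name")
    if (!all(out$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  }
  class(out) <- c("genes", "data.frame")
  out
}

#' Cytoband table
#'
#' @param chrom,start,end Band location (0-based half-open).
#' @param band Band name (e.g. `"p36.33"`).
#' @param stain UCSC stain token (`gneg`, `gpos50`, `acen`, ...).
#' @return Data frame of class `"cytobands"`; bands on one chromosome must
#'   not overlap.
#' @export
cytoband_table <- function(chrom, start, end, band, stain) {
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), band = as.character(band),
                    stain = as.character(stain), stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (any(out$end <= out$start)) stop("cytoband with empty span")
    for (cc in unique(out$chrom)) {
      k <- out[out$chrom == cc, , drop = FALSE]
      k <- k[order(k$start, k$end), , drop = FALSE]
      if (nrow(k) > 1L && any(k$start[-1] < k$end[-nrow(k)])) {
        stop("overlapping cytobands on ", cc)
      }
    }
  }
  class(out) <- c("cytobands", "data.frame")
  out
}

#' Pairwise projection of a synteny map onto one target
#'
#' Joins the placements for one target genome with the reference intervals,
#' one row per block that has a placement for that target, in reference
#' order.
#'
#' @param map A [synteny_map()].
#' @param target Target genome name.
#' @return Data frame: `block_id`, `ref_chrom`, `ref_start`, `ref_end`,
#'   `tgt_chrom`, `tgt_start`, `tgt_end`, `orientation`.
#' @export
pairwise_blocks <- function(map, target) {
  if (!target %in% map$targets) stop("unknown target genome: ", target)
  p <- map$placements[map$placements$target == target, , drop = FALSE]
  b <- map$blocks
  i <- match(p$block_id, b$block_id)
  out <- cbind(b[i, c("block_id", "ref_chrom", "ref_start", "ref_end")],
               p[, c("tgt_chrom", "tgt_start", "tgt_end", "orientation")])
  out <- out[order(match(out$ref_chrom, map$chrom_order), out$ref_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
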