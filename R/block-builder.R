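# Synteny block construction from alignment anchors.
#
# The construction is greedy orientation-consistent chaining: anchors are
# sorted along the reference, walked left to right per reference
# chromosome, and joined into runs while they stay on the same target
# chromosome, keep the same orientation, advance consistently on the target
# (forward for "+", backward for "-"), and leave gaps no larger than
# max_gap on either genome (small overlaps up to min_anchor bp, as produced
# by chain trimming, are tolerated).  Each run becomes one candidate block
# spanning its anchors; blocks shorter than the resolution on either genome
# are dropped; residual overlaps between blocks are resolved by trimming
# the smaller block.  Multi-species maps are formed by partitioning the
# reference at the union of all pairwise block boundaries and keeping the
# segments covered in every pairwise map.

#' Filter and sort anchors before chaining
#'
#' Drops exact duplicate rows, removes anchors whose reference or target
#' span is below `params$min_anchor`, and sorts survivors by (reference
#' chromosome order, start, then larger span first).
#'
#' @param anchors An [anchor_table()].
#' @param params [build_params()].
#' @param chrom_order Optional reference chromosome order (karyotype order);
#'   defaults to order of first appearance.
#' @return Filtered, sorted [anchor_table()].
#' @export
filter_anchors <- function(anchors, params, chrom_order = NULL) {
  a <- validate_anchors(anchors)
  a <- unique(a) # exact duplicates carry no extra evidence
  keep <- pmin(a$ref_end - a$ref_start, a$tgt_end - a$tgt_start) >=
    params$min_anchor
  a <- a[keep, , drop = FALSE]
  if (is.null(chrom_order)) chrom_order <- unique(a$ref_chrom)
  ord <- order(match(a$ref_chrom, chrom_order), a$ref_start, -a$ref_end)
  a <- a[ord, , drop = FALSE]
  rownames(a) <- NULL
  a
}

# join test between the open run's last anchor (l) and candidate row i of a
join_ok <- function(a, i, l, params) {
  if (a$tgt_chrom[i] != a$tgt_chrom[l] ||
      a$orientation[i] != a$orientation[l]) return(FALSE)
  if (a$ref_start[i] <= a$ref_start[l]) return(FALSE) # ref must advance
  ref_gap <- a$ref_start[i] - a$ref_end[l]
  if (ref_gap < -params$min_anchor || ref_gap > params$max_gap) return(FALSE)
  if (a$orientation[i] == "+") {
    if (a$tgt_start[i] <= a$tgt_start[l]) return(FALSE)
    tgt_gap <- a$tgt_start[i] - a$tgt_end[l]
  } else {
    if (a$tgt_start[i] >= a$tgt_start[l]) return(FALSE)
    tgt_gap <- a$tgt_start[l] - a$tgt_end[i]
  }
  tgt_gap >= -params$min_anchor && tgt_gap <= params$max_gap
}

#' Chain sorted anchors into collinear runs
#'
#' Greedy left-to-right chaining per reference chromosome: each anchor
#' either extends the currently open run or closes it and opens a new one.
#' Every anchor belongs to exactly one run.
#'
#' @param anchors Output of [filter_anchors()] (sorted).
#' @param params [build_params()].
#' @return The anchor table with an added integer `run_id` column; runs are
#'   numbered in order of opening.
#' @export
chain_anchors <- function(anchors, params) {
  a <- anchors
  n <- nrow(a)
  run_id <- integer(n)
  rid <- 0L
  last <- 0L # row index of the open run's last anchor
  for (i in seq_len(n)) {
    new_run <- last == 0L ||
      a$ref_chrom[i] != a$ref_chrom[last] ||
      !join_ok(a, i, last, params)
    if (new_run) rid <- rid + 1L
    run_id[i] <- rid
    last <- i
  }
  a$run_id <- run_id
  a
}

#' Turn chained runs into candidate synteny blocks
#'
#' Each run becomes one block: the reference interval spans first to last
#' anchor, the target interval is the enclosing span of member target
#' intervals, orientation is the run's.  Blocks below `params$resolution`
#' on either genome are dropped; survivors are numbered 1..n in reference
#' order.
#'
#' @param chained Output of [chain_anchors()] (`run_id` column present).
#' @param params [build_params()].
#' @param chrom_order Optional reference chromosome order.
#' @return Data frame of candidate blocks with columns `block_id`,
#'   `ref_chrom`, `ref_start`, `ref_end`, `tgt_chrom`, `tgt_start`,
#'   `tgt_end`, `orientation`.
#' @export
runs_to_blocks <- function(chained, params, chrom_order = NULL) {
  if (nrow(chained) == 0L) {
    return(data.frame(block_id = integer(), ref_chrom = character(),
                      ref_start = numeric(), ref_end = numeric(),
                      tgt_chrom = character(), tgt_start = numeric(),
                      tgt_end = numeric(), orientation = character(),
                      stringsAsFactors = FALSE))
  }
  g <- split(chained, chained$run_id)
  blk <- do.call(rbind, lapply(g, function(r) {
    data.frame(ref_chrom = r$ref_chrom[1],
               ref_start = min(r$ref_start), ref_end = max(r$ref_end),
               tgt_chrom = r$tgt_chrom[1],
               tgt_start = min(r$tgt_start), tgt_end = max(r$tgt_end),
               orientation = r$orientation[1], stringsAsFactors = FALSE)
  }))
  keep <- (blk$ref_end - blk$ref_start) >= params$resolution &
    (blk$tgt_end - blk$tgt_start) >= params$resolution
  blk <- blk[keep, , drop = FALSE]
  if (is.null(chrom_order)) chrom_order <- unique(chained$ref_chrom)
  ord <- order(match(blk$ref_chrom, chrom_order), blk$ref_start,
               -(blk$ref_end - blk$ref_start))
  blk <- blk[ord, , drop = FALSE]
  blk <- cbind(block_id = seq_len(nrow(blk)), blk)
  rownames(blk) <- NULL
  blk
}

# trim `bp` off one side of a block, cropping the other genome
# proportionally (direction respects orientation).  side: "ref_left",
# "ref_right", "tgt_left", "tgt_right".
trim_block <- function(b, side, bp) {
  rs <- b$ref_end - b$ref_start
  ts <- b$tgt_end - b$tgt_start
  if (side %in% c("ref_left", "ref_right")) {
    prop <- round(bp / rs * ts)
    if (side == "ref_left") {
      b$ref_start <- b$ref_start + bp
      if (b$orientation == "+") b$tgt_start <- b$tgt_start + prop
      else b$tgt_end <- b$tgt_end - prop
    } else {
      b$ref_end <- b$ref_end - bp
      if (b$orientation == "+") b$tgt_end <- b$tgt_end - prop
      else b$tgt_start <- b$tgt_start + prop
    }
  } else {
    prop <- round(bp / ts * rs)
    if (side == "tgt_left") {
      b$tgt_start <- b$tgt_start + bp
      if (b$orientation == "+") b$ref_start <- b$ref_start + prop
      else b$ref_end <- b$ref_end - prop
    } else {
      b$tgt_end <- b$tgt_end - bp
      if (b$orientation == "+") b$ref_end <- b$ref_end - prop
      else b$ref_start <- b$ref_start + prop
    }
  }
  b
}

# one left-to-right sweep resolving overlaps on one genome ("ref" or
# "tgt").  Maintains a per-chromosome set of accepted, pairwise-disjoint
# blocks; each incoming block (sorted by start) is resolved against every
# accepted block it still overlaps, leftmost first.  The block with the
# smaller *reference* span is trimmed by the overlap amount on its
# overlapping side (ties trim the incoming block); anything trimmed below
# the resolution on either genome is dropped.
sweep_overlaps <- function(blk, params, genome = c("ref", "tgt")) {
  genome <- match.arg(genome)
  sc <- paste0(genome, "_chrom"); ss <- paste0(genome, "_start")
  se <- paste0(genome, "_end")
  alive <- rep(TRUE, nrow(blk))
  too_small <- function(j) {
    (blk$ref_end[j] - blk$ref_start[j]) < params$resolution ||
      (blk$tgt_end[j] - blk$tgt_start[j]) < params$resolution
  }
  ord <- order(blk[[sc]], blk[[ss]], blk[[se]])
  acc <- list() # per-chromosome integer vectors of accepted row indices
  for (k in ord) {
    cc <- blk[[sc]][k]
    rows <- acc[[cc]]
    repeat {
      if (!alive[k] || length(rows) == 0L) break
      ovl <- .ovl(blk[[ss]][rows], blk[[se]][rows],
                  blk[[ss]][k], blk[[se]][k])
      hit <- rows[ovl > 0]
      if (length(hit) == 0L) break
      p <- hit[which.min(blk[[ss]][hit])]
      o <- min(blk[[se]][p], blk[[se]][k]) - max(blk[[ss]][p], blk[[ss]][k])
      span_p <- blk$ref_end[p] - blk$ref_start[p]
      span_k <- blk$ref_end[k] - blk$ref_start[k]
      if (span_k <= span_p) {
        if (blk[[se]][k] <= blk[[se]][p]) {
          alive[k] <- FALSE # incoming block contained in accepted one
        } else {
          blk[k, ] <- trim_block(blk[k, ], paste0(genome, "_left"), o)
          if (too_small(k)) alive[k] <- FALSE
        }
      } else {
        blk[p, ] <- trim_block(blk[p, ], paste0(genome, "_right"), o)
        if (too_small(p)) {
          alive[p] <- FALSE
          rows <- setdiff(rows, p)
          acc[[cc]] <- rows
        }
      }
    }
    if (alive[k]) acc[[cc]] <- c(rows, k)
  }
  blk[alive, , drop = FALSE]
}

#' Resolve residual overlaps between candidate blocks
#'
#' Deterministic left-to-right sweep, first along the reference, then along
#' each target chromosome: where two blocks overlap, the one with the
#' smaller reference span is trimmed by the overlap amount on the
#' overlapping side (the other genome's interval is cropped
#' proportionally); blocks trimmed below the resolution are dropped.
#'
#' @param blocks Candidate blocks from [runs_to_blocks()].
#' @param params [build_params()].
#' @param chrom_order Optional reference chromosome order.
#' @return Non-overlapping blocks, renumbered in reference order.
#' @export
resolve_overlaps <- function(blocks, params, chrom_order = NULL) {
  if (nrow(blocks) == 0L) return(blocks)
  blk <- sweep_overlaps(blocks, params, "ref")
  blk <- sweep_overlaps(blk, params, "tgt")
  if (is.null(chrom_order)) chrom_order <- unique(blocks$ref_chrom)
  ord <- order(match(blk$ref_chrom, chrom_order), blk$ref_start)
  blk <- blk[ord, , drop = FALSE]
  blk$block_id <- seq_len(nrow(blk))
  rownames(blk) <- NULL
  blk
}

#' Build a pairwise synteny map from anchors
#'
#' Full pipeline: [filter_anchors()] -> [chain_anchors()] ->
#' [runs_to_blocks()] -> [resolve_overlaps()] -> renumber.
#'
#' @param anchors An [anchor_table()].
#' @param reference,target Genome names.
#' @param params [build_params()].
#' @param ref_karyotype Optional reference [karyotype()]; supplies the
#'   chromosome order and bounds checks.
#' @return A [synteny_map()] with a single target.
#' @export
build_pairwise <- function(anchors, reference, target, params,
                           ref_karyotype = NULL) {
  chrom_order <- if (!is.null(ref_karyotype)) ref_karyotype$chrom else NULL
  a <- filter_anchors(anchors, params, chrom_order)
  ch <- chain_anchors(a, params)
  blk <- runs_to_blocks(ch, params, chrom_order)
  blk <- resolve_overlaps(blk, params, chrom_order)
  synteny_map(
    reference, target,
    blocks = blk[, c("block_id", "ref_chrom", "ref_start", "ref_end"),
                 drop = FALSE],
    placements = if (nrow(blk)) data.frame(
      block_id = blk$block_id, target = target, tgt_chrom = blk$tgt_chrom,
      tgt_start = blk$tgt_start, tgt_end = blk$tgt_end,
      orientation = blk$orientation, stringsAsFactors = FALSE
    ) else data.frame(),
    resolution = params$resolution, chrom_order = chrom_order
  )
}

# linear crop of a placement to a reference sub-interval [s,e), direction
# respecting orientation
crop_placement <- function(p, ref_start, ref_end, s, e) {
  rs <- ref_end - ref_start
  ts <- p$tgt_end - p$tgt_start
  f1 <- (s - ref_start) / rs
  f2 <- (e - ref_start) / rs
  if (p$orientation == "+") {
    c(p$tgt_start + round(f1 * ts), p$tgt_start + round(f2 * ts))
  } else {
    c(p$tgt_end - round(f2 * ts), p$tgt_end - round(f1 * ts))
  }
}

#' Intersect pairwise maps into a multi-species map
#'
#' The reference is partitioned at the union of all pairwise block
#' boundaries; a segment is kept iff it is covered by exactly one block in
#' every pairwise map and spans at least the resolution.  Kept segments
#' become multi-species blocks whose per-target placements are the covering
#' blocks' target intervals cropped linearly in proportion to the
#' reference crop.
#'
#' @param pairwise_maps List of single-target [synteny_map()]s sharing one
#'   reference.
#' @param params [build_params()].
#' @return A multi-target [synteny_map()].
#' @export
intersect_maps <- function(pairwise_maps, params) {
  stopifnot(length(pairwise_maps) >= 1L)
  refs <- vapply(pairwise_maps, function(m) m$reference, "")
  if (length(unique(refs)) != 1L) {
    stop("pairwise maps disagree on the reference genome: ",
         paste(unique(refs), collapse = " vs "))
  }
  targets <- unlist(lapply(pairwise_maps, function(m) m$targets))
  if (anyDuplicated(targets)) stop("duplicate target across pairwise maps")
  chrom_order <- unique(unlist(lapply(pairwise_maps,
                                      function(m) m$chrom_order)))
  pb <- lapply(seq_along(pairwise_maps), function(i) {
    pairwise_blocks(pairwise_maps[[i]], targets[i])
  })
  chroms <- unique(unlist(lapply(pb, function(b) b$ref_chrom)))
  chroms <- chroms[order(match(chroms, chrom_order))]
  out_blocks <- list(); out_pl <- list(); nb <- 0L
  for (cc in chroms) {
    bds <- sort(unique(unlist(lapply(pb, function(b) {
      k <- b[b$ref_chrom == cc, ]
      c(k$ref_start, k$ref_end)
    }))))
    if (length(bds) < 2L) next
    for (s_i in seq_len(length(bds) - 1L)) {
      s <- bds[s_i]; e <- bds[s_i + 1L]
      if (e - s < params$resolution) next
      covers <- lapply(pb, function(b) {
        k <- b[b$ref_chrom == cc & b$ref_start <= s & b$ref_end >= e, ,
               drop = FALSE]
        if (nrow(k) == 1L) k else NULL
      })
      if (any(vapply(covers, is.null, TRUE))) next
      nb <- nb + 1L
      out_blocks[[nb]] <- data.frame(block_id = nb, ref_chrom = cc,
                                     ref_start = s, ref_end = e,
                                     stringsAsFactors = FALSE)
      out_pl[[nb]] <- do.call(rbind, lapply(seq_along(covers), function(i) {
        p <- covers[[i]]
        tt <- crop_placement(p, p$ref_start, p$ref_end, s, e)
        data.frame(block_id = nb, target = targets[i],
                   tgt_chrom = p$tgt_chrom, tgt_start = tt[1],
                   tgt_end = tt[2], orientation = p$orientation,
                   stringsAsFactors = FALSE)
      }))
    }
  }
  synteny_map(refs[1], targets,
              blocks = if (nb) do.call(rbind, out_blocks) else data.frame(),
              placements = if (nb) do.call(rbind, out_pl) else data.frame(),
              resolution = params$resolution, chrom_order = chrom_order)
}
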