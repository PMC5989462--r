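# Rearrangement simulator with exact ground truth.
#
# A target genome is evolved from a reference karyotype by a sequence of
# bp-preserving operations (inversion, reciprocal translocation, fusion,
# fission, transposition).  The evolving genome is a list of chromosomes,
# each an ordered table of reference segments with orientation; because no
# operation gains or loses sequence, the final segments tile both genomes
# exactly and constitute the true synteny block decomposition.  Anchors
# and genes with known classes are then emitted from that truth, so block
# construction and the downstream analyses can be validated without any
# real alignment.

#' Simulate a karyotype
#'
#' @param n_chroms Number of chromosomes (>= 1).
#' @param length_range Length range in bp, `c(min, max)`, sampled uniformly.
#' @param seed Integer seed; same seed, same karyotype.
#' @param genome Genome label.
#' @return A [karyotype()] with chromosomes `chr1..chrN`.
#' @export
simulate_karyotype <- function(n_chroms, length_range, seed = 1,
                               genome = "ref") {
  if (n_chroms < 1) stop("n_chroms must be >= 1")
  length_range <- as.numeric(length_range)
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2]) {
    stop("length_range must be c(min, max) with 1 <= min <= max")
  }
  set.seed(seed)
  len <- round(stats::runif(n_chroms, length_range[1], length_range[2]))
  karyotype(paste0("chr", seq_len(n_chroms)), len, genome = genome)
}

# ---- evolving-genome primitives ------------------------------------------
# a chromosome is a data.frame(ref_chrom, ref_start, ref_end, orient);
# its target length is sum(ref_end - ref_start)

chr_len <- function(chr) sum(chr$ref_end - chr$ref_start)

# split a chromosome at target offset pos (0 < pos < length)
split_chr <- function(chr, pos) {
  lens <- chr$ref_end - chr$ref_start
  cum <- cumsum(lens)
  i <- which(pos <= cum)[1]
  c0 <- if (i == 1L) 0 else cum[i - 1L]
  d <- pos - c0
  if (d == 0) {
    list(head = chr[seq_len(i - 1L), , drop = FALSE],
         tail = chr[seq(i, nrow(chr)), , drop = FALSE])
  } else if (d == lens[i]) {
    list(head = chr[seq_len(i), , drop = FALSE],
         tail = chr[-seq_len(i), , drop = FALSE])
  } else {
    s <- chr[i, , drop = FALSE]
    if (s$orient == "+") {
      left <- transform(s, ref_end = ref_start + d)
      right <- transform(s, ref_start = ref_start + d)
    } else { # target-left part of a "-" segment is the reference-right part
      left <- transform(s, ref_start = ref_end - d)
      right <- transform(s, ref_end = ref_end - d)
    }
    list(head = rbind(chr[seq_len(i - 1L), , drop = FALSE], left),
         tail = rbind(right, chr[-seq_len(i), , drop = FALSE]))
  }
}

flip_chr <- function(chr) {
  out <- chr[rev(seq_len(nrow(chr))), , drop = FALSE]
  out$orient <- ifelse(out$orient == "+", "-", "+")
  out
}

apply_op <- function(genome, op) {
  k <- op$kind
  if (k == "inversion") {
    chr <- genome[[op$chrom]]
    p1 <- split_chr(chr, op$start)
    p2 <- split_chr(p1$tail, op$end - op$start)
    genome[[op$chrom]] <- rbind(p1$head, flip_chr(p2$head), p2$tail)
  } else if (k == "translocation") {
    a <- split_chr(genome[[op$chrom1]], op$pos1)
    b <- split_chr(genome[[op$chrom2]], op$pos2)
    genome[[op$chrom1]] <- rbind(a$head, b$tail)
    genome[[op$chrom2]] <- rbind(b$head, a$tail)
  } else if (k == "fusion") {
    genome[[op$chrom1]] <- rbind(genome[[op$chrom1]], genome[[op$chrom2]])
    genome[[op$chrom2]] <- NULL
  } else if (k == "fission") {
    p <- split_chr(genome[[op$chrom]], op$pos)
    genome[[op$chrom]] <- p$head
    genome[[length(genome) + 1L]] <- p$tail
  } else if (k == "transposition") {
    p1 <- split_chr(genome[[op$chrom]], op$start)
    p2 <- split_chr(p1$tail, op$end - op$start)
    moved <- p2$head
    genome[[op$chrom]] <- rbind(p1$head, p2$tail)
    d <- split_chr(genome[[op$dest_chrom]], op$dest_pos)
    genome[[op$dest_chrom]] <- rbind(d$head, moved, d$tail)
  } else {
    stop("unknown rearrangement kind: ", k)
  }
  genome
}

# merge target-adjacent segments that are exact collinear continuations
merge_collinear <- function(chr) {
  if (nrow(chr) <= 1L) return(chr)
  keep <- list(chr[1, , drop = FALSE])
  for (i in seq(2L, nrow(chr))) {
    s <- keep[[length(keep)]]
    t <- chr[i, , drop = FALSE]
    joinable <- s$ref_chrom == t$ref_chrom && s$orient == t$orient &&
      ((s$orient == "+" && t$ref_start == s$ref_end) ||
         (s$orient == "-" && t$ref_end == s$ref_start))
    if (joinable) {
      s$ref_start <- min(s$ref_start, t$ref_start)
      s$ref_end <- max(s$ref_end, t$ref_end)
      keep[[length(keep)]] <- s
    } else {
      keep[[length(keep) + 1L]] <- t
    }
  }
  do.call(rbind, keep)
}

# TRUE when some pair of target-adjacent segments has a small nonzero
# reference gap in the joinable direction (decomposition would be ambiguous
# for any chaining gap <= guard)
is_ambiguous <- function(genome, guard) {
  for (chr in genome) {
    if (nrow(chr) <= 1L) next
    for (i in seq_len(nrow(chr) - 1L)) {
      s <- chr[i, ]; t <- chr[i + 1L, ]
      if (s$ref_chrom != t$ref_chrom || s$orient != t$orient) next
      g <- if (s$orient == "+") t$ref_start - s$ref_end
           else s$ref_start - t$ref_end
      if (g > 0 && g <= guard) return(TRUE)
    }
  }
  FALSE
}

# draw a breakpoint >= min_seg away from every existing boundary of chr
# (including the ends) and from positions in `avoid`; NA when impossible
draw_pos <- function(chr, min_seg, avoid = numeric(0), tries = 200L) {
  L <- chr_len(chr)
  if (L < 2 * min_seg) return(NA_real_)
  bnd <- c(0, cumsum(chr$ref_end - chr$ref_start), avoid)
  for (t in seq_len(tries)) {
    p <- round(stats::runif(1, min_seg, L - min_seg))
    if (all(abs(p - bnd) >= min_seg)) return(p)
  }
  NA_real_
}

random_op <- function(genome, kinds, min_seg) {
  lens <- vapply(genome, chr_len, 0)
  for (try in seq_len(200L)) {
    k <- sample(kinds, 1L)
    if (k %in% c("translocation", "fusion") && length(genome) < 2L) next
    if (k == "inversion") {
      ci <- sample.int(length(genome), 1L, prob = lens)
      if (lens[ci] < 3 * min_seg) next
      a <- draw_pos(genome[[ci]], min_seg)
      if (is.na(a)) next
      b <- draw_pos(genome[[ci]], min_seg, avoid = a)
      if (is.na(b)) next
      return(list(kind = k, chrom = ci, start = min(a, b), end = max(a, b)))
    } else if (k == "translocation") {
      cij <- sample.int(length(genome), 2L)
      p1 <- draw_pos(genome[[cij[1]]], min_seg)
      p2 <- draw_pos(genome[[cij[2]]], min_seg)
      if (is.na(p1) || is.na(p2)) next
      return(list(kind = k, chrom1 = cij[1], pos1 = p1,
                  chrom2 = cij[2], pos2 = p2))
    } else if (k == "fusion") {
      cij <- sample.int(length(genome), 2L)
      return(list(kind = k, chrom1 = cij[1], chrom2 = cij[2]))
    } else if (k == "fission") {
      ci <- sample.int(length(genome), 1L, prob = lens)
      p <- draw_pos(genome[[ci]], min_seg)
      if (is.na(p)) next
      return(list(kind = k, chrom = ci, pos = p))
    } else if (k == "transposition") {
      ci <- sample.int(length(genome), 1L, prob = lens)
      if (lens[ci] < 4 * min_seg) next
      a <- draw_pos(genome[[ci]], min_seg)
      if (is.na(a)) next
      b <- draw_pos(genome[[ci]], min_seg, avoid = a)
      if (is.na(b)) next
      ab <- sort(c(a, b))
      if (ab[2] - ab[1] > lens[ci] - 3 * min_seg) next
      cj <- sample.int(length(genome), 1L)
      # destination position on the post-excision chromosome
      tmp <- genome
      tmp[[ci]] <- rbind(split_chr(tmp[[ci]], ab[1])$head,
                         split_chr(split_chr(tmp[[ci]], ab[1])$tail,
                                   ab[2] - ab[1])$tail)
      p <- draw_pos(tmp[[cj]], min_seg)
      if (is.na(p)) next
      return(list(kind = k, chrom = ci, start = ab[1], end = ab[2],
                  dest_chrom = cj, dest_pos = p))
    }
  }
  stop("could not draw a valid rearrangement operation ",
       "(min_seg too large for the genome?)")
}

#' Simulate rearrangements with an exact truth decomposition
#'
#' Applies either an explicit operation list or `n_ops` randomly drawn
#' operations to a copy of the reference genome.  Because every operation
#' is bp-preserving, the resulting segments tile the reference exactly and
#' form the ground-truth synteny map: inversions flip orientation,
#' translocations move segments between target chromosomes, fusion and
#' fission edit the target karyotype.  Randomly drawn breakpoints keep at
#' least `min_seg` bp between any two breakpoints, and op sequences whose
#' decomposition would be ambiguous at joining gaps up to `guard` bp are
#' redrawn, so that truth recovery by chaining is well-posed whenever
#' `max_gap <= guard`.
#'
#' @param ref_karyotype Reference [karyotype()].
#' @param n_ops Number of random operations (ignored when `ops` given).
#' @param ops Optional explicit list of operations; each a list with a
#'   `kind` of `"inversion"` (`chrom`, `start`, `end`), `"translocation"`
#'   (`chrom1`, `pos1`, `chrom2`, `pos2`), `"fusion"` (`chrom1`, `chrom2`),
#'   `"fission"` (`chrom`, `pos`) or `"transposition"` (`chrom`, `start`,
#'   `end`, `dest_chrom`, `dest_pos`).  Chromosomes are indices into the
#'   evolving target genome; positions are target-coordinate breakpoints.
#' @param seed Integer seed.
#' @param kinds Kinds sampled in random mode.
#' @param min_seg Minimum distance between breakpoints (and to chromosome
#'   ends), bp.
#' @param guard Ambiguity guard in bp (see above); must be <= `min_seg`.
#' @param target_genome Label for the evolved genome.
#' @return A list of class `"truth_set"`: `ref_karyotype`,
#'   `tgt_karyotype`, `map` (the truth [synteny_map()]), `ops`.
#' @export
simulate_rearrangements <- function(ref_karyotype, n_ops = NULL, ops = NULL,
                                    seed = 1,
                                    kinds = c("inversion", "translocation",
                                              "fission", "fusion",
                                              "transposition"),
                                    min_seg = 1e5, guard = 5e4,
                                    target_genome = "tgt") {
  if (guard > min_seg) stop("guard must be <= min_seg")
  init <- lapply(seq_len(nrow(ref_karyotype)), function(i) {
    data.frame(ref_chrom = ref_karyotype$chrom[i], ref_start = 0,
               ref_end = ref_karyotype$length[i], orient = "+",
               stringsAsFactors = FALSE)
  })
  set.seed(seed)
  if (is.null(ops)) {
    if (is.null(n_ops)) stop("give either n_ops or ops")
    for (attempt in seq_len(25L)) {
      genome <- init
      drawn <- vector("list", n_ops)
      for (i in seq_len(n_ops)) {
        drawn[[i]] <- random_op(genome, kinds, min_seg)
        genome <- apply_op(genome, drawn[[i]])
      }
      genome <- lapply(genome, merge_collinear)
      if (!is_ambiguous(genome, guard)) { ops <- drawn; break }
      if (attempt == 25L) stop("could not draw an unambiguous op sequence")
    }
  } else {
    genome <- init
    for (op in ops) {
      # validate breakpoints fall strictly inside the named chromosome
      for (f in intersect(names(op), c("start", "end", "pos", "pos1",
                                       "pos2", "dest_pos"))) {
        ci <- op[[switch(f, pos1 = "chrom1", pos2 = "chrom2",
                         dest_pos = "dest_chrom", "chrom")]]
        if (op[[f]] <= 0 || op[[f]] >= chr_len(genome[[ci]])) {
          stop("breakpoint ", f, "=", fmt_bp(op[[f]]),
               " outside chromosome ", ci)
        }
      }
      genome <- apply_op(genome, op)
    }
    genome <- lapply(genome, merge_collinear)
  }
  # lay out target coordinates and collect truth blocks
  tgt_names <- paste0("tchr", seq_along(genome))
  tgt_len <- vapply(genome, chr_len, 0)
  rows <- list()
  for (m in seq_along(genome)) {
    chr <- genome[[m]]
    off <- c(0, cumsum(chr$ref_end - chr$ref_start))
    for (i in seq_len(nrow(chr))) {
      rows[[length(rows) + 1L]] <- data.frame(
        ref_chrom = chr$ref_chrom[i], ref_start = chr$ref_start[i],
        ref_end = chr$ref_end[i], tgt_chrom = tgt_names[m],
        tgt_start = off[i], tgt_end = off[i + 1L],
        orientation = chr$orient[i], stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, rows)
  ord <- order(match(seg$ref_chrom, ref_karyotype$chrom), seg$ref_start)
  seg <- seg[ord, , drop = FALSE]
  seg$block_id <- seq_len(nrow(seg))
  map <- synteny_map(
    attr(ref_karyotype, "genome"), target_genome,
    blocks = seg[, c("block_id", "ref_chrom", "ref_start", "ref_end")],
    placements = data.frame(block_id = seg$block_id, target = target_genome,
                            tgt_chrom = seg$tgt_chrom,
                            tgt_start = seg$tgt_start,
                            tgt_end = seg$tgt_end,
                            orientation = seg$orientation,
                            stringsAsFactors = FALSE),
    resolution = 0, chrom_order = ref_karyotype$chrom)
  structure(list(ref_karyotype = ref_karyotype,
                 tgt_karyotype = karyotype(tgt_names, tgt_len,
                                           genome = target_genome),
                 map = map, ops = ops),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth set: %d ops, %d truth blocks, %d -> %d chromosomes\n",
              length(x$ops), nrow(x$map$blocks), nrow(x$ref_karyotype),
              nrow(x$tgt_karyotype)))
  invisible(x)
}

#' Emit alignment anchors from a truth decomposition
#'
#' Each truth block is tiled with alternating anchor/gap segments whose
#' lengths are drawn uniformly within +/- 50% of the given means; the first
#' anchor starts exactly at the block start and the last ends exactly at
#' the block end, so noise-free anchors reproduce block boundaries
#' precisely.  Optional noise: boundary jitter (normal, truncated at 3 sd),
#' uniformly placed spurious anchors, and random dropping of true anchors.
#'
#' @param truth A `"truth_set"` from [simulate_rearrangements()].
#' @param anchor_len_mean,gap_mean Mean anchor and inter-anchor gap length
#'   (bp); `anchor_len_mean > gap_mean >= 0`.
#' @param jitter_sd Boundary jitter sd in bp (0 = exact).
#' @param spurious_rate Spurious anchors as a fraction of true anchors.
#' @param drop_rate Probability that each true anchor is dropped.
#' @param seed Integer seed.
#' @param exclude_blocks Truth block ids to omit entirely (creates
#'   uncovered reference regions, e.g. for planting unplaced genes).
#' @return An [anchor_table()].
#' @export
anchors_from_truth <- function(truth, anchor_len_mean = 20000,
                               gap_mean = 2000, jitter_sd = 0,
                               spurious_rate = 0, drop_rate = 0, seed = 1,
                               exclude_blocks = integer()) {
  if (anchor_len_mean <= gap_mean || gap_mean < 0) {
    stop("need anchor_len_mean > gap_mean >= 0")
  }
  if (spurious_rate < 0 || spurious_rate > 1 || drop_rate < 0 ||
      drop_rate > 1) stop("rates must lie in [0, 1]")
  set.seed(seed)
  pw <- pairwise_blocks(truth$map, truth$map$targets[1])
  pw <- pw[!pw$block_id %in% exclude_blocks, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(pw))) {
    b <- pw[i, ]
    pos <- b$ref_start
    repeat {
      len <- round(stats::runif(1, 0.5, 1.5) * anchor_len_mean)
      gap <- round(stats::runif(1, 0.5, 1.5) * gap_mean)
      last <- pos + len + gap + 0.5 * anchor_len_mean >= b$ref_end
      if (last) len <- b$ref_end - pos
      if (b$orientation == "+") {
        ts <- b$tgt_start + (pos - b$ref_start)
      } else {
        ts <- b$tgt_end - (pos - b$ref_start) - len
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ref_chrom = b$ref_chrom, ref_start = pos, ref_end = pos + len,
        tgt_chrom = b$tgt_chrom, tgt_start = ts, tgt_end = ts + len,
        orientation = b$orientation, score = 0, stringsAsFactors = FALSE)
      if (last) break
      pos <- pos + len + gap
    }
  }
  a <- do.call(rbind, rows)
  if (is.null(a)) {
    return(anchor_table(character(), numeric(), numeric(), character(),
                        numeric(), numeric()))
  }
  n_true <- nrow(a)
  if (drop_rate > 0) {
    a <- a[stats::runif(n_true) >= drop_rate, , drop = FALSE]
  }
  if (jitter_sd > 0 && nrow(a)) {
    rlen <- vapply(a$ref_chrom, function(cc) {
      truth$ref_karyotype$length[match(cc, truth$ref_karyotype$chrom)]
    }, 0)
    tlen <- vapply(a$tgt_chrom, function(cc) {
      truth$tgt_karyotype$length[match(cc, truth$tgt_karyotype$chrom)]
    }, 0)
    jit <- function(x) {
      d <- round(stats::rnorm(length(x), 0, jitter_sd))
      x + pmax(pmin(d, 3 * jitter_sd), -3 * jitter_sd)
    }
    rs <- pmax(0, jit(a$ref_start)); re <- pmin(rlen, jit(a$ref_end))
    ts <- pmax(0, jit(a$tgt_start)); te <- pmin(tlen, jit(a$tgt_end))
    ok <- rs < re & ts < te
    a$ref_start[ok] <- rs[ok]; a$ref_end[ok] <- re[ok]
    a$tgt_start[ok] <- ts[ok]; a$tgt_end[ok] <- te[ok]
  }
  n_spur <- round(spurious_rate * n_true)
  if (n_spur > 0) {
    rk <- truth$ref_karyotype; tk <- truth$tgt_karyotype
    sp <- lapply(seq_len(n_spur), function(i) {
      len <- round(stats::runif(1, 0.5, 1.5) * anchor_len_mean)
      ri <- sample.int(nrow(rk), 1L, prob = rk$length)
      ti <- sample.int(nrow(tk), 1L, prob = tk$length)
      rs <- round(stats::runif(1, 0, max(1, rk$length[ri] - len)))
      ts <- round(stats::runif(1, 0, max(1, tk$length[ti] - len)))
      data.frame(ref_chrom = rk$chrom[ri], ref_start = rs,
                 ref_end = min(rk$length[ri], rs + len),
                 tgt_chrom = tk$chrom[ti], tgt_start = ts,
                 tgt_end = min(tk$length[ti], ts + len),
                 orientation = sample(c("+", "-"), 1L), score = 0,
                 stringsAsFactors = FALSE)
    })
    a <- rbind(a, do.call(rbind, sp))
  }
  rownames(a) <- NULL
  validate_anchors(a)
}

#' Plant genes with known block relationships
#'
#' Emits genes whose class under [classify_genes()] is known by
#' construction: `conserved` genes strictly inside one block, `broken`
#' genes straddling block boundaries (including one three-block spanner
#' when three consecutive unmasked blocks exist), and `unplaced` genes
#' strictly inside blocks listed in `masked_blocks` (whose anchors the
#' caller omits via `exclude_blocks` in [anchors_from_truth()], leaving
#' those reference regions uncovered).
#'
#' @param truth A `"truth_set"`.
#' @param n_per_class Genes per class.
#' @param seed Integer seed.
#' @param masked_blocks Block ids masked out of the anchor set; required
#'   nonempty when unplaced genes are requested.
#' @param margin Safety margin in bp kept between planted genes and block
#'   boundaries they must not cross.
#' @return Data frame: `chrom`, `start`, `end`, `name`, `strand`,
#'   `intended_class`.
#' @export
genes_from_truth <- function(truth, n_per_class = 5, seed = 1,
                             masked_blocks = integer(), margin = 5000) {
  set.seed(seed)
  if (n_per_class == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      strand = character(), intended_class = character(),
                      stringsAsFactors = FALSE))
  }
  pw <- pairwise_blocks(truth$map, truth$map$targets[1])
  unmasked <- pw[!pw$block_id %in% masked_blocks, , drop = FALSE]
  masked <- pw[pw$block_id %in% masked_blocks, , drop = FALSE]
  strands <- c("+", "-")
  out <- list()
  add <- function(chrom, start, end, name, cls) {
    out[[length(out) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, name = name,
      strand = strands[1L + length(out) %% 2L], intended_class = cls,
      stringsAsFactors = FALSE)
  }
  # conserved: strictly inside one unmasked block
  wide <- unmasked[unmasked$ref_end - unmasked$ref_start > 4 * margin, ,
                   drop = FALSE]
  if (nrow(wide) < 1L) stop("no block wide enough for conserved genes")
  pick <- wide[1L + (seq_len(n_per_class) - 1L) %% nrow(wide), ,
               drop = FALSE]
  for (i in seq_len(n_per_class)) {
    b <- pick[i, ]
    span <- b$ref_end - b$ref_start
    gs <- b$ref_start + round(span * stats::runif(1, 0.2, 0.5))
    add(b$ref_chrom, gs, gs + round(span * 0.2), sprintf("CONS%d", i),
        "conserved")
  }
  # broken: straddle boundaries between consecutive unmasked blocks that
  # tile the reference contiguously; first one spans a whole middle block
  # (three blocks) when the geometry allows
  adj <- list() # pairs (i, i+1) of unmasked rows adjacent on the reference
  if (nrow(unmasked) > 1L) {
    for (i in seq_len(nrow(unmasked) - 1L)) {
      if (unmasked$ref_chrom[i] == unmasked$ref_chrom[i + 1L] &&
          unmasked$ref_end[i] == unmasked$ref_start[i + 1L]) {
        adj[[length(adj) + 1L]] <- i
      }
    }
  }
  if (length(adj) < 1L) stop("no adjacent unmasked blocks for broken genes")
  adj <- unlist(adj)
  triple <- NA_integer_
  for (i in adj) {
    if ((i + 1L) %in% adj) { triple <- i; break }
  }
  made <- 0L
  if (!is.na(triple) && n_per_class >= 1L) {
    mid <- unmasked[triple + 1L, ]
    add(mid$ref_chrom, mid$ref_start - margin, mid$ref_end + margin,
        "SPAN3", "broken")
    made <- 1L
  }
  i <- 0L
  while (made < n_per_class) {
    j <- adj[1L + i %% length(adj)]
    b1 <- unmasked[j, ]; b2 <- unmasked[j + 1L, ]
    bd <- b1$ref_end
    d <- floor(min(margin, (b1$ref_end - b1$ref_start) / 4,
                   (b2$ref_end - b2$ref_start) / 4))
    add(b1$ref_chrom, bd - d, bd + d, sprintf("BRK%d", made + 1L), "broken")
    made <- made + 1L; i <- i + 1L
  }
  # unplaced: strictly inside masked blocks, away from their edges
  if (nrow(masked) < 1L) {
    stop("unplaced genes need masked blocks (pass masked_blocks and ",
         "exclude the same ids in anchors_from_truth)")
  }
  for (i in seq_len(n_per_class)) {
    b <- masked[1L + (i - 1L) %% nrow(masked), ]
    span <- b$ref_end - b$ref_start
    if (span <= 4 * margin) stop("masked block too narrow for unplaced gene")
    gs <- b$ref_start + round(span * stats::runif(1, 0.3, 0.5))
    add(b$ref_chrom, gs, gs + round(span * 0.2), sprintf("UNPL%d", i),
        "unplaced")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
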