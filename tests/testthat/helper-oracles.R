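# Shared fixtures and independent oracles used across the suite.

toy_karyotype <- function(genome = "ref", n = 2, len = 1e6) {
  karyotype(paste0("chr", seq_len(n)), rep(len, n), genome = genome)
}

# random valid synteny map for round-trip properties: disjoint reference
# intervals per chromosome, every block placed on a random nonempty subset
# of targets
random_map <- function(seed, max_blocks = 8, n_targets = 2) {
  set.seed(seed)
  targets <- paste0("t", seq_len(n_targets))
  n <- sample.int(max_blocks, 1)
  blocks <- list(); placements <- list()
  pos <- c(chrA = 0, chrB = 0)
  for (i in seq_len(n)) {
    cc <- sample(names(pos), 1)
    start <- pos[[cc]] + sample.int(5000, 1)
    end <- start + sample.int(50000, 1)
    pos[[cc]] <- end
    blocks[[i]] <- data.frame(block_id = i, ref_chrom = cc,
                              ref_start = start, ref_end = end,
                              stringsAsFactors = FALSE)
    placed <- sample(targets, sample.int(n_targets, 1))
    placements[[i]] <- do.call(rbind, lapply(placed, function(t) {
      ts <- sample.int(1e6, 1)
      data.frame(block_id = i, target = t,
                 tgt_chrom = sample(c("x1", "x2"), 1), tgt_start = ts,
                 tgt_end = ts + sample.int(40000, 1),
                 orientation = sample(c("+", "-"), 1),
                 stringsAsFactors = FALSE)
    }))
  }
  synteny_map("ref", targets, do.call(rbind, blocks),
              do.call(rbind, placements),
              resolution = sample(c(0, 10000, 150000), 1),
              chrom_order = c("chrA", "chrB"))
}

expect_same_map <- function(a, b) {
  expect_equal(a$reference, b$reference)
  expect_equal(a$targets, b$targets)
  expect_equal(a$resolution, b$resolution)
  norm_blocks <- function(m) {
    x <- m$blocks[order(m$blocks$block_id), ]
    rownames(x) <- NULL
    x$block_id <- as.numeric(x$block_id)
    x
  }
  norm_pl <- function(m) {
    x <- m$placements[order(m$placements$block_id, m$placements$target), ]
    rownames(x) <- NULL
    x$block_id <- as.numeric(x$block_id)
    x
  }
  expect_equal(norm_blocks(a), norm_blocks(b))
  expect_equal(norm_pl(a), norm_pl(b))
}

# independent brute-force chaining oracle: enumerate every partition of the
# (already sorted) anchors into consecutive internally-chainable segments
# and pick the greedy-leftmost one (longest first segment, then recurse).
oracle_pair_ok <- function(a, i, j, params) {
  # may anchor j directly follow anchor i in a run?
  if (a$ref_chrom[j] != a$ref_chrom[i]) return(FALSE)
  if (a$tgt_chrom[j] != a$tgt_chrom[i]) return(FALSE)
  if (a$orientation[j] != a$orientation[i]) return(FALSE)
  if (a$ref_start[j] <= a$ref_start[i]) return(FALSE)
  rg <- a$ref_start[j] - a$ref_end[i]
  if (rg < -params$min_anchor || rg > params$max_gap) return(FALSE)
  if (a$orientation[j] == "+") {
    if (a$tgt_start[j] <= a$tgt_start[i]) return(FALSE)
    tg <- a$tgt_start[j] - a$tgt_end[i]
  } else {
    if (a$tgt_start[j] >= a$tgt_start[i]) return(FALSE)
    tg <- a$tgt_start[i] - a$tgt_end[j]
  }
  tg >= -params$min_anchor && tg <= params$max_gap
}

# exhaustive oracle: lists every partition of the sorted anchors into
# consecutive valid segments, then selects the greedy-leftmost one
# (lexicographically largest sequence of segment end positions).
oracle_chain_enum <- function(a, params) {
  n <- nrow(a)
  if (n == 0) return(integer(0))
  valid_seg <- function(i, j) {
    if (i == j) return(TRUE)
    all(vapply(i:(j - 1L), function(k) oracle_pair_ok(a, k, k + 1L, params),
               TRUE))
  }
  parts <- list()
  recurse <- function(start, acc) {
    if (start > n) { parts[[length(parts) + 1L]] <<- acc; return() }
    for (end in start:n) {
      if (valid_seg(start, end)) recurse(end + 1L, c(acc, end))
    }
  }
  recurse(1L, integer(0))
  # greedy-leftmost: lexicographically largest sequence of segment ends
  best <- parts[[1]]
  for (p in parts[-1]) {
    k <- min(length(p), length(best))
    cmp <- which(p[1:k] != best[1:k])
    if (length(cmp) && p[cmp[1]] > best[cmp[1]]) best <- p
  }
  run_id <- integer(n)
  s <- 1L
  for (r in seq_along(best)) {
    run_id[s:best[r]] <- r
    s <- best[r] + 1L
  }
  run_id
}

random_anchor_set <- function(seed, n_max = 12) {
  set.seed(seed)
  n <- sample.int(n_max, 1)
  pos <- cumsum(sample.int(800, n)) # increasing, gaps 1..800
  len <- sample(50:400, n, replace = TRUE)
  a <- anchor_table(
    ref_chrom = sample(c("c1", "c1", "c2"), n, replace = TRUE),
    ref_start = pos, ref_end = pos + len,
    tgt_chrom = sample(c("x", "y"), n, replace = TRUE),
    tgt_start = (ts <- sample.int(5000, n)), tgt_end = ts + len,
    orientation = sample(c("+", "-"), n, replace = TRUE)
  )
  filter_anchors(a, build_params(100, 500, min_anchor = 0))
}

# exhaustive longest strictly-monotone subsequence (for order-break oracle)
oracle_lims <- function(x) {
  n <- length(x)
  if (n == 0) return(0L)
  best <- 1L
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k, simplify = FALSE)
    for (s in combos) {
      v <- x[s]
      if (all(diff(v) > 0) || all(diff(v) < 0)) { best <- k; break }
    }
  }
  best
}

# standard 5x2Mb genome + 20 mixed ops used by several recovery tests
recovery_fixture <- function(seed, jitter_sd = 0, spurious_rate = 0,
                             drop_rate = 0, min_anchor = 100) {
  rk <- simulate_karyotype(5, c(1.8e6, 2.2e6), seed = seed)
  truth <- simulate_rearrangements(
    rk, n_ops = 20, seed = seed,
    kinds = c("inversion", "translocation", "fission", "fusion"))
  anchors <- anchors_from_truth(truth, anchor_len_mean = 20000,
                                gap_mean = 2000, jitter_sd = jitter_sd,
                                spurious_rate = spurious_rate,
                                drop_rate = drop_rate, seed = seed + 1000)
  params <- build_params(50000, 10000, min_anchor = min_anchor)
  built <- build_pairwise(anchors, "ref", "tgt", params, ref_karyotype = rk)
  list(karyotype = rk, truth = truth, anchors = anchors, params = params,
       built = built)
}

# parse an SVG string and strip the namespace so plain XPaths work
read_svg <- function(svg) xml2::xml_ns_strip(xml2::read_xml(svg))
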