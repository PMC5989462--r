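test_that("filter_anchors drops short anchors and sorts deterministically", {
  a <- anchor_table(c("c1", "c1", "c1"), c(50, 10, 10), c(120, 300, 200),
                    "x", c(0, 400, 800), c(70, 690, 990), "+")
  p <- build_params(100, 1000, min_anchor = 100)
  out <- filter_anchors(a, p)
  expect_equal(nrow(out), 2) # the 70 bp anchor is below min_anchor
  # ties on ref start broken by larger ref end first
  expect_equal(out$ref_end, c(300, 200))
  p0 <- build_params(100, 1000, min_anchor = 0)
  expect_equal(nrow(filter_anchors(a, p0)), 3)
})

test_that("chaining joins collinear anchors and splits on chrom/orientation", {
  p <- build_params(200, 1000, min_anchor = 100)
  a <- anchor_table(c("chr1", "chr1"), c(100, 250), c(200, 350),
                    c("X", "X"), c(1000, 1150), c(1100, 1250), "+")
  ch <- chain_anchors(filter_anchors(a, p), p)
  expect_equal(ch$run_id, c(1L, 1L))
  a2 <- a; a2$tgt_chrom[2] <- "Y"
  ch2 <- chain_anchors(filter_anchors(a2, p), p)
  expect_equal(ch2$run_id, c(1L, 2L))
  a3 <- a; a3$orientation[2] <- "-"
  ch3 <- chain_anchors(filter_anchors(a3, p), p)
  expect_equal(ch3$run_id, c(1L, 2L))
})

test_that("minus-strand runs require the target to move backwards", {
  p <- build_params(100, 1000, min_anchor = 100)
  # backward-moving target: chains
  a <- anchor_table(c("c", "c"), c(0, 200), c(100, 300),
                    c("x", "x"), c(2000, 1800), c(2100, 1900), "-")
  expect_equal(chain_anchors(filter_anchors(a, p), p)$run_id, c(1L, 1L))
  # forward-moving target with '-' orientation: must split
  a2 <- anchor_table(c("c", "c"), c(0, 200), c(100, 300),
                     c("x", "x"), c(1800, 2000), c(1900, 2100), "-")
  expect_equal(chain_anchors(filter_anchors(a2, p), p)$run_id, c(1L, 2L))
})

test_that("runs_to_blocks spans runs and applies the resolution filter", {
  a <- anchor_table(c("chr1", "chr1"), c(100, 250), c(200, 350),
                    c("X", "X"), c(1000, 1150), c(1100, 1250), "+")
  p200 <- build_params(200, 1000, min_anchor = 100)
  blk <- runs_to_blocks(chain_anchors(filter_anchors(a, p200), p200), p200)
  expect_equal(nrow(blk), 1)
  expect_equal(blk$ref_start, 100)
  expect_equal(blk$ref_end, 350)
  expect_equal(blk$tgt_start, 1000)
  expect_equal(blk$tgt_end, 1250)
  p300 <- build_params(300, 1000, min_anchor = 100)
  blk2 <- runs_to_blocks(chain_anchors(filter_anchors(a, p300), p300), p300)
  expect_equal(nrow(blk2), 0) # 250 bp spans < resolution 300
  expect_equal(nrow(runs_to_blocks(chain_anchors(
    filter_anchors(a[0, ], p200), p200), p200)), 0)
})

test_that("greedy chaining equals the exhaustive partition oracle", {
  p <- build_params(100, 500, min_anchor = 0)
  for (seed in 1:200) {
    a <- random_anchor_set(seed)
    got <- chain_anchors(a, p)$run_id
    want <- oracle_chain_enum(a, p)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("overlap resolution trims the smaller block on the overlap side", {
  p <- build_params(100, 1000, min_anchor = 100)
  blk <- data.frame(block_id = 1:2, ref_chrom = "c",
                    ref_start = c(0, 400), ref_end = c(500, 1200),
                    tgt_chrom = c("x", "y"), tgt_start = c(0, 0),
                    tgt_end = c(500, 800), orientation = "+",
                    stringsAsFactors = FALSE)
  out <- resolve_overlaps(blk, p)
  expect_equal(out$ref_end[1], 400) # B1 is smaller: trimmed to [0,400)
  expect_equal(out$ref_start[2], 400)
  # disjoint blocks pass through unchanged
  blk2 <- blk; blk2$ref_start[2] <- 600
  expect_equal(resolve_overlaps(blk2, p)[, -1], blk2[, -1])
  # trim below resolution drops the block
  p300 <- build_params(300, 1000, min_anchor = 100)
  blk3 <- data.frame(block_id = 1:2, ref_chrom = "c",
                     ref_start = c(0, 100), ref_end = c(300, 450),
                     tgt_chrom = c("x", "y"), tgt_start = c(0, 0),
                     tgt_end = c(300, 350), orientation = "+",
                     stringsAsFactors = FALSE)
  out3 <- resolve_overlaps(blk3, p300)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$ref_start, 100)
})

test_that("resolved blocks are always pairwise disjoint on both genomes", {
  p <- build_params(50, 500, min_anchor = 0)
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample.int(8, 1)
    s <- sample.int(2000, n)
    blk <- data.frame(block_id = seq_len(n),
                      ref_chrom = sample(c("c1", "c2"), n, replace = TRUE),
                      ref_start = s, ref_end = s + sample(50:800, n, TRUE),
                      tgt_chrom = sample(c("x", "y"), n, replace = TRUE),
                      tgt_start = (t0 <- sample.int(2000, n)),
                      tgt_end = t0 + sample(50:800, n, TRUE),
                      orientation = sample(c("+", "-"), n, TRUE),
                      stringsAsFactors = FALSE)
    out <- resolve_overlaps(blk, p)
    for (cols in list(c("ref_chrom", "ref_start", "ref_end"),
                      c("tgt_chrom", "tgt_start", "tgt_end"))) {
      for (cc in unique(out[[cols[1]]])) {
        k <- out[out[[cols[1]]] == cc, , drop = FALSE]
        k <- k[order(k[[cols[2]]]), , drop = FALSE]
        if (nrow(k) > 1) {
          expect_true(all(k[[cols[2]]][-1] >= k[[cols[3]]][-nrow(k)]),
                      info = paste("seed", seed, cols[1]))
        }
      }
    }
    # size floor holds on both genomes
    expect_true(all(out$ref_end - out$ref_start >= p$resolution))
    expect_true(all(out$tgt_end - out$tgt_start >= p$resolution))
  }
})

test_that("build_pairwise recovers a planted decomposition exactly", {
  rk <- simulate_karyotype(3, c(1e6, 1.4e6), seed = 11)
  truth <- simulate_rearrangements(rk, n_ops = 5, seed = 11)
  a <- anchors_from_truth(truth, 20000, 2000, seed = 11)
  p <- build_params(50000, 10000)
  built <- build_pairwise(a, "ref", "tgt", p, ref_karyotype = rk)
  pairwise_blocks_df <- function(m) {
    b <- m$blocks
    p <- m$placements[order(m$placements$block_id), ]
    cbind(b[, c("ref_chrom", "ref_start", "ref_end")],
          p[, c("tgt_chrom", "tgt_start", "tgt_end", "orientation")])
  }
  expect_equal(pairwise_blocks_df(built), pairwise_blocks_df(truth$map))
  # anchors below min_anchor produce an empty map
  p_big <- build_params(50000, 50000, min_anchor = 50000)
  expect_equal(nrow(build_pairwise(a, "ref", "tgt", p_big,
                                   ref_karyotype = rk)$blocks), 0)
  # duplicating every anchor changes nothing
  built2 <- build_pairwise(rbind(a, a), "ref", "tgt", p, ref_karyotype = rk)
  expect_equal(pairwise_blocks_df(built2), pairwise_blocks_df(built))
})

test_that("every block lies within the union of its anchors' reference span", {
  fx <- recovery_fixture(3)
  a <- fx$anchors; built <- fx$built
  for (i in seq_len(nrow(built$blocks))) {
    b <- built$blocks[i, ]
    k <- a[a$ref_chrom == b$ref_chrom, ]
    expect_gte(b$ref_start, min(k$ref_start))
    expect_lte(b$ref_end, max(k$ref_end))
  }
})

test_that("intersect_maps keeps segments covered in every pairwise map", {
  mk <- function(target, s, e) {
    synteny_map("ref", target,
                data.frame(block_id = 1, ref_chrom = "c", ref_start = s,
                           ref_end = e),
                data.frame(block_id = 1, target = target, tgt_chrom = "x",
                           tgt_start = s, tgt_end = e, orientation = "+"),
                resolution = 300)
  }
  p <- build_params(300, 300)
  # identical single-block maps: identity partition
  multi <- intersect_maps(list(mk("t1", 0, 1000), mk("t2", 0, 1000)), p)
  expect_equal(nrow(multi$blocks), 1)
  expect_equal(multi$blocks$ref_start, 0)
  expect_equal(multi$blocks$ref_end, 1000)
  expect_equal(sort(multi$placements$target), c("t1", "t2"))
  # offset blocks: only the jointly covered part survives
  multi2 <- intersect_maps(list(mk("t1", 0, 1000), mk("t2", 500, 1500)), p)
  expect_equal(nrow(multi2$blocks), 1)
  expect_equal(multi2$blocks$ref_start, 500)
  expect_equal(multi2$blocks$ref_end, 1000)
  # jointly covered part below the resolution: empty result
  multi3 <- intersect_maps(list(mk("t1", 0, 1000), mk("t2", 800, 1500)), p)
  expect_equal(nrow(multi3$blocks), 0)
  expect_error(intersect_maps(list(mk("t1", 0, 1000), {
    m <- mk("t2", 0, 1000); m$reference <- "other"; m
  }), p), "reference")
})

test_that("intersection crops inverted placements from the far end", {
  b <- data.frame(block_id = 1, ref_chrom = "c", ref_start = 0,
                  ref_end = 1000)
  pl <- data.frame(block_id = 1, target = "t1", tgt_chrom = "x",
                   tgt_start = 5000, tgt_end = 6000, orientation = "-")
  m1 <- synteny_map("ref", "t1", b, pl, resolution = 100)
  m2 <- synteny_map("ref", "t2",
                    data.frame(block_id = 1, ref_chrom = "c",
                               ref_start = 400, ref_end = 1000),
                    data.frame(block_id = 1, target = "t2", tgt_chrom = "y",
                               tgt_start = 0, tgt_end = 600,
                               orientation = "+"), resolution = 100)
  multi <- intersect_maps(list(m1, m2), build_params(100, 100))
  expect_equal(multi$blocks$ref_start, 400)
  p1 <- multi$placements[multi$placements$target == "t1", ]
  # reference [400,1000) of an inverted [0,1000)->[5000,6000) placement
  # maps to target [5000, 5600)
  expect_equal(p1$tgt_start, 5000)
  expect_equal(p1$tgt_end, 5600)
})

test_that("coverage is non-increasing in resolution", {
  fx <- recovery_fixture(5)
  prev <- Inf
  for (res in c(10000, 50000, 100000, 200000)) {
    p <- build_params(res, 10000)
    m <- build_pairwise(fx$anchors, "ref", "tgt", p,
                        ref_karyotype = fx$karyotype)
    cov <- sum(m$blocks$ref_end - m$blocks$ref_start)
    expect_lte(cov, prev)
    prev <- cov
  }
})

test_that("identical inputs give byte-identical unified output", {
  fx1 <- recovery_fixture(9)
  fx2 <- recovery_fixture(9)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_unified(fx1$built, f1)
  write_unified(fx2$built, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
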