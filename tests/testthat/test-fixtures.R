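test_that("simulate_karyotype is reproducible and respects ranges", {
  k <- simulate_karyotype(1, c(1000, 1000), seed = 7)
  expect_equal(k$chrom, "chr1")
  expect_equal(k$length, 1000)
  k1 <- simulate_karyotype(5, c(1e6, 3e6), seed = 1)
  k2 <- simulate_karyotype(5, c(1e6, 3e6), seed = 1)
  expect_identical(k1, k2)
  expect_true(all(k1$length >= 1e6 & k1$length <= 3e6))
  expect_error(simulate_karyotype(0, c(10, 20)), "n_chroms")
  expect_error(simulate_karyotype(2, c(30, 20)), "length_range")
})

test_that("zero operations give one identity block per chromosome", {
  rk <- simulate_karyotype(3, c(5e5, 8e5), seed = 2)
  truth <- simulate_rearrangements(rk, ops = list(), seed = 2)
  b <- truth$map$blocks
  expect_equal(nrow(b), 3)
  expect_equal(b$ref_start, c(0, 0, 0))
  expect_equal(b$ref_end, rk$length)
  expect_equal(truth$map$placements$orientation, rep("+", 3))
  expect_equal(truth$map$placements$tgt_start, c(0, 0, 0))
  expect_equal(truth$tgt_karyotype$length, rk$length)
})

test_that("one inversion yields three blocks with an inverted middle", {
  rk <- karyotype("chr1", 1e6, genome = "ref")
  truth <- simulate_rearrangements(
    rk, ops = list(list(kind = "inversion", chrom = 1, start = 3e5,
                        end = 7e5)), seed = 1)
  b <- truth$map$blocks
  p <- truth$map$placements
  expect_equal(nrow(b), 3)
  expect_equal(b$ref_start, c(0, 3e5, 7e5))
  expect_equal(b$ref_end, c(3e5, 7e5, 1e6))
  expect_equal(p$orientation, c("+", "-", "+"))
  # inverted middle keeps its target interval (forward-strand storage)
  expect_equal(p$tgt_start, c(0, 3e5, 7e5))
})

test_that("a reciprocal translocation connects each side to two chromosomes", {
  rk <- karyotype(c("chr1", "chr2"), c(1e6, 8e5), genome = "ref")
  truth <- simulate_rearrangements(
    rk, ops = list(list(kind = "translocation", chrom1 = 1, pos1 = 4e5,
                        chrom2 = 2, pos2 = 3e5)), seed = 1)
  expect_equal(connectivity(truth$map, "chr1", "tgt"),
               c("tchr1", "tchr2"))
  expect_equal(connectivity(truth$map, "chr2", "tgt"),
               c("tchr1", "tchr2"))
  expect_equal(truth$tgt_karyotype$length, c(4e5 + 5e5, 3e5 + 6e5))
})

test_that("fission and fusion edit the target karyotype", {
  rk <- karyotype(c("chr1", "chr2"), c(1e6, 8e5), genome = "ref")
  t1 <- simulate_rearrangements(
    rk, ops = list(list(kind = "fission", chrom = 1, pos = 250000)),
    seed = 1)
  expect_equal(nrow(t1$tgt_karyotype), 3)
  t2 <- simulate_rearrangements(
    rk, ops = list(list(kind = "fusion", chrom1 = 1, chrom2 = 2)),
    seed = 1)
  expect_equal(nrow(t2$tgt_karyotype), 1)
  expect_equal(t2$tgt_karyotype$length, 1.8e6)
  expect_equal(connectivity(t2$map, "chr1", "tgt"), "tchr1")
})

test_that("breakpoints outside the chromosome are rejected", {
  rk <- karyotype("chr1", 1e6, genome = "ref")
  expect_error(simulate_rearrangements(
    rk, ops = list(list(kind = "fission", chrom = 1, pos = 2e6)),
    seed = 1), "outside chromosome")
})

test_that("operations conserve total bp for random op sequences", {
  for (seed in 1:10) {
    rk <- simulate_karyotype(4, c(8e5, 1.2e6), seed = seed)
    truth <- simulate_rearrangements(rk, n_ops = 8, seed = seed)
    b <- truth$map$blocks
    expect_equal(sum(b$ref_end - b$ref_start), sum(rk$length))
    expect_equal(sum(truth$tgt_karyotype$length), sum(rk$length))
    # placements tile each target chromosome exactly
    p <- truth$map$placements
    for (tc in truth$tgt_karyotype$chrom) {
      k <- p[p$tgt_chrom == tc, ]
      k <- k[order(k$tgt_start), ]
      expect_equal(k$tgt_start[1], 0)
      expect_equal(k$tgt_end[nrow(k)],
                   truth$tgt_karyotype$length[
                     match(tc, truth$tgt_karyotype$chrom)])
      if (nrow(k) > 1) {
        expect_equal(k$tgt_start[-1], k$tgt_end[-nrow(k)])
      }
    }
  }
})

test_that("noise-free anchors lie inside exactly one truth block", {
  rk <- simulate_karyotype(3, c(1e6, 1.5e6), seed = 21)
  truth <- simulate_rearrangements(rk, n_ops = 6, seed = 21)
  a <- anchors_from_truth(truth, 20000, 2000, seed = 21)
  tb <- pairwise_blocks(truth$map, "tgt")
  for (i in seq_len(nrow(a))) {
    hits <- sum(tb$ref_chrom == a$ref_chrom[i] &
                  tb$ref_start <= a$ref_start[i] &
                  tb$ref_end >= a$ref_end[i])
    expect_equal(hits, 1)
  }
  # determinism
  a2 <- anchors_from_truth(truth, 20000, 2000, seed = 21)
  expect_identical(a, a2)
})

test_that("drop_rate 1 empties the anchor set", {
  rk <- simulate_karyotype(2, c(5e5, 5e5), seed = 3)
  truth <- simulate_rearrangements(rk, ops = list(), seed = 3)
  a <- anchors_from_truth(truth, 20000, 2000, drop_rate = 1, seed = 3)
  expect_equal(nrow(a), 0)
})

test_that("end-to-end: noise-free anchors rebuild the truth exactly", {
  fx <- recovery_fixture(17)
  tb <- pairwise_blocks(fx$truth$map, "tgt")
  bb <- pairwise_blocks(fx$built, "tgt")
  expect_equal(bb[, -1], tb[, -1], ignore_attr = TRUE)
})

test_that("planted genes classify exactly as intended", {
  rk <- simulate_karyotype(4, c(1.5e6, 2e6), seed = 31)
  truth <- simulate_rearrangements(rk, n_ops = 10, seed = 31)
  n_blocks <- nrow(truth$map$blocks)
  masked <- truth$map$blocks$block_id[c(2, n_blocks - 1)]
  genes <- genes_from_truth(truth, n_per_class = 4, seed = 31,
                            masked_blocks = masked)
  a <- anchors_from_truth(truth, 20000, 2000, seed = 31,
                          exclude_blocks = masked)
  built <- build_pairwise(a, "ref", "tgt", build_params(50000, 10000),
                          ref_karyotype = rk)
  got <- classify_genes(gene_table(genes$chrom, genes$start, genes$end,
                                   genes$name, genes$strand),
                        built, "tgt")
  expect_equal(got$class, genes$intended_class)
  # confusion matrix is diagonal
  tab <- table(intended = genes$intended_class, got = got$class)
  expect_true(all(tab[row(tab) != col(tab)] == 0))
  # the planted three-block spanner reports three blocks
  spanner <- got[got$name == "SPAN3", ]
  expect_equal(nrow(spanner), 1)
  expect_equal(spanner$n_blocks, 3L)
  expect_equal(nrow(genes_from_truth(truth, 0, seed = 1)), 0)
})

test_that("unplaced genes require masked blocks", {
  rk <- simulate_karyotype(2, c(1e6, 1e6), seed = 5)
  truth <- simulate_rearrangements(rk, n_ops = 3, seed = 5)
  expect_error(genes_from_truth(truth, 2, seed = 5), "masked")
})

test_that("fixture outputs round-trip through the io formats", {
  rk <- simulate_karyotype(3, c(1e6, 1.5e6), seed = 41)
  truth <- simulate_rearrangements(rk, n_ops = 5, seed = 41)
  a <- anchors_from_truth(truth, 20000, 2000, seed = 41)
  d <- withr::local_tempdir()
  write_chrom_sizes(truth$ref_karyotype, file.path(d, "ref.sizes"))
  write_chrom_sizes(truth$tgt_karyotype, file.path(d, "tgt.sizes"))
  write_anchors_tsv(a, file.path(d, "anchors.tsv"))
  write_unified(truth$map, file.path(d, "truth.txt"))
  expect_equal(read_chrom_sizes(file.path(d, "ref.sizes"), "ref")$length,
               truth$ref_karyotype$length)
  expect_equal(read_anchors_tsv(file.path(d, "anchors.tsv")), a)
  expect_same_map(read_unified(file.path(d, "truth.txt")), truth$map)
})
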