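mk_map <- function(tgt_chroms, orientations, tgt_starts,
                   ref_chrom = "chr2", span = 1000) {
  n <- length(tgt_chroms)
  b <- data.frame(block_id = seq_len(n), ref_chrom = ref_chrom,
                  ref_start = (seq_len(n) - 1) * 2000,
                  ref_end = (seq_len(n) - 1) * 2000 + span)
  p <- data.frame(block_id = seq_len(n), target = "mm",
                  tgt_chrom = tgt_chroms, tgt_start = tgt_starts,
                  tgt_end = tgt_starts + span, orientation = orientations)
  synteny_map("hg", "mm", b, p, resolution = 100)
}

test_that("connectivity returns the distinct partner chromosomes", {
  m <- mk_map(c("mA", "mB", "mA"), c("+", "+", "+"), c(0, 0, 5000))
  expect_equal(connectivity(m, "chr2", "mm"), c("mA", "mB"))
  expect_error(connectivity(m, "chr99", "mm"), "unknown reference")
  expect_error(connectivity(m, "chr2", "rat"), "unknown target")
})

test_that("chromosomes with no blocks have empty connectivity", {
  m <- mk_map("mA", "+", 0)
  m$chrom_order <- c("chr2", "chr3")
  expect_equal(connectivity(m, "chr3", "mm"), character(0))
})

test_that("chromosome classification separates collinear/intra/inter", {
  collinear <- mk_map(c("mA", "mA", "mA"), c("+", "+", "+"),
                      c(0, 2000, 4000))
  r <- classify_chromosome(collinear, "chr2", "mm")
  expect_equal(r$class, "collinear")
  expect_equal(r$n_order_breaking, 0L)
  inv <- mk_map(c("mA", "mA", "mA"), c("+", "-", "+"), c(0, 2000, 4000))
  r2 <- classify_chromosome(inv, "chr2", "mm")
  expect_equal(r2$class, "intra_only")
  expect_equal(r2$n_inverted, 1L)
  inter <- mk_map(c("mA", "mB"), c("+", "+"), c(0, 0))
  expect_equal(classify_chromosome(inter, "chr2", "mm")$class, "inter")
  # scrambled target order on one partner: order-breaking, intra class
  scram <- mk_map(c("mA", "mA", "mA"), c("+", "+", "+"),
                  c(4000, 0, 2000))
  r3 <- classify_chromosome(scram, "chr2", "mm")
  expect_equal(r3$class, "intra_only")
  expect_equal(r3$n_order_breaking, 1L)
})

test_that("order-breaking counts agree with the exhaustive subsequence oracle", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample.int(9, 1)
    starts <- sample.int(1e5, n)
    m <- mk_map(rep("mA", n), rep("+", n), starts)
    got <- classify_chromosome(m, "chr2", "mm")$n_order_breaking
    mids <- starts[order(m$blocks$ref_start)] + 500
    # placements keep block order; ref order is construction order here
    expect_equal(got, as.integer(n - oracle_lims(starts + 500)),
                 info = paste("seed", seed))
  }
})

test_that("gene classification covers conserved, broken and unplaced", {
  m <- mk_map(c("mA", "mA"), c("+", "+"), c(0, 2000), span = 1000)
  # blocks: [0,1000) and [2000,3000)
  g <- gene_table(c("chr2", "chr2", "chr2", "chr2"),
                  c(100, 900, 1200, 950),
                  c(300, 2100, 1800, 1000),
                  c("IN", "ACROSS", "BETWEEN", "EDGE"),
                  c("+", "-", "+", "-"))
  r <- classify_genes(g, m, "mm")
  expect_equal(r$class, c("conserved", "broken", "unplaced", "conserved"))
  expect_equal(r$n_blocks, c(1L, 2L, 0L, 1L))
  expect_false(r$partial[1])
  # partition property: each gene has exactly one class
  expect_equal(sum(r$class %in% c("conserved", "broken", "unplaced")),
               nrow(g))
})

test_that("a gene partially overlapping one block is conserved+partial", {
  m <- mk_map("mA", "+", 0, span = 1000)
  g <- gene_table("chr2", 900, 1500, "HALF", "+")
  r <- classify_genes(g, m, "mm")
  expect_equal(r$class, "conserved")
  expect_true(r$partial)
})

test_that("connectivity equals the partner set of the chromosome report", {
  fx <- recovery_fixture(13)
  m <- fx$built
  for (cc in m$chrom_order) {
    rep <- classify_chromosome(m, cc, "tgt")
    conn <- connectivity(m, cc, "tgt")
    expect_equal(rep$partner_chroms, paste(conn, collapse = ","))
  }
})

test_that("coverage_summary sums disjoint block spans", {
  k <- karyotype("chr2", 1000, genome = "hg")
  m <- mk_map("mA", "+", 0, span = 500)
  m$blocks$ref_end <- 500
  m$placements$tgt_end <- 500
  cov <- coverage_summary(m, k)
  expect_equal(cov$covered_bp, c(500, 500))
  expect_equal(cov$fraction, c(0.5, 0.5))
  expect_equal(cov$chrom, c("chr2", "TOTAL"))
  m2 <- mk_map(c("mA", "mA"), c("+", "+"), c(0, 2000), span = 250)
  cov2 <- coverage_summary(m2, k)
  expect_equal(cov2$covered_bp[2], 500)
  expect_error(coverage_summary(mk_map("mA", "+", 0, ref_chrom = "chrZ"),
                                k), "absent")
})

test_that("empty maps give zero coverage everywhere", {
  k <- karyotype(c("c1", "c2"), c(1000, 2000), genome = "hg")
  m <- synteny_map("hg", "mm", data.frame(), data.frame())
  cov <- coverage_summary(m, k)
  expect_equal(cov$covered_bp, c(0, 0, 0))
})

test_that("reports serialize as deterministic TSV", {
  fx <- recovery_fixture(13)
  rep <- rearrangement_report(fx$built)
  f <- withr::local_tempfile()
  write_report_tsv(rep, f)
  txt <- readLines(f)
  expect_equal(txt[1], paste(names(rep), collapse = "\t"))
  expect_equal(length(txt), nrow(rep) + 1)
})
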