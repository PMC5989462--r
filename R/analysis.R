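# Block-based rearrangement and gene analyses.
#
# A reference chromosome is classified per target as:
#   inter      -- its blocks land on >= 2 target chromosomes
#                 (translocation / fission / fusion signature),
#   intra_only -- one partner chromosome but inversions or order changes,
#   collinear  -- one partner chromosome, no inversion, no order break,
#   none       -- no blocks for that target.
# Order breaking is quantified as the number of blocks outside one maximal
# collinear order: n_blocks minus the longest strictly increasing OR
# strictly decreasing subsequence (the better of the two) of block target
# midpoints, summed over partner chromosomes.

# longest strictly monotone subsequence length; O(n^2), n is block count
lims_len <- function(x) {
  n <- length(x)
  if (n <= 1L) return(n)
  best <- function(v) {
    d <- rep(1L, n)
    for (i in seq_len(n)[-1]) {
      for (j in seq_len(i - 1L)) {
        if (v[j] < v[i] && d[j] + 1L > d[i]) d[i] <- d[j] + 1L
      }
    }
    max(d)
  }
  max(best(x), best(-x))
}

#' Target chromosomes connected to a reference chromosome
#'
#' @param map A [synteny_map()].
#' @param ref_chrom Reference chromosome name.
#' @param target Target genome name.
#' @return Character vector of distinct target chromosomes receiving at
#'   least one block from `ref_chrom` (sorted for determinism).
#' @export
connectivity <- function(map, ref_chrom, target) {
  if (!ref_chrom %in% map$chrom_order &&
      !ref_chrom %in% map$blocks$ref_chrom) {
    stop("unknown reference chromosome: ", ref_chrom)
  }
  pw <- pairwise_blocks(map, target)
  sort(unique(pw$tgt_chrom[pw$ref_chrom == ref_chrom]))
}

#' Classify the rearrangement state of one reference chromosome
#'
#' @inheritParams connectivity
#' @return One-row data frame: `ref_chrom`, `target`, `partner_chroms`
#'   (comma-separated), `n_blocks`, `n_inverted`, `n_order_breaking`,
#'   `class`.
#' @export
classify_chromosome <- function(map, ref_chrom, target) {
  partners <- connectivity(map, ref_chrom, target)
  pw <- pairwise_blocks(map, target)
  pw <- pw[pw$ref_chrom == ref_chrom, , drop = FALSE]
  n_blocks <- nrow(pw)
  n_inverted <- sum(pw$orientation == "-")
  n_ob <- 0L
  for (tc in partners) {
    k <- pw[pw$tgt_chrom == tc, , drop = FALSE] # already in ref order
    mid <- (k$tgt_start + k$tgt_end) / 2
    n_ob <- n_ob + nrow(k) - lims_len(mid)
  }
  cls <- if (n_blocks == 0L) "none"
  else if (length(partners) >= 2L) "inter"
  else if (n_inverted == 0L && n_ob == 0L) "collinear"
  else "intra_only"
  data.frame(ref_chrom = ref_chrom, target = target,
             partner_chroms = paste(partners, collapse = ","),
             n_blocks = n_blocks, n_inverted = n_inverted,
             n_order_breaking = as.integer(n_ob), class = cls,
             stringsAsFactors = FALSE)
}

#' Rearrangement report for all reference chromosomes
#'
#' @param map A [synteny_map()].
#' @param targets Target genomes (default: all in the map).
#' @return Data frame with one row per (reference chromosome, target), in
#'   karyotype order; columns as in [classify_chromosome()].
#' @export
rearrangement_report <- function(map, targets = map$targets) {
  rows <- list()
  for (t in targets) {
    for (cc in map$chrom_order) {
      rows[[length(rows) + 1L]] <- classify_chromosome(map, cc, t)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify genes by their relationship to synteny blocks
#'
#' Each reference gene is intersected with the blocks of the pairwise
#' projection of the map onto one target:
#' * `conserved` -- overlaps exactly 1 block (`partial = TRUE` when not
#'   fully contained in it),
#' * `broken` -- overlaps >= 2 blocks (a rearrangement breakpoint falls
#'   inside the gene),
#' * `unplaced` -- overlaps no block (reference-specific region).
#'
#' A gene may therefore be broken against one target and conserved against
#' another; classify per target of interest.
#'
#' @param genes A [gene_table()] on reference coordinates.
#' @param map A [synteny_map()].
#' @param target Target genome name.
#' @return Data frame: gene columns plus `n_blocks`, `class`, `partial`.
#' @export
classify_genes <- function(genes, map, target) {
  pw <- pairwise_blocks(map, target)
  n <- nrow(genes)
  n_blocks <- integer(n); partial <- logical(n)
  for (i in seq_len(n)) {
    k <- pw[pw$ref_chrom == genes$chrom[i] &
              pw$ref_start < genes$end[i] &
              pw$ref_end > genes$start[i], , drop = FALSE]
    n_blocks[i] <- nrow(k)
    partial[i] <- nrow(k) == 1L &&
      !(k$ref_start <= genes$start[i] && k$ref_end >= genes$end[i])
  }
  cls <- ifelse(n_blocks == 0L, "unplaced",
                ifelse(n_blocks == 1L, "conserved", "broken"))
  out <- cbind(as.data.frame(genes),
               data.frame(n_blocks = n_blocks, class = cls,
                          partial = partial, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Reference coverage of a synteny map
#'
#' @param map A [synteny_map()].
#' @param karyotype Reference [karyotype()]; every chromosome carrying
#'   blocks must be present.
#' @return Data frame with one row per chromosome plus a final `TOTAL` row:
#'   `chrom`, `length`, `covered_bp`, `fraction`.
#' @export
coverage_summary <- function(map, karyotype) {
  b <- map$blocks
  extra <- setdiff(unique(b$ref_chrom), karyotype$chrom)
  if (length(extra)) {
    stop("map chromosome(s) absent from karyotype: ",
         paste(extra, collapse = ", "))
  }
  cov <- vapply(karyotype$chrom, function(cc) {
    k <- b[b$ref_chrom == cc, , drop = FALSE]
    sum(k$ref_end - k$ref_start) # blocks are disjoint by invariant
  }, 0)
  out <- data.frame(chrom = karyotype$chrom, length = karyotype$length,
                    covered_bp = unname(cov),
                    fraction = unname(cov) / karyotype$length,
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(chrom = "TOTAL", length = sum(out$length),
                               covered_bp = sum(out$covered_bp),
                               fraction = sum(out$covered_bp) /
                                 sum(out$length),
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Write an analysis report as TSV
#'
#' Fixed column order, no quoting, no row names: deterministic output
#' suitable for diffing between builds.
#'
#' @param report A data frame from [rearrangement_report()],
#'   [classify_genes()] or [coverage_summary()].
#' @param path Output path.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
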