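# UCSC chain format reader.
#
# A chain describes one gapped pairwise alignment as a header line
#   chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id
# followed by data lines "size [dt dq]" (the last line has only "size").
# "t" is the reference genome here, "q" the target.  tStrand is always "+";
# when qStrand is "-", query coordinates count from the start of the
# *reversed* query chromosome and are converted back to forward-strand
# coordinates (forward_start = qSize - reverse_end).  Each ungapped block
# becomes one anchor carrying the chain's score and orientation.

#' Read pairwise alignment anchors from a UCSC chain file
#'
#' @param path Chain file (plain text, possibly several chains).
#' @param tgt_karyotype Optional target [karyotype()]; when given, each
#'   chain's `qSize` is checked against it.
#' @return An [anchor_table()] with one anchor per ungapped block, target
#'   intervals on the forward strand, orientation `"-"` for reverse-strand
#'   chains.
#' @export
read_chain <- function(path, tgt_karyotype = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[!grepl("^#", lines)]
  i <- 1L
  n <- length(lines)
  acc <- vector("list", 64L); nacc <- 0L
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    h <- strsplit(lines[i], "\\s+")[[1]]
    if (h[1] != "chain" || length(h) < 12L) {
      stop("malformed chain header at line ", i, ": ", lines[i])
    }
    score <- as.numeric(h[2])
    t_name <- h[3]; t_size <- as.numeric(h[4]); t_strand <- h[5]
    t_start <- as.numeric(h[6]); t_end <- as.numeric(h[7])
    q_name <- h[8]; q_size <- as.numeric(h[9]); q_strand <- h[10]
    q_start <- as.numeric(h[11]); q_end <- as.numeric(h[12])
    if (anyNA(c(score, t_size, t_start, t_end, q_size, q_start, q_end))) {
      stop("non-numeric field in chain header at line ", i)
    }
    if (t_strand != "+") stop("chain tStrand must be '+' (line ", i, ")")
    if (!q_strand %in% c("+", "-")) stop("invalid qStrand in chain header")
    if (!is.null(tgt_karyotype)) {
      k <- match(q_name, tgt_karyotype$chrom)
      if (is.na(k)) stop("chain query chromosome '", q_name,
                         "' absent from target karyotype")
      if (tgt_karyotype$length[k] != q_size) {
        stop("qSize ", fmt_bp(q_size), " for '", q_name,
             "' does not match karyotype length ",
             fmt_bp(tgt_karyotype$length[k]))
      }
    }
    i <- i + 1L
    t_pos <- t_start; q_pos <- q_start
    repeat {
      if (i > n || !nzchar(lines[i])) break
      f <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (anyNA(f) || !length(f) %in% c(1L, 3L)) {
        stop("malformed chain data line ", i, ": ", lines[i])
      }
      size <- f[1]
      if (t_pos + size > t_end || q_pos + size > q_end) {
        stop("chain block arithmetic exceeds declared extent at line ", i)
      }
      if (q_strand == "+") {
        qs <- q_pos; qe <- q_pos + size
      } else {
        qs <- q_size - (q_pos + size); qe <- q_size - q_pos
      }
      nacc <- nacc + 1L
      if (nacc > length(acc)) acc <- c(acc, vector("list", length(acc)))
      acc[[nacc]] <- list(t_name, t_pos, t_pos + size, q_name, qs, qe,
                          q_strand, score)
      last <- length(f) == 1L
      if (last) { i <- i + 1L; break }
      t_pos <- t_pos + size + f[2]
      q_pos <- q_pos + size + f[3]
      i <- i + 1L
    }
  }
  acc <- acc[seq_len(nacc)]
  if (nacc == 0L) {
    return(anchor_table(character(), numeric(), numeric(), character(),
                        numeric(), numeric(), character(), numeric()))
  }
  anchor_table(
    ref_chrom = vapply(acc, `[[`, "", 1L),
    ref_start = vapply(acc, function(a) a[[2]], 0),
    ref_end = vapply(acc, function(a) a[[3]], 0),
    tgt_chrom = vapply(acc, `[[`, "", 4L),
    tgt_start = vapply(acc, function(a) a[[5]], 0),
    tgt_end = vapply(acc, function(a) a[[6]], 0),
    orientation = vapply(acc, `[[`, "", 7L),
    score = vapply(acc, function(a) a[[8]], 0)
  )
}

#' Write anchors as a minimal chain file (one chain per anchor)
#'
#' Mostly useful for generating test inputs; real chains group many blocks,
#' this writer emits one single-block chain per anchor.
#'
#' @param anchors An [anchor_table()].
#' @param ref_karyotype,tgt_karyotype Karyotypes supplying tSize/qSize.
#' @param path Output path.
#' @export
write_chain <- function(anchors, ref_karyotype, tgt_karyotype, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    t_size <- ref_karyotype$length[match(a$ref_chrom, ref_karyotype$chrom)]
    q_size <- tgt_karyotype$length[match(a$tgt_chrom, tgt_karyotype$chrom)]
    if (is.na(t_size) || is.na(q_size)) {
      stop("anchor chromosome missing from karyotype")
    }
    size <- a$ref_end - a$ref_start
    if (a$orientation == "+") {
      qs <- a$tgt_start; qe <- a$tgt_end
    } else {
      qs <- q_size - a$tgt_end; qe <- q_size - a$tgt_start
    }
    writeLines(c(sprintf("chain %g %s %s + %s %s %s %s %s %s %s %d",
                         a$score, a$ref_chrom, fmt_bp(t_size),
                         fmt_bp(a$ref_start), fmt_bp(a$ref_end),
                         a$tgt_chrom, fmt_bp(q_size), a$orientation,
                         fmt_bp(qs), fmt_bp(qe), i),
                 fmt_bp(size), ""), con)
  }
  invisible(path)
}
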