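# Independent brute-force oracles. These deliberately avoid the package's
# CIGAR/block machinery: the CIGAR is stepped base by base and junction
# support is decided by per-base containment.

# Reference positions covered by an alignment; D consumes and covers
# reference, N consumes but does not cover, I/S/H/P consume none.
oracle_covered_positions <- function(pos, cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  covered <- integer(0)
  cur <- pos
  for (tk in toks) {
    n <- as.integer(substr(tk, 1, nchar(tk) - 1L))
    op <- substr(tk, nchar(tk), nchar(tk))
    if (op %in% c("M", "=", "X", "D")) {
      covered <- c(covered, seq.int(cur, length.out = n))
      cur <- cur + n
    } else if (op == "N") {
      cur <- cur + n
    }
  }
  covered
}

# TRUE iff every base in [j - mf + 1, j + mf] is covered (equivalent to a
# single gapless aligned stretch with >= mf bases each side of j).
oracle_spans <- function(pos, cigar, j, mf = 5L) {
  all((j - mf + 1L):(j + mf) %in% oracle_covered_positions(pos, cigar))
}

# Per-read scan over a reads data.frame (qname, rname, pos, cigar, plus
# optional mapq/flag columns), testing every rule clause independently.
oracle_count <- function(reads, chrom, j, mf = 5L, mapq_min = 0L,
                         dedup = FALSE, unit = "read") {
  hits <- character(0)
  n <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$rname[i] != chrom) next
    if (!is.null(reads$mapq) && reads$mapq[i] < mapq_min) next
    if (dedup && !is.null(reads$flag) &&
        bitwAnd(reads$flag[i], 1024L) != 0L) next
    if (oracle_spans(reads$pos[i], reads$cigar[i], j, mf)) {
      n <- n + 1L
      hits <- c(hits, reads$qname[i])
    }
  }
  if (unit == "fragment") length(unique(hits)) else n
}

# Random alignment fixture around a junction: gapless, soft-clipped,
# spliced, deletion- and insertion-bearing reads at randomized offsets,
# plus deterministic 4 bp / 5 bp flank and splice-boundary edge cases.
random_read_fixture <- function(j, n = 50L, read_len = 50L, chrom = "chrT") {
  kind <- sample(c("plain", "clip", "splice", "del", "ins"), n, replace = TRUE)
  pos <- j + sample(-(read_len + 10L):10L, n, replace = TRUE)
  pos <- pmax(pos, 1L)
  cigar <- character(n)
  for (i in seq_len(n)) {
    cigar[i] <- switch(kind[i],
      plain = sprintf("%dM", read_len),
      clip = sprintf("%dS%dM", sample(3:8, 1), read_len - sample(3:8, 1)),
      splice = sprintf("%dM%dN%dM", sample(5:20, 1), sample(5:50, 1),
                       sample(5:20, 1)),
      del = sprintf("%dM%dD%dM", sample(5:20, 1), sample(1:4, 1),
                    sample(5:20, 1)),
      ins = sprintf("%dM%dI%dM", sample(5:20, 1), sample(1:4, 1),
                    sample(5:20, 1)))
  }
  # the deterministic edge reads need room for their fixed geometry
  edge <- if (read_len >= 45L && j >= 45L) data.frame(
    qname = c("edge_flank5", "edge_flank4", "edge_splice_at", "edge_splice_ok"),
    rname = chrom,
    pos = c(j - 4L, j - 3L, j - 19L, j - 44L),
    cigar = c(sprintf("%dM", read_len), sprintf("%dM", read_len),
              sprintf("20M10N%dM", read_len - 20L),
              sprintf("10M5N%dM", read_len - 15L)),
    mapq = 60L, flag = 0L) else NULL
  rnd <- data.frame(qname = sprintf("r%03d", seq_len(n)), rname = chrom,
                    pos = pos, cigar = cigar,
                    mapq = sample(c(0L, 10L, 60L), n, replace = TRUE),
                    flag = sample(c(0L, 1024L), n, replace = TRUE,
                                  prob = c(0.9, 0.1)))
  rbind(edge, rnd)
}

# Write a reads data.frame as SAM (reference long enough for every read).
write_fixture_sam <- function(reads, chrom = "chrT", ref_len = NULL) {
  if (is.null(ref_len)) {
    ref_len <- if (nrow(reads) == 0L) 1000L else {
      width <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
      max(reads$pos + width) + 10L
    }
  }
  path <- tempfile(fileext = ".sam")
  refs <- unique(c(as.character(reads$rname), chrom))
  lens <- stats::setNames(rep(ref_len, length(refs)), refs)
  write_sam(path, lens, reads)
  path
}

# Welch two-sample t statistic and two-sided p value from the textbook
# formulas, independent of stats::t.test.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}
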