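parse_sam_reads <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0)
    return(data.frame(qname = character(0), rname = character(0),
                      pos = integer(0), cigar = character(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  data.frame(qname = vapply(f, `[`, "", 1),
             flag = as.integer(vapply(f, `[`, "", 2)),
             rname = vapply(f, `[`, "", 3),
             pos = as.integer(vapply(f, `[`, "", 4)),
             mapq = as.integer(vapply(f, `[`, "", 5)),
             cigar = vapply(f, `[`, "", 6),
             stringsAsFactors = FALSE)
}

test_that("simulation is reproducible: same seed, identical files", {
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_bulk(clone_mixture_config(p = 0.2, depth = 300, seed = 99),
                      dir = d1)
  s2 <- simulate_bulk(clone_mixture_config(p = 0.2, depth = 300, seed = 99),
                      dir = d2)
  for (f in c("sam", "fasta", "gtf", "fusion_table", "truth_manifest")) {
    expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]))
  }
  f1 <- make_fixture_suite(tempfile(), seed = 4)
  f2 <- make_fixture_suite(tempfile(), seed = 4)
  expect_identical(readLines(f1$paths$sam), readLines(f2$paths$sam))
})

test_that("truth manifests equal a brute-force recount of the emitted SAM", {
  sim <- simulate_bulk(clone_mixture_config(p = 0.3, depth = 400, seed = 17))
  reads <- parse_sam_reads(sim$paths$sam)
  truth <- read_ifcr_tsv(sim$paths$truth_manifest)
  for (i in seq_len(nrow(truth))) {
    expect_identical(oracle_count(reads, truth$rname[i], truth$coordinate[i]),
                     truth$spanning_reads[i])
  }
  fx <- make_fixture_suite(tempfile(), seed = 5)
  freads <- parse_sam_reads(fx$paths$sam)
  for (i in seq_len(nrow(fx$expected))) {
    expect_identical(
      oracle_count(freads, fx$expected$rname[i], fx$expected$coordinate[i]),
      fx$expected$spanning_reads[i])
  }
})

test_that("fixture edge reads sit exactly on the 4 bp / 5 bp flank boundary", {
  fx <- make_fixture_suite(tempfile(), seed = 6)
  aln <- read_alignments(fx$paths$sam)
  qn <- S4Vectors::mcols(aln)$qname
  bp <- breakpoint(fx$locus$chrom_a, fx$locus$junction_a)
  sp <- read_spans_junction(aln, bp)
  expect_true(sp[qn == "pa_flank5L"])
  expect_true(sp[qn == "pa_flank5R"])
  expect_false(sp[qn == "pa_flank4L"])
  expect_false(sp[qn == "pa_flank4R"])
  expect_false(sp[qn == "pa_spliceAt"])
  expect_true(sp[qn == "pa_spliceSpan"])
  # package counts equal the manifest through the real pipeline
  for (i in seq_len(nrow(fx$expected))) {
    expect_identical(
      count_overlapping_reads(aln, breakpoint(fx$expected$rname[i],
                                              fx$expected$coordinate[i])),
      fx$expected$spanning_reads[i])
  }
})

test_that("no fusion clone means no fusion reads", {
  sim <- simulate_bulk(clone_mixture_config(p = 0, depth = 300, seed = 23))
  expect_identical(unname(sim$truth$emitted["f"]), 0L)
  aln <- read_alignments(sim$paths$sam)
  f <- count_fusion_reads(aln, list(name = sim$locus$contig_name,
                                    junction_offset = sim$locus$contig_junction))
  expect_identical(f, 0L)
  res <- compute_ifcr(f,
                      count_overlapping_reads(aln,
                        breakpoint(sim$locus$chrom_a, sim$locus$junction_a)),
                      count_overlapping_reads(aln,
                        breakpoint(sim$locus$chrom_b, sim$locus$junction_b)))
  expect_equal(res$average, 0)
})

test_that("a symmetric mixture estimates iFCR near 1", {
  sim <- simulate_bulk(clone_mixture_config(p = 0.5, depth = 4000, seed = 29))
  aln <- read_alignments(sim$paths$sam)
  est <- compute_ifcr(
    count_fusion_reads(aln, list(name = sim$locus$contig_name,
                                 junction_offset = sim$locus$contig_junction)),
    count_overlapping_reads(aln, breakpoint(sim$locus$chrom_a,
                                            sim$locus$junction_a)),
    count_overlapping_reads(aln, breakpoint(sim$locus$chrom_b,
                                            sim$locus$junction_b)))
  expect_lt(abs(est$average - 1), 0.1)
})

test_that("emitted reads respect the declared reference bounds", {
  sim <- simulate_bulk(clone_mixture_config(p = 0.4, depth = 500, seed = 31))
  reads <- parse_sam_reads(sim$paths$sam)
  lens <- c(chrA = 3000L, chrB = 3000L)
  lens[sim$locus$contig_name] <- sim$locus$contig_len
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  expect_true(all(reads$pos >= 1))
  expect_true(all(reads$pos + width - 1L <= lens[reads$rname]))
  # and the SAM round-trips through the standard BAM machinery
  expect_s4_class(read_alignments(sim$paths$sam), "GAlignments")
})

test_that("min and max variants bracket the truth under unequal capture", {
  # engineered asymmetry: parent b captured at 3x the rate of parent a
  set.seed(37)
  p <- 0.2; r <- p / (1 - p); depth <- 2000
  est_min <- est_max <- numeric(40)
  for (i in 1:40) {
    f <- rpois(1, depth * p)
    n_a <- rpois(1, depth * (1 - p) * 0.5)
    n_b <- rpois(1, depth * (1 - p) * 1.5)
    est <- compute_ifcr(f, n_a, n_b)
    est_min[i] <- est$minimum; est_max[i] <- est$maximum
  }
  expect_lt(mean(est_min), r)
  expect_gt(mean(est_max), r)
})

test_that("single-cell panels show the log-linear iFCR / real-ratio relation", {
  ev <- simulate_cell_events(n_events = 40, seed = 43)
  expect_equal(nrow(ev), 40)
  fit <- ifcr_vs_real_ratio(ev)
  expect_gt(fit$r, 0.7)
  expect_gt(fit$slope, 0)
  # boundary: p = 1 makes every cell fusion-bearing
  sim1 <- simulate_cells(clone_mixture_config(p = 1, n_cells = 30, seed = 47))
  expect_true(all(sim1$cells$clone == "fusion"))
  expect_equal(sim1$truth$n_fusion_clone_cells, 30)
  # binomial construction of fusion-cell counts
  sim2 <- simulate_cells(clone_mixture_config(p = 0.1, n_cells = 100, seed = 53))
  expect_lte(abs(sim2$truth$n_fusion_clone_cells - 10), 12)
})

test_that("invalid mixture configurations are rejected", {
  expect_error(clone_mixture_config(p = 1.2), "\\[0, 1\\]")
  expect_error(clone_mixture_config(p = 0.5, read_length = 8, min_flank = 5),
               "min_flank")
  expect_error(clone_mixture_config(p = 0.5, depth = 0), "invalid")
  expect_error(simulate_cells(clone_mixture_config(p = 0.5)), "n_cells")
})
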