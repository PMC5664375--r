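#' Configuration for a simulated clone mixture
#'
#' Describes a tumour as a two-population mixture: a fusion-bearing
#' subclone at fraction `p` that expresses the chimeric transcript, and
#' wild-type clones at fraction `1 - p` expressing both parent genes.
#' Per-cell expression of the fused locus is equal for chimeric and
#' wild-type transcripts — the core assumption under which the iFCR
#' estimates the clone ratio r = p / (1 - p).
#'
#' @param p Fusion-clone fraction in `[0, 1]`.
#' @param n_cells Number of cells for single-cell simulation (`NULL` for
#'   bulk).
#' @param read_length Read length in bp; must be at least
#'   `2 * min_flank` so a read can satisfy the flank rule. Default 100.
#' @param depth Expected number of junction-spanning reads per junction
#'   window contributed by a clone occupying the whole sample (i.e. a
#'   junction carried by clone fraction q contributes `depth * q`
#'   expected spanning reads). Default 6000.
#' @param expr_chimeric,expr_wildtype Relative per-cell expression of
#'   the chimeric and wild-type transcripts; both default 1 (equal).
#' @param residual_wildtype Fraction of wild-type parent expression
#'   retained by fusion-bearing cells (e.g. from an unfused allele).
#'   Default 0: the simple two-population model in which the expected
#'   iFCR-average equals `r` exactly.
#' @param min_flank Flank rule the emitted spanning reads are generated
#'   to satisfy; default 5.
#' @param background_frac Expected non-spanning near-junction reads per
#'   junction, as a fraction of that junction's spanning expectation;
#'   these exercise the flank filter without contributing counts.
#'   Default 0.1.
#' @param cell_depth Single-cell mode: expected junction-spanning reads
#'   per cell per expressed junction. Default 5.
#' @param gene_depth Single-cell mode: expected whole-gene transcript
#'   counts per cell per expressed parent gene (used for the nonzero
#'   detection behind the cell-count real ratio). Default 20.
#' @param seed Integer seed; every simulation is reproducible given it.
#' @return A `clone_mixture_config` object.
#' @export
clone_mixture_config <- function(p, n_cells = NULL, read_length = 100L,
                                 depth = 6000, expr_chimeric = 1,
                                 expr_wildtype = 1, residual_wildtype = 0,
                                 min_flank = 5L, background_frac = 0.1,
                                 cell_depth = 5, gene_depth = 20,
                                 seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]", call. = FALSE)
  read_length <- as.integer(read_length)
  min_flank <- as.integer(min_flank)
  if (read_length < 2L * min_flank)
    stop("read_length must be >= 2 * min_flank", call. = FALSE)
  if (depth <= 0 || expr_chimeric < 0 || expr_wildtype < 0 ||
      residual_wildtype < 0 || residual_wildtype > 1 || background_frac < 0)
    stop("invalid expression/depth configuration", call. = FALSE)
  if (!is.null(n_cells)) {
    n_cells <- as.integer(n_cells)
    if (is.na(n_cells) || n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  }
  structure(list(p = p, n_cells = n_cells, read_length = read_length,
                 depth = depth, expr_chimeric = expr_chimeric,
                 expr_wildtype = expr_wildtype,
                 residual_wildtype = residual_wildtype,
                 min_flank = min_flank, background_frac = background_frac,
                 cell_depth = cell_depth, gene_depth = gene_depth,
                 seed = seed),
            class = "clone_mixture_config")
}

# Toy two-gene locus shared by the simulator: single-exon genes on their
# own chromosomes, junction mid-exon, plus the chimeric contig built by
# the same convention as build_chimeric_contig().
.toy_locus <- function() {
  list(event_id = "GENEA-GENEB",
       gene_a = "GENEA", chrom_a = "chrA", junction_a = 1500L, strand_a = "+",
       gene_b = "GENEB", chrom_b = "chrB", junction_b = 1500L, strand_b = "+",
       exon_a = c(1001L, 2000L), exon_b = c(1001L, 2000L),
       chrom_len = 3000L,
       contig_name = "FUS_GENEA-GENEB", contig_junction = 500L,
       contig_len = 1000L)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Write alignment records as a SAM file
#'
#' Minimal single-end SAM emitter for simulated or hand-built fixtures:
#' an `@HD`/`@SQ` header followed by one line per record.
#'
#' @param path Output path.
#' @param ref_lengths Named integer vector: reference name -> length.
#' @param reads data.frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq` (optional columns default sensibly).
#' @return `path`, invisibly.
#' @export
write_sam <- function(path, ref_lengths, reads) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                      as.integer(ref_lengths)))
  if (nrow(reads) > 0) {
    if (is.null(reads$flag)) reads$flag <- 0L
    if (is.null(reads$mapq)) reads$mapq <- 60L
    if (is.null(reads$seq)) reads$seq <- "*"
    qual <- ifelse(reads$seq == "*", "*",
                   strrep("I", nchar(reads$seq)))
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                    reads$qname, as.integer(reads$flag), reads$rname,
                    as.integer(reads$pos), as.integer(reads$mapq),
                    reads$cigar, reads$seq, qual)
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

# Uniformly sample read start positions that do (spanning) or do not
# (background) satisfy the flank rule at junction j.
.spanning_starts <- function(n, j, L, mf) {
  lo <- j + mf - L + 1L
  hi <- j - mf + 1L
  if (hi < lo) stop("read_length too short for flank rule", call. = FALSE)
  sample(lo:hi, n, replace = TRUE)
}

.background_starts <- function(n, j, L, mf) {
  cand <- c(seq.int(j - L + 1L, length.out = mf - 1L),  # right flank < mf
            seq.int(j - mf + 2L, length.out = mf - 1L)) # left flank < mf
  cand <- cand[cand >= 1L]
  if (length(cand) == 0L || n == 0L) return(integer(0))
  cand[sample.int(length(cand), n, replace = TRUE)]
}

#' Simulate bulk RNA-seq junction reads for a clone mixture
#'
#' Draws Poisson read counts for the chimeric junction and both parent
#' junctions from the mixture model, places each read uniformly over the
#' positions compatible with its spanning status, and writes pre-aligned
#' SAM (no external aligner needed), reference FASTA, toy GTF, the
#' fusion event table and a truth manifest. Fusion-clone transcripts
#' contribute reads only to the chimeric junction; wild-type clones only
#' to the parent junctions (plus an optional residual, see
#' [clone_mixture_config()]).
#'
#' Expected counts: chimeric `depth * p * expr_chimeric`; each parent
#' `depth * ((1 - p) + p * residual) * expr_wildtype`. Under the default
#' equal-expression, zero-residual model the expected iFCR-average is
#' exactly r = p / (1 - p).
#'
#' @param config A [clone_mixture_config()].
#' @param dir Output directory (created).
#' @param fastq Also write the reads as FASTQ (for runs through a real
#'   aligner). Default `FALSE`.
#' @return List with file paths (`sam`, `fasta`, `gtf`, `fusion_table`,
#'   `truth_manifest`, optionally `fastq`), the `locus` description and
#'   `truth`: `r`, `expected_ifcr`, `lambda`, `emitted` (the realised
#'   spanning-read counts per junction) and `background` counts.
#' @export
simulate_bulk <- function(config, dir = tempfile("ifcr_bulk"), fastq = FALSE) {
  stopifnot(inherits(config, "clone_mixture_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loc <- .toy_locus()
  L <- config$read_length
  mf <- config$min_flank
  p <- config$p

  refs <- c(chrA = .random_dna(loc$chrom_len), chrB = .random_dna(loc$chrom_len))
  contig_seq <- paste0(
    substr(refs["chrA"], loc$exon_a[1], loc$junction_a),
    substr(refs["chrB"], loc$junction_b + 1L, loc$exon_b[2]))
  refs <- c(refs, structure(contig_seq, names = loc$contig_name))
  ref_lengths <- vapply(refs, nchar, integer(1))

  lam_f <- config$depth * p * config$expr_chimeric
  lam_n <- config$depth * ((1 - p) + p * config$residual_wildtype) *
    config$expr_wildtype
  emitted <- c(f = stats::rpois(1, lam_f),
               n_a = stats::rpois(1, lam_n),
               n_b = stats::rpois(1, lam_n))
  bg <- stats::rpois(3, config$background_frac * c(lam_f, lam_n, lam_n))

  junctions <- data.frame(
    rname = c(loc$contig_name, loc$chrom_a, loc$chrom_b),
    j = c(loc$contig_junction, loc$junction_a, loc$junction_b))
  reads <- do.call(rbind, lapply(1:3, function(k) {
    span <- .spanning_starts(emitted[k], junctions$j[k], L, mf)
    back <- .background_starts(bg[k], junctions$j[k], L, mf)
    pos <- c(span, back)
    if (length(pos) == 0L) return(NULL)
    data.frame(rname = junctions$rname[k], pos = pos,
               spanning = rep(c(TRUE, FALSE), c(length(span), length(back))))
  }))
  if (is.null(reads))
    reads <- data.frame(rname = character(0), pos = integer(0),
                        spanning = logical(0))
  if (nrow(reads) > 0) {
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    reads$qname <- sprintf("sim%06d", seq_len(nrow(reads)))
    reads$flag <- 0L
    reads$mapq <- 60L
    reads$cigar <- sprintf("%dM", L)
    reads$seq <- substr(refs[reads$rname], reads$pos, reads$pos + L - 1L)
  } else {
    reads <- data.frame(qname = character(0), flag = integer(0),
                        rname = character(0), pos = integer(0),
                        mapq = integer(0), cigar = character(0),
                        seq = character(0))
  }

  paths <- list(sam = file.path(dir, "reads.sam"),
                fasta = file.path(dir, "refs.fa"),
                gtf = file.path(dir, "genes.gtf"),
                fusion_table = file.path(dir, "fusions.tsv"),
                truth_manifest = file.path(dir, "truth.tsv"))
  write_sam(paths$sam, ref_lengths, reads)
  writeLines(as.vector(rbind(paste0(">", names(refs)), refs)), paths$fasta)
  .write_toy_gtf(paths$gtf, loc)

  fus <- data.frame(event_id = loc$event_id,
                    gene_a = loc$gene_a, chrom_a = loc$chrom_a,
                    junction_a = loc$junction_a, strand_a = loc$strand_a,
                    gene_b = loc$gene_b, chrom_b = loc$chrom_b,
                    junction_b = loc$junction_b, strand_b = loc$strand_b,
                    fusion_reads = NA_integer_,
                    contig_name = loc$contig_name,
                    contig_junction = loc$contig_junction)
  write_ifcr_tsv(fus, paths$fusion_table)
  truth_tab <- data.frame(junction = c("fusion", "parent_a", "parent_b"),
                          rname = junctions$rname, coordinate = junctions$j,
                          spanning_reads = as.integer(emitted),
                          background_reads = as.integer(bg))
  write_ifcr_tsv(truth_tab, paths$truth_manifest)

  if (fastq) {
    paths$fastq <- file.path(dir, "reads.fastq")
    writeLines(as.vector(rbind(paste0("@", reads$qname), reads$seq,
                               "+", strrep("I", L))), paths$fastq)
  }

  r <- if (p < 1) p / (1 - p) else Inf
  expected_ifcr <- if (lam_n > 0) lam_f / lam_n else NA_real_
  list(dir = dir, paths = paths, locus = loc,
       truth = list(p = p, r = r, expected_ifcr = expected_ifcr,
                    lambda = c(f = lam_f, n_a = lam_n, n_b = lam_n),
                    emitted = emitted, background = bg))
}

.write_toy_gtf <- function(path, loc) {
  attrs <- function(g) sprintf('gene_id "%s"; transcript_id "%s.t1";', g, g)
  lines <- c(
    sprintf("%s\tifcr_sim\texon\t%d\t%d\t.\t%s\t.\t%s",
            loc$chrom_a, loc$exon_a[1], loc$exon_a[2], loc$strand_a,
            attrs(loc$gene_a)),
    sprintf("%s\tifcr_sim\texon\t%d\t%d\t.\t%s\t.\t%s",
            loc$chrom_b, loc$exon_b[1], loc$exon_b[2], loc$strand_b,
            attrs(loc$gene_b)))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate single-cell records for a clone mixture
#'
#' Assigns each cell to the fusion clone by a Bernoulli(`p`) draw.
#' Fusion cells emit chimeric-junction reads; wild-type cells emit
#' parent-junction reads and whole-gene transcript counts (used for
#' nonzero parent detection). Under the default zero-residual model a
#' fusion cell expresses no wild-type parent transcript, so the
#' cell-count real ratio recovers r = p / (1 - p) up to binomial
#' sampling error.
#'
#' @param config A [clone_mixture_config()] with `n_cells` set.
#' @param sample_id Sample label attached to every cell.
#' @return List with `cells` (data.frame: cell_id, sample_id, clone,
#'   fusion_reads, n_a, n_b, gene_a_count, gene_b_count) and `truth`
#'   (`p`, `r`, `n_fusion_clone_cells`).
#' @export
simulate_cells <- function(config, sample_id = "S1") {
  stopifnot(inherits(config, "clone_mixture_config"))
  if (is.null(config$n_cells))
    stop("config$n_cells must be set for single-cell simulation", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_cells
  fus <- stats::rbinom(n, 1L, config$p) == 1L
  cd <- config$cell_depth
  gd <- config$gene_depth
  res <- config$residual_wildtype
  cells <- data.frame(
    cell_id = sprintf("%s_c%04d", sample_id, seq_len(n)),
    sample_id = sample_id,
    clone = ifelse(fus, "fusion", "wildtype"),
    fusion_reads = ifelse(fus, stats::rpois(n, cd * config$expr_chimeric), 0L),
    n_a = ifelse(fus, stats::rpois(n, cd * res * config$expr_wildtype),
                 stats::rpois(n, cd * config$expr_wildtype)),
    n_b = ifelse(fus, stats::rpois(n, cd * res * config$expr_wildtype),
                 stats::rpois(n, cd * config$expr_wildtype)),
    gene_a_count = ifelse(fus, stats::rpois(n, gd * res), stats::rpois(n, gd)),
    gene_b_count = ifelse(fus, stats::rpois(n, gd * res), stats::rpois(n, gd)),
    stringsAsFactors = FALSE)
  r <- if (config$p < 1) config$p / (1 - config$p) else Inf
  list(cells = cells,
       truth = list(p = config$p, r = r, n_fusion_clone_cells = sum(fus)))
}

#' Simulate a panel of single-cell fusion events
#'
#' One fusion event per simulated sample, with clone fractions drawn
#' uniformly from `[p_min, p_max]`; for each event the sample-level
#' iFCR ([aggregate_ifcr()]) and the cell-count real ratio
#' ([real_ratio()]) are computed from the simulated cells. This is the
#' panel on which the log-linear association between iFCR and the real
#' ratio is examined.
#'
#' @param n_events Number of events/samples. Default 50.
#' @param p_min,p_max Clone-fraction range. Defaults 0.02 and 0.5.
#' @param n_cells Cells per sample. Default 96.
#' @param seed Integer seed.
#' @param ... Further arguments to [clone_mixture_config()].
#' @return data.frame: event_id, p, r, f, n_a, n_b, ifcr_average,
#'   real_ratio, n_fusion_cells, n_parent_cells.
#' @export
simulate_cell_events <- function(n_events = 50, p_min = 0.02, p_max = 0.5,
                                 n_cells = 96, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ps <- stats::runif(n_events, p_min, p_max)
  rows <- lapply(seq_len(n_events), function(i) {
    cfg <- clone_mixture_config(p = ps[i], n_cells = n_cells, ...)
    sim <- simulate_cells(cfg, sample_id = sprintf("S%03d", i))
    agg <- aggregate_ifcr(sim$cells)
    rr <- real_ratio(sim$cells)
    cnt <- attr(agg, "counts")
    data.frame(event_id = sprintf("EV%03d", i), p = ps[i],
               r = sim$truth$r, f = cnt["f"], n_a = cnt["n_a"],
               n_b = cnt["n_b"], ifcr_average = agg$average,
               real_ratio = rr$ratio, n_fusion_cells = rr$n_fusion_cells,
               n_parent_cells = rr$n_parent_cells, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Simulate an annotated fusion-event cohort
#'
#' Draws per-event fusion and overlapping read counts from the clone
#' mixture count model at group-specific clone fractions, producing an
#' events table ready for [ifcr_table()] and [assign_groups()]. Default
#' fractions encode the expected ordering cell line (near-homogeneous)
#' above recurrent, above non-recurrent tumour, above normal.
#'
#' @param n_per_group Events per group. Default 50.
#' @param fractions Named vector of clone fractions per group label;
#'   names drawn from C, TMPRSS2_ERG, R, T, N.
#' @param depth Expected junction-spanning reads per junction for a
#'   full-sample clone. Default 200, typical of moderately expressed
#'   loci in a bulk library.
#' @param seed Integer seed.
#' @return data.frame: event_id, gene_a, gene_b, sample_class,
#'   recurrent, true_p, true_r, f, n_a, n_b.
#' @export
simulate_cohort <- function(n_per_group = 50,
                            fractions = c(C = 0.9, R = 0.3, T = 0.1, N = 0.02),
                            depth = 200, seed = NULL) {
  stopifnot(all(names(fractions) %in% GROUP_LEVELS))
  if (!is.null(seed)) set.seed(seed)
  class_of <- c(C = "cell_line", TMPRSS2_ERG = "tumor", R = "tumor",
                T = "tumor", N = "normal")
  rec_of <- c(C = 0L, TMPRSS2_ERG = 1L, R = 1L, T = 0L, N = 0L)
  rows <- lapply(names(fractions), function(g) {
    p <- fractions[[g]]
    f <- stats::rpois(n_per_group, depth * p)
    n_a <- stats::rpois(n_per_group, depth * (1 - p))
    n_b <- stats::rpois(n_per_group, depth * (1 - p))
    ga <- if (g == "TMPRSS2_ERG") rep("TMPRSS2", n_per_group)
          else sprintf("G%s%03dA", g, seq_len(n_per_group))
    gb <- if (g == "TMPRSS2_ERG") rep("ERG", n_per_group)
          else sprintf("G%s%03dB", g, seq_len(n_per_group))
    data.frame(event_id = sprintf("%s_%03d", g, seq_len(n_per_group)),
               gene_a = ga, gene_b = gb,
               sample_class = class_of[[g]], recurrent = rec_of[[g]],
               true_p = p, true_r = p / (1 - p),
               f = f, n_a = n_a, n_b = n_b, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a deterministic on-disk fixture suite
#'
#' Emits a small, fully determined set of files for exercising the
#' counting pipeline: toy reference FASTA and GTF, a SAM of hand-placed
#' reads at both parent junctions and the chimeric contig junction
#' (including exact 4-bp and 5-bp flank edge reads and a spliced read
#' whose skip boundary falls on the junction), the fusion event table,
#' and a manifest of expected spanning-read counts under the default
#' 5-bp flank rule. Outputs are byte-identical for a given seed.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed for the randomized portion (reference bases
#'   and extra spanning reads).
#' @param n_random Extra randomized spanning reads per junction.
#'   Default 10.
#' @return List with the file paths and the `expected` manifest
#'   data.frame.
#' @export
make_fixture_suite <- function(dir, seed = 1L, n_random = 10L) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loc <- .toy_locus()
  L <- 50L
  mf <- 5L
  refs <- c(chrA = .random_dna(loc$chrom_len), chrB = .random_dna(loc$chrom_len))
  contig_seq <- paste0(
    substr(refs["chrA"], loc$exon_a[1], loc$junction_a),
    substr(refs["chrB"], loc$junction_b + 1L, loc$exon_b[2]))
  refs <- c(refs, structure(contig_seq, names = loc$contig_name))
  ref_lengths <- vapply(refs, nchar, integer(1))

  one_junction <- function(rname, j, prefix) {
    # deterministic edge reads: flanks exactly 5 (counted), exactly 4
    # (rejected), and a spliced read skipping across the junction
    edge <- data.frame(
      qname = paste0(prefix, c("_flank5L", "_flank5R", "_flank4L", "_flank4R",
                               "_spliceAt", "_spliceSpan")),
      rname = rname,
      pos = c(j - mf + 1L, j + mf - L + 1L, j - mf + 2L, j + mf - L,
              j - 20L + 1L, j - 30L + 1L),
      cigar = c(sprintf("%dM", L), sprintf("%dM", L),
                sprintf("%dM", L), sprintf("%dM", L),
                sprintf("20M10N%dM", L - 20L),      # skip starts at junction
                sprintf("10M5N%dM", L - 10L)),      # block spans junction
      spanning = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
    rnd <- data.frame(
      qname = sprintf("%s_rand%02d", prefix, seq_len(n_random)),
      rname = rname,
      pos = .spanning_starts(n_random, j, L, mf),
      cigar = sprintf("%dM", L),
      spanning = TRUE)
    rbind(edge, rnd)
  }
  reads <- rbind(one_junction(loc$contig_name, loc$contig_junction, "fus"),
                 one_junction(loc$chrom_a, loc$junction_a, "pa"),
                 one_junction(loc$chrom_b, loc$junction_b, "pb"))
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  reads$seq <- substr(refs[reads$rname], reads$pos, reads$pos + width - 1L)
  # the N-skipped bases must not appear in SEQ; patch the spliced reads
  qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(reads$cigar)
  spliced <- qwidth != width
  reads$seq[spliced] <- vapply(which(spliced), function(i) {
    rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      reads$cigar[i], pos = reads$pos[i], ops = c("M", "=", "X"))[[1]]
    paste(substring(refs[[reads$rname[i]]], IRanges::start(rng),
                    IRanges::end(rng)), collapse = "")
  }, character(1))

  paths <- list(sam = file.path(dir, "reads.sam"),
                fasta = file.path(dir, "refs.fa"),
                gtf = file.path(dir, "genes.gtf"),
                fusion_table = file.path(dir, "fusions.tsv"),
                manifest = file.path(dir, "manifest.tsv"))
  write_sam(paths$sam, ref_lengths,
            reads[, c("qname", "rname", "pos", "cigar", "seq")])
  writeLines(as.vector(rbind(paste0(">", names(refs)), refs)), paths$fasta)
  .write_toy_gtf(paths$gtf, loc)
  fus <- data.frame(event_id = loc$event_id,
                    gene_a = loc$gene_a, chrom_a = loc$chrom_a,
                    junction_a = loc$junction_a, strand_a = loc$strand_a,
                    gene_b = loc$gene_b, chrom_b = loc$chrom_b,
                    junction_b = loc$junction_b, strand_b = loc$strand_b,
                    fusion_reads = NA_integer_,
                    contig_name = loc$contig_name,
                    contig_junction = loc$contig_junction)
  write_ifcr_tsv(fus, paths$fusion_table)
  expected <- data.frame(
    junction = c("fusion", "parent_a", "parent_b"),
    rname = c(loc$contig_name, loc$chrom_a, loc$chrom_b),
    coordinate = c(loc$contig_junction, loc$junction_a, loc$junction_b),
    spanning_reads = as.integer(tapply(reads$spanning, reads$rname, sum)[
      c(loc$contig_name, loc$chrom_a, loc$chrom_b)]))
  write_ifcr_tsv(expected, paths$manifest)
  list(dir = dir, paths = paths, expected = expected, locus = loc)
}
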