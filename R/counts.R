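#' Describe a genomic breakpoint
#'
#' The junction is encoded as lying between reference base `junction` and
#' `junction + 1` (1-based), which avoids the ambiguity of a single-base
#' breakpoint coordinate.
#'
#' @param chrom Chromosome / reference sequence name.
#' @param junction 1-based coordinate of the base immediately 5' (in
#'   reference orientation) of the junction; >= 1.
#' @param strand `"+"` or `"-"`.
#' @param gene_id Annotation identifier of the parent gene.
#' @param region_class One of `"exonic"`, `"intronic"`, `"utr"`,
#'   `"unknown"` — breakpoints occur in all three genic region classes.
#' @return A `breakpoint` object.
#' @export
breakpoint <- function(chrom, junction, strand = "+", gene_id = NA_character_,
                       region_class = c("unknown", "exonic", "intronic", "utr")) {
  region_class <- match.arg(region_class)
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string", call. = FALSE)
  junction <- as.integer(junction)
  if (is.na(junction) || junction < 1L)
    stop("junction must be a coordinate >= 1", call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'", call. = FALSE)
  structure(list(chrom = chrom, junction = junction, strand = strand,
                 gene_id = gene_id, region_class = region_class),
            class = "breakpoint")
}

#' Describe a fusion event (paired breakpoints)
#'
#' @param id Event label, e.g. `"TMPRSS2-ERG"`.
#' @param bp_a [breakpoint()] of the 5' parent gene.
#' @param bp_b [breakpoint()] of the 3' parent gene.
#' @param fusion_reads Externally supplied fusion-read count, or `NA` to
#'   defer to contig-based counting. Fusion callers and publications
#'   report this number directly; it is taken as given when present.
#' @param same_gene Set `TRUE` to allow bp_a and bp_b on the same gene
#'   (e.g. an internal rearrangement).
#' @return A `fusion_event` object.
#' @export
fusion_event <- function(id, bp_a, bp_b, fusion_reads = NA_integer_,
                         same_gene = FALSE) {
  stopifnot(inherits(bp_a, "breakpoint"), inherits(bp_b, "breakpoint"))
  if (!is.na(fusion_reads) && fusion_reads < 0)
    stop("fusion_reads must be non-negative", call. = FALSE)
  if (!same_gene && !is.na(bp_a$gene_id) && !is.na(bp_b$gene_id) &&
      identical(bp_a$gene_id, bp_b$gene_id))
    stop("bp_a and bp_b are on the same gene; set same_gene = TRUE if intended",
         call. = FALSE)
  structure(list(id = id, bp_a = bp_a, bp_b = bp_b,
                 fusion_reads = fusion_reads, same_gene = same_gene),
            class = "fusion_event")
}

#' Junction-spanning rule for overlapping / fusion reads
#'
#' A read supports a junction only when a single gapless aligned stretch
#' carries at least `min_flank` aligned reference bases on each side of
#' it. The 5 bp default is the flanking requirement used when retrieving
#' overlapping reads by realignment. Duplicate removal and a mapping
#' quality floor are off by default (the original counting applies
#' neither) but are exposed because library protocols differ.
#'
#' @param min_flank Minimum aligned reference bases required on each side
#'   of the junction; >= 1. Default 5.
#' @param count_unit `"read"` counts each read end independently;
#'   `"fragment"` counts distinct query names, so a mate pair spanning
#'   the same junction twice contributes once.
#' @param mapq_min Minimum mapping quality (reads below are ignored).
#' @param dedup If `TRUE`, reads with the duplicate SAM flag are skipped.
#' @return An `overlap_rule` object.
#' @export
overlap_rule <- function(min_flank = 5L, count_unit = c("read", "fragment"),
                         mapq_min = 0L, dedup = FALSE) {
  count_unit <- match.arg(count_unit)
  min_flank <- as.integer(min_flank)
  if (is.na(min_flank) || min_flank < 1L)
    stop("min_flank must be >= 1", call. = FALSE)
  structure(list(min_flank = min_flank, count_unit = count_unit,
                 mapq_min = as.integer(mapq_min), dedup = isTRUE(dedup)),
            class = "overlap_rule")
}

#' Read an alignment file into a GAlignments object
#'
#' SAM input is converted to coordinate-sorted, indexed BAM in a
#' temporary directory; BAM input is used as is (an index is created
#' beside it, or in a temporary copy if the directory is read-only, when
#' `region` queries are requested). Unmapped, secondary and supplementary
#' records are excluded: counting units are primary read ends.
#'
#' @param path SAM (`.sam`) or BAM (`.bam`) file.
#' @param region Optional `GRanges` restricting the scan.
#' @return A [GenomicAlignments::GAlignments] with metadata columns
#'   `qname`, `flag`, `mapq`.
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
  } else {
    if (!file.exists(paste0(path, ".bai")) && !is.null(region))
      Rsamtools::indexBam(path)
    path
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = c("qname", "flag", "mapq"), flag = flags)
  } else {
    Rsamtools::ScanBamParam(what = c("qname", "flag", "mapq"), flag = flags,
                            which = region)
  }
  GenomicAlignments::readGAlignments(bam, param = param)
}

# Reference-space aligned blocks per read: M/=/X/D runs merged (a deletion
# keeps reference coverage contiguous), N gaps split blocks.
.aligned_blocks <- function(aln) {
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(aln),
    pos = GenomicAlignments::start(aln),
    ops = c("M", "=", "X", "D")
  )
  IRanges::reduce(rng, min.gapwidth = 1L)
}

#' Does a read span a junction with sufficient flanks?
#'
#' TRUE when one contiguous aligned block of the read covers at least
#' `rule$min_flank` reference bases at positions `<= junction` and at
#' least `min_flank` at positions `>= junction + 1`. A spliced read whose
#' skip (N) boundary coincides with the junction does not qualify: it
#' carries no contiguous sequence across the junction. Flank lengths are
#' measured in aligned reference bases, so deletions inside a flank count
#' towards it and insertions do not.
#'
#' @param read A `GAlignments` (any length; vectorised).
#' @param bp A [breakpoint()]; reads on other reference sequences return
#'   `FALSE`.
#' @param rule An [overlap_rule()].
#' @return Logical vector, one element per alignment record.
#' @export
read_spans_junction <- function(read, bp, rule = overlap_rule()) {
  stopifnot(methods::is(read, "GAlignments"), inherits(bp, "breakpoint"),
            inherits(rule, "overlap_rule"))
  if (length(read) == 0L) return(logical(0))
  out <- logical(length(read))
  on_chrom <- as.character(GenomicAlignments::seqnames(read)) == bp$chrom
  if (!any(on_chrom)) return(out)
  bl <- .aligned_blocks(read[on_chrom])
  mf <- rule$min_flank
  j <- bp$junction
  flat <- unlist(bl, use.names = FALSE)
  grp <- rep(seq_along(bl), lengths(bl))
  hit <- IRanges::start(flat) <= j - mf + 1L & IRanges::end(flat) >= j + mf
  out[on_chrom] <- as.logical(tabulate(grp[hit], nbins = length(bl)) > 0L)
  out
}

#' Count overlapping reads at a parent-gene breakpoint
#'
#' Counts alignment records (or fragments, per the rule) that span the
#' breakpoint junction with the required flanks. This is the realignment
#' count `n_a` / `n_b` of the iFCR denominator.
#'
#' @param alignments A SAM/BAM path or a `GAlignments` (as produced by
#'   [read_alignments()], whose metadata columns are required for MAPQ,
#'   duplicate and fragment handling).
#' @param bp A [breakpoint()].
#' @param rule An [overlap_rule()].
#' @return Non-negative integer count; deterministic for fixed input.
#' @export
count_overlapping_reads <- function(alignments, bp, rule = overlap_rule()) {
  stopifnot(inherits(bp, "breakpoint"))
  aln <- if (is.character(alignments)) read_alignments(alignments) else alignments
  stopifnot(methods::is(aln, "GAlignments"))
  if (!bp$chrom %in% GenomeInfoDb::seqlevels(aln))
    stop("reference sequence '", bp$chrom, "' absent from alignment header ",
         "(breakpoint ", bp$chrom, ":", bp$junction, ")", call. = FALSE)
  mc <- S4Vectors::mcols(aln)
  keep <- rep(TRUE, length(aln))
  if (!is.null(mc$mapq) && rule$mapq_min > 0L)
    keep <- keep & !is.na(mc$mapq) & mc$mapq >= rule$mapq_min
  if (rule$dedup && !is.null(mc$flag))
    keep <- keep & bitwAnd(mc$flag, 1024L) == 0L
  aln <- aln[keep]
  spans <- read_spans_junction(aln, bp, rule)
  if (rule$count_unit == "fragment") {
    qn <- S4Vectors::mcols(aln)$qname
    if (is.null(qn))
      stop("fragment counting needs qname metadata; read alignments with ",
           "read_alignments()", call. = FALSE)
    length(unique(qn[spans]))
  } else {
    sum(spans)
  }
}

#' Count fusion reads against a chimeric contig
#'
#' Applies the same junction-spanning rule at the contig's junction
#' offset. Used when fusion-read counts are not supplied externally
#' (published counts, when available, are taken as given).
#'
#' @param alignments SAM/BAM path or `GAlignments` of reads aligned to
#'   the contig coordinate system.
#' @param contig A [build_chimeric_contig()] result, or any list with
#'   elements `name` (reference sequence name) and `junction_offset`.
#' @param rule An [overlap_rule()].
#' @return Non-negative integer count.
#' @export
count_fusion_reads <- function(alignments, contig, rule = overlap_rule()) {
  stopifnot(!is.null(contig$name), !is.null(contig$junction_offset))
  bp <- breakpoint(contig$name, contig$junction_offset)
  count_overlapping_reads(alignments, bp, rule)
}
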