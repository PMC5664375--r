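#' Assemble the chimeric transcript contig for a fusion event
#'
#' Concatenates the 5' parent's transcript sequence through its
#' breakpoint with the 3' parent's transcript sequence from its
#' breakpoint, in transcript orientation (minus-strand genes are
#' reverse-complemented). Only exonic bases of a single annotated
#' transcript per parent are used, so intronic breakpoints contribute the
#' spliced sequence up to / from the junction.
#'
#' Coordinate convention: the junction lies between genomic base
#' `junction` and `junction + 1`. For the 5' parent the retained bases
#' are those transcribed before crossing that junction (`<= junction` on
#' `+` genes, `>= junction + 1` on `-` genes); for the 3' parent, those
#' transcribed after it. When a gene has several transcripts containing
#' the breakpoint, the transcript retaining the most exonic sequence is
#' used (first transcript id on ties); the choice is recorded in the
#' result.
#'
#' @param event A [fusion_event()].
#' @param annotation Exon annotation: a `GRanges` with metadata columns
#'   `gene_id` and `transcript_id` (rows of other `type`s are ignored if
#'   a `type` column is present), e.g. from
#'   `rtracklayer::import("genes.gtf")`.
#' @param genome Named [Biostrings::DNAStringSet] of reference sequences.
#' @return A `chimeric_contig`: list with `name` (`"FUS_<event id>"`),
#'   `event_id`, `seq` (a `DNAString`), `junction_offset` (the contig
#'   junction lies between offset and offset + 1), `transcript_a`,
#'   `transcript_b`.
#' @export
build_chimeric_contig <- function(event, annotation, genome) {
  stopifnot(inherits(event, "fusion_event"),
            methods::is(annotation, "GRanges"),
            methods::is(genome, "DNAStringSet"))
  exons <- annotation
  if (!is.null(exons$type)) exons <- exons[exons$type == "exon"]
  if (is.null(exons$gene_id) || is.null(exons$transcript_id))
    stop("annotation needs gene_id and transcript_id metadata columns",
         call. = FALSE)

  pre <- .transcript_side_seq(event$bp_a, "five", exons, genome)
  suf <- .transcript_side_seq(event$bp_b, "three", exons, genome)
  offset <- length(pre$seq)
  contig <- Biostrings::xscat(pre$seq, suf$seq)
  if (offset < 1L || offset >= length(contig))
    stop("degenerate contig for event ", event$id,
         ": junction offset ", offset, " of ", length(contig), call. = FALSE)
  structure(list(name = paste0("FUS_", event$id), event_id = event$id,
                 seq = contig, junction_offset = offset,
                 transcript_a = pre$transcript, transcript_b = suf$transcript),
            class = "chimeric_contig")
}

# Exonic sequence of one parent on one side of its junction, in
# transcript orientation.
.transcript_side_seq <- function(bp, side, exons, genome) {
  gx <- exons[!is.na(exons$gene_id) & exons$gene_id == bp$gene_id &
              as.character(GenomeInfoDb::seqnames(exons)) == bp$chrom]
  if (length(gx) == 0L)
    stop("no exons for gene ", bp$gene_id, " on ", bp$chrom, call. = FALSE)
  j <- bp$junction
  plus <- bp$strand == "+"
  # genomic interval retained on this side
  keep_lo <- if ((side == "five") == plus) 1L else j + 1L
  keep_hi <- if ((side == "five") == plus) j else .Machine$integer.max

  tx_ids <- unique(gx$transcript_id)
  spans <- vapply(tx_ids, function(tid) {
    e <- gx[gx$transcript_id == tid]
    c(min(GenomicRanges::start(e)), max(GenomicRanges::end(e)))
  }, numeric(2))
  containing <- tx_ids[spans[1, ] <= j & spans[2, ] >= j + 1L]
  if (length(containing) == 0L)
    stop("breakpoint ", bp$chrom, ":", j, " lies outside every transcript of ",
         bp$gene_id, "; candidates: ", paste(tx_ids, collapse = ", "),
         call. = FALSE)

  pick <- function(tid) {
    e <- sort(gx[gx$transcript_id == tid])
    lo <- pmax(GenomicRanges::start(e), keep_lo)
    hi <- pmin(GenomicRanges::end(e), keep_hi)
    ok <- lo <= hi
    list(starts = lo[ok], ends = hi[ok], len = sum(hi[ok] - lo[ok] + 1L))
  }
  kept <- lapply(containing, pick)
  lens <- vapply(kept, `[[`, numeric(1), "len")
  best <- which.max(lens)  # ties: first transcript id
  tid <- containing[best]
  ranges <- kept[[best]]
  if (ranges$len == 0L)
    stop("no exonic sequence retained for ", bp$gene_id, " (", side,
         " side of ", bp$chrom, ":", j, ")", call. = FALSE)

  chrom_seq <- genome[[bp$chrom]]
  if (is.null(chrom_seq))
    stop("reference sequence ", bp$chrom, " absent from genome", call. = FALSE)
  pieces <- lapply(seq_along(ranges$starts), function(i)
    Biostrings::subseq(chrom_seq, ranges$starts[i], ranges$ends[i]))
  seq <- if (length(pieces) == 1L) pieces[[1L]] else
    do.call(Biostrings::xscat, pieces)
  if (!plus) seq <- Biostrings::reverseComplement(seq)
  list(seq = seq, transcript = tid)
}

#' Write chimeric contigs as FASTA
#'
#' @param contigs A `chimeric_contig` or list of them.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_contig_fasta <- function(contigs, path) {
  if (inherits(contigs, "chimeric_contig")) contigs <- list(contigs)
  seqs <- Biostrings::DNAStringSet(lapply(contigs, `[[`, "seq"))
  names(seqs) <- vapply(contigs, `[[`, character(1), "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
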