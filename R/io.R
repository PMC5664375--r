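SCHEMA_COMMENT <- "# ifcr-schema: 1"

#' Write a result table as TSV
#'
#' Tab-separated, with a schema-version comment line ahead of the
#' header; `NA` is written literally so undefined values are visible
#' rather than dropped.
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ifcr_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SCHEMA_COMMENT, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV written by this package (or any commented TSV)
#'
#' @param path Input path; `#`-prefixed lines are skipped.
#' @return data.frame.
#' @export
read_ifcr_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

FUSION_TABLE_COLS <- c("event_id", "gene_a", "chrom_a", "junction_a",
                       "strand_a", "gene_b", "chrom_b", "junction_b",
                       "strand_b", "fusion_reads")

#' Read and validate a fusion event table
#'
#' Expected columns: event_id, gene_a, chrom_a, junction_a, strand_a,
#' gene_b, chrom_b, junction_b, strand_b, fusion_reads (`NA` to request
#' contig-based fusion-read counting; optional columns `contig_name`
#' and `contig_junction` locate the chimeric junction for that).
#'
#' @param path TSV path.
#' @return data.frame with validated schema.
#' @export
read_fusion_table <- function(path) {
  tab <- read_ifcr_tsv(path)
  miss <- setdiff(FUSION_TABLE_COLS, names(tab))
  if (length(miss))
    stop("fusion table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(tab) > 0) {
    if (any(is.na(tab$junction_a)) || any(is.na(tab$junction_b)) ||
        any(tab$junction_a < 1) || any(tab$junction_b < 1))
      stop("fusion table has invalid junction coordinates", call. = FALSE)
    if (!all(tab$strand_a %in% c("+", "-")) ||
        !all(tab$strand_b %in% c("+", "-")))
      stop("fusion table strands must be '+' or '-'", call. = FALSE)
    neg <- !is.na(tab$fusion_reads) & tab$fusion_reads < 0
    if (any(neg))
      stop("negative fusion_reads for event(s): ",
           paste(tab$event_id[neg], collapse = ", "), call. = FALSE)
  }
  tab
}
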