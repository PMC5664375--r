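#' Aggregate per-cell fusion evidence into a sample-level iFCR
#'
#' Sums fusion-supporting reads and parent-junction overlapping reads
#' across the single-cell libraries of one sample, then applies the iFCR
#' estimator to the summed counts. Summation before division is what
#' makes the estimate a clone-size ratio for the whole sample rather
#' than an average of noisy per-cell ratios.
#'
#' @param cells data.frame of per-cell records with numeric columns
#'   `fusion_reads`, `n_a`, `n_b` (one row per cell; extra columns such
#'   as `cell_id` are ignored). If an `event_id` column is present,
#'   `event` selects the rows to aggregate.
#' @param event Optional event id filter.
#' @return An `ifcr_result` (see [compute_ifcr()]) with the summed
#'   counts attached as attribute `counts`.
#' @export
aggregate_ifcr <- function(cells, event = NULL) {
  cells <- .select_event(cells, event)
  if (nrow(cells) == 0L) stop("no cells to aggregate", call. = FALSE)
  f <- sum(cells$fusion_reads)
  n_a <- sum(cells$n_a)
  n_b <- sum(cells$n_b)
  res <- compute_ifcr(f, n_a, n_b)
  attr(res, "counts") <- c(f = f, n_a = n_a, n_b = n_b)
  res
}

.select_event <- function(cells, event) {
  stopifnot(is.data.frame(cells))
  if (!is.null(event)) {
    if (is.null(cells$event_id))
      stop("cells table has no event_id column to filter on", call. = FALSE)
    cells <- cells[cells$event_id == event, , drop = FALSE]
  }
  cells
}

#' Cell-count "real" ratio of fusion clones to normal clones
#'
#' In single-cell data the subclone ratio can be measured directly from
#' cell counts instead of transcript counts: the number of cells in
#' which the fusion is identified, divided by the number of cells in
#' which both parent genes have nonzero transcript counts. This is the
#' validation quantity that sample-level iFCR is compared against.
#'
#' @param cells data.frame with per-cell columns `fusion_reads` (reads
#'   supporting the fusion in that cell) and parent-gene transcript
#'   counts `gene_a_count`, `gene_b_count`.
#' @param event Optional event id filter (needs an `event_id` column).
#' @param min_fusion_reads Reads required to call the fusion "identified"
#'   in a cell; default 1. Exposed because the original identification is
#'   delegated to a fusion caller whose evidence threshold may differ.
#' @return List with `n_fusion_cells`, `n_parent_cells`, `ratio` (`NA`
#'   with flag `NO_PARENT_CELLS` when no cell expresses both parents)
#'   and `flags`.
#' @export
real_ratio <- function(cells, event = NULL, min_fusion_reads = 1L) {
  cells <- .select_event(cells, event)
  need <- c("fusion_reads", "gene_a_count", "gene_b_count")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cells table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_fus <- sum(cells$fusion_reads >= min_fusion_reads)
  n_par <- sum(cells$gene_a_count > 0 & cells$gene_b_count > 0)
  flags <- character(0)
  ratio <- if (n_par > 0) n_fus / n_par else {
    flags <- "NO_PARENT_CELLS"
    NA_real_
  }
  list(n_fusion_cells = n_fus, n_parent_cells = n_par,
       ratio = ratio, flags = flags)
}

#' Regress log iFCR on the cell-count real ratio across events
#'
#' Fits `log(iFCR_average) ~ real_ratio` over fusion events of one or
#' more samples and reports the Pearson correlation, slope, intercept
#' and the number of events used. Events with undefined or zero
#' iFCR-average (whose log is not finite) or undefined ratio are
#' excluded and counted. Natural logarithm throughout.
#'
#' @param events data.frame with numeric columns `ifcr_average` and
#'   `real_ratio`, one row per event.
#' @return List with `r` (Pearson correlation; `NA` with a warning when
#'   either variable is constant), `slope`, `intercept`, `n`,
#'   `n_excluded`.
#' @export
ifcr_vs_real_ratio <- function(events) {
  stopifnot(is.data.frame(events))
  need <- c("ifcr_average", "real_ratio")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- is.finite(events$ifcr_average) & events$ifcr_average > 0 &
    is.finite(events$real_ratio)
  n_excl <- nrow(events) - sum(ok)
  if (sum(ok) < 3L)
    stop("need at least 3 events with positive iFCR and defined ratio; have ",
         sum(ok), call. = FALSE)
  y <- log(events$ifcr_average[ok])
  x <- events$real_ratio[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("degenerate variance; correlation undefined")
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                n = sum(ok), n_excluded = n_excl))
  }
  fit <- stats::lm(y ~ x)
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = sum(ok), n_excluded = n_excl)
}
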