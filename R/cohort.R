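GROUP_LEVELS <- c("C", "TMPRSS2_ERG", "R", "T", "N")

#' Assign recurrence-based group labels to fusion events
#'
#' Stratifies events into the five-group scheme used for cohort
#' comparison: `C` (cell-line events), `TMPRSS2_ERG` (tumour events
#' whose parent pair is TMPRSS2 + ERG, the most recurrent prostate
#' cancer fusion), `R` (other recurrent tumour events), `T` (remaining
#' tumour events) and `N` (normal-tissue events). Cell lines act as a
#' near-homogeneous positive control and normal tissue as the negative
#' control; recurrence itself is an input annotation taken from the
#' source studies, not computed here.
#'
#' @param events data.frame with columns `gene_a`, `gene_b`,
#'   `sample_class` (`"cell_line"`, `"tumor"` or `"normal"`) and
#'   `recurrent` (0/1 or logical). An `event_id` column, if present, is
#'   used in error messages.
#' @return `events` with a `group` factor column (levels C, TMPRSS2_ERG,
#'   R, T, N) appended. Labels partition the events: every annotated
#'   event gets exactly one.
#' @export
assign_groups <- function(events) {
  stopifnot(is.data.frame(events))
  need <- c("gene_a", "gene_b", "sample_class", "recurrent")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- is.na(events$sample_class) | is.na(events$recurrent) |
    !events$sample_class %in% c("cell_line", "tumor", "normal")
  if (any(bad)) {
    ids <- if (!is.null(events$event_id)) events$event_id[bad] else which(bad)
    stop("missing or invalid annotation for event(s): ",
         paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
  }
  is_te <- mapply(function(a, b) setequal(c(a, b), c("TMPRSS2", "ERG")),
                  events$gene_a, events$gene_b)
  recurrent <- as.logical(events$recurrent)
  lab <- ifelse(events$sample_class == "cell_line", "C",
         ifelse(events$sample_class == "normal", "N",
         ifelse(is_te, "TMPRSS2_ERG",
         ifelse(recurrent, "R", "T"))))
  events$group <- factor(lab, levels = GROUP_LEVELS)
  events
}

#' Compare iFCR distributions between adjacent groups
#'
#' Runs a two-sided two-sample t-test (Welch by default) of the chosen
#' iFCR variant for each adjacent pair of groups in the order C,
#' TMPRSS2_ERG, R, T, N (restricted to groups present in the data), and
#' summarises each group. Undefined iFCR values are excluded and the
#' exclusion count reported; no multiple-testing correction is applied
#' across the pairs.
#'
#' @param events Output of [assign_groups()] with iFCR columns from
#'   [ifcr_table()].
#' @param variant `"average"`, `"max"` or `"min"`.
#' @param var_equal `FALSE` (default) for Welch's unequal-variance test;
#'   `TRUE` for the pooled-variance test.
#' @return List with `comparisons` (data.frame: group1, group2, n1, n2,
#'   t, p_value, tier — tiers `NS`, `10%`, `5%`, `1%` thresholded at
#'   0.10 / 0.05 / 0.01; `NA` statistics when either group has fewer
#'   than 2 usable values), `summary` (per group: n, n_undefined,
#'   median, q1, q3) and `n_excluded`.
#' @export
compare_groups <- function(events, variant = c("average", "max", "min"),
                           var_equal = FALSE) {
  variant <- match.arg(variant)
  col <- paste0("ifcr_", variant)
  if (is.null(events$group))
    stop("events lack a group column; run assign_groups() first", call. = FALSE)
  if (is.null(events[[col]]))
    stop("events lack column ", col, "; run ifcr_table() first", call. = FALSE)

  vals <- split(events[[col]], events$group)
  summ <- do.call(rbind, lapply(names(vals), function(g) {
    v <- vals[[g]]
    ok <- v[is.finite(v)]
    data.frame(group = g, n = length(ok), n_undefined = sum(!is.finite(v)),
               median = if (length(ok)) stats::median(ok) else NA_real_,
               q1 = if (length(ok)) unname(stats::quantile(ok, 0.25)) else NA_real_,
               q3 = if (length(ok)) unname(stats::quantile(ok, 0.75)) else NA_real_)
  }))
  present <- GROUP_LEVELS[GROUP_LEVELS %in% names(vals)[lengths(vals) > 0]]
  comps <- NULL
  if (length(present) >= 2L) {
    comps <- do.call(rbind, lapply(seq_len(length(present) - 1L), function(i) {
      g1 <- present[i]; g2 <- present[i + 1L]
      .group_ttest(vals[[g1]], vals[[g2]], g1, g2, var_equal)
    }))
  }
  list(comparisons = comps, summary = summ,
       n_excluded = sum(!is.finite(events[[col]])))
}

#' Test one pair of groups
#'
#' @inheritParams compare_groups
#' @param group1,group2 Group labels to compare.
#' @return One-row comparison data.frame as in [compare_groups()].
#' @export
test_group_pair <- function(events, group1, group2,
                            variant = c("average", "max", "min"),
                            var_equal = FALSE) {
  variant <- match.arg(variant)
  col <- paste0("ifcr_", variant)
  .group_ttest(events[[col]][events$group == group1],
               events[[col]][events$group == group2],
               group1, group2, var_equal)
}

.group_ttest <- function(x, y, g1, g2, var_equal) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    return(data.frame(group1 = g1, group2 = g2,
                      n1 = length(x), n2 = length(y),
                      t = NA_real_, p_value = NA_real_, tier = NA_character_))
  tt <- stats::t.test(x, y, alternative = "two.sided", var.equal = var_equal)
  p <- tt$p.value
  tier <- if (p < 0.01) "1%" else if (p < 0.05) "5%" else
    if (p < 0.10) "10%" else "NS"
  data.frame(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
             t = unname(tt$statistic), p_value = p, tier = tier)
}

#' Fusion-read vs overlapping-read scatter table
#'
#' Emits a tidy table of fusion-read and overlapping-read counts per
#' event for dot-scatter comparison across sample classes, together with
#' the per-class fraction of events having reads mapped to both parents
#' (n_a > 0 and n_b > 0) — cell lines typically show fewer such events
#' than primary tumours and normal tissue, where wild-type clones
#' dominate.
#'
#' @param events data.frame with `f`, `n_a`, `n_b` and a class column
#'   (`group` if present, else `sample_class`).
#' @return List with `table` (event_id, f, n_a, n_b, overlap_total,
#'   class) and `both_parent_fraction` (class, n_events, n_both,
#'   fraction).
#' @export
read_scatter_table <- function(events) {
  stopifnot(is.data.frame(events))
  need <- c("f", "n_a", "n_b")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cls <- if (!is.null(events$group)) as.character(events$group)
         else if (!is.null(events$sample_class)) events$sample_class
         else rep("all", nrow(events))
  tab <- data.frame(
    event_id = if (!is.null(events$event_id)) events$event_id
               else seq_len(nrow(events)),
    f = events$f, n_a = events$n_a, n_b = events$n_b,
    overlap_total = events$n_a + events$n_b,
    class = cls, stringsAsFactors = FALSE)
  both <- tab$n_a > 0 & tab$n_b > 0
  fr <- do.call(rbind, lapply(split(both, tab$class), function(v)
    data.frame(n_events = length(v), n_both = sum(v),
               fraction = if (length(v)) sum(v) / length(v) else NA_real_)))
  fr <- cbind(data.frame(class = rownames(fr), stringsAsFactors = FALSE), fr)
  rownames(fr) <- NULL
  list(table = tab, both_parent_fraction = fr)
}

#' Pair parent-gene expression with event iFCR
#'
#' One row per event-parent pair, joining each usable event's
#' iFCR-average with the RPKM of its two parent genes, for
#' expression-vs-clone-ratio scatter plots.
#'
#' @param events data.frame with `event_id`, `gene_a`, `gene_b`,
#'   `ifcr_average`; events with undefined iFCR are excluded and counted
#'   in attribute `n_excluded`.
#' @param expression data.frame with `gene_id` and either an `rpkm`
#'   column or the columns `mapped_reads`, `gene_length_bp`,
#'   `library_mapped_reads` from which RPKM is computed.
#' @return data.frame (event_id, gene_id, parent — `"a"`/`"b"` —,
#'   ifcr_average, rpkm, flag) where genes absent from `expression` get
#'   `rpkm = NA` and flag `MISSING_EXPRESSION`.
#' @export
expression_vs_ifcr <- function(events, expression) {
  stopifnot(is.data.frame(events), is.data.frame(expression))
  expression <- .ensure_rpkm(expression)
  ok <- is.finite(events$ifcr_average)
  used <- events[ok, , drop = FALSE]
  long <- rbind(
    data.frame(event_id = used$event_id, gene_id = used$gene_a, parent = "a",
               ifcr_average = used$ifcr_average, stringsAsFactors = FALSE),
    data.frame(event_id = used$event_id, gene_id = used$gene_b, parent = "b",
               ifcr_average = used$ifcr_average, stringsAsFactors = FALSE))
  long <- long[order(match(long$event_id, used$event_id), long$parent), ,
               drop = FALSE]
  idx <- match(long$gene_id, expression$gene_id)
  long$rpkm <- expression$rpkm[idx]
  long$flag <- ifelse(is.na(idx), "MISSING_EXPRESSION", "")
  rownames(long) <- NULL
  attr(long, "n_excluded") <- sum(!ok)
  long
}

.ensure_rpkm <- function(expression) {
  if (!is.null(expression$rpkm)) return(expression)
  need <- c("gene_id", "mapped_reads", "gene_length_bp", "library_mapped_reads")
  miss <- setdiff(need, names(expression))
  if (length(miss))
    stop("expression table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  expression$rpkm <- compute_rpkm(expression$mapped_reads,
                                  expression$gene_length_bp,
                                  expression$library_mapped_reads)
  expression
}

#' Parent-gene expression fold change between paired samples
#'
#' Per-gene RPKM ratio between a tumour sample and its paired
#' counterpart (typically the adjacent normal tissue), used to ask
#' whether a fusion changed its parents' expression.
#'
#' @param tumor,counterpart Expression data.frames (`gene_id` plus
#'   `rpkm` or the raw RPKM components, as in [expression_vs_ifcr()]).
#'   Every tumour gene must be present in `counterpart`.
#' @return data.frame (gene_id, rpkm_tumor, rpkm_counterpart,
#'   fold_change, flag): fold change is `NA` with flag `UNDEFINED` when
#'   the counterpart RPKM is zero.
#' @export
parent_fold_change <- function(tumor, counterpart) {
  tumor <- .ensure_rpkm(tumor)
  counterpart <- .ensure_rpkm(counterpart)
  idx <- match(tumor$gene_id, counterpart$gene_id)
  if (anyNA(idx))
    stop("unpaired gene(s) missing from counterpart sample: ",
         paste(utils::head(tumor$gene_id[is.na(idx)], 10), collapse = ", "),
         call. = FALSE)
  rc <- counterpart$rpkm[idx]
  fc <- ifelse(rc > 0, tumor$rpkm / rc, NA_real_)
  data.frame(gene_id = tumor$gene_id,
             rpkm_tumor = tumor$rpkm,
             rpkm_counterpart = rc,
             fold_change = fc,
             flag = ifelse(rc > 0, "", "UNDEFINED"),
             stringsAsFactors = FALSE)
}
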