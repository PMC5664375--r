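annotated_events <- function() {
  data.frame(
    event_id = c("e1", "e2", "e3", "e4", "e5", "e6"),
    gene_a = c("TMPRSS2", "USP9Y", "ZC3H6", "TMPRSS2", "UPF3A", "ERG"),
    gene_b = c("ERG", "TTTY15", "LRP1B", "ERG", "CDC16", "TMPRSS2"),
    sample_class = c("tumor", "tumor", "tumor", "cell_line", "normal",
                     "tumor"),
    recurrent = c(1L, 1L, 0L, 1L, 0L, 1L),
    stringsAsFactors = FALSE)
}

test_that("group labels follow class, recurrence and the TMPRSS2-ERG pair", {
  g <- assign_groups(annotated_events())
  expect_equal(as.character(g$group),
               c("TMPRSS2_ERG",  # tumor TMPRSS2+ERG
                 "R",            # recurrent tumor fusion (USP9Y-TTTY15)
                 "T",            # non-recurrent tumor
                 "C",            # cell line dominates the gene pair
                 "N",            # normal tissue regardless of recurrence
                 "TMPRSS2_ERG")) # pair matched in either orientation
})

test_that("group assignment partitions all annotated events", {
  set.seed(31)
  n <- 200
  ev <- data.frame(
    event_id = sprintf("x%03d", 1:n),
    gene_a = sample(c("TMPRSS2", "AAA", "BBB"), n, TRUE),
    gene_b = sample(c("ERG", "CCC"), n, TRUE),
    sample_class = sample(c("cell_line", "tumor", "normal"), n, TRUE),
    recurrent = sample(0:1, n, TRUE))
  g <- assign_groups(ev)
  expect_false(anyNA(g$group))
  expect_equal(nrow(g), n)
  # exhaustive and mutually exclusive by construction of a single column
  expect_true(all(levels(g$group) == c("C", "TMPRSS2_ERG", "R", "T", "N")))
  bad <- annotated_events()
  bad$sample_class[2] <- NA
  expect_error(assign_groups(bad), "e2")
})

test_that("identical groups give t = 0 and NS; separated groups reach 1%", {
  ev <- data.frame(
    event_id = sprintf("v%d", 1:6),
    gene_a = "GX", gene_b = "GY",
    sample_class = rep(c("tumor", "normal"), each = 3),
    recurrent = 0L,
    f = 1, n_a = 1, n_b = 1,
    ifcr_average = c(0.5, 0.6, 0.7, 0.5, 0.6, 0.7),
    ifcr_max = 1, ifcr_min = 1)
  ev <- assign_groups(ev)
  cmp <- compare_groups(ev)
  expect_equal(cmp$comparisons$t, 0)
  expect_equal(cmp$comparisons$tier, "NS")
  # clearly separated values: verified against the Welch formulas
  x <- c(0.9, 1.1, 1.0); y <- c(0.01, 0.02, 0.03)
  row <- .subset2(ifcr:::.group_ttest(x, y, "T", "N", FALSE), "p_value")
  ref <- oracle_welch(x, y)
  expect_equal(row, ref$p, tolerance = 1e-12)
  expect_true(ref$p < 0.01)
  ev2 <- ev
  ev2$ifcr_average <- c(x, y)
  cmp2 <- compare_groups(ev2)
  expect_equal(cmp2$comparisons$tier, "1%")
  expect_equal(cmp2$comparisons$p_value, ref$p, tolerance = 1e-12)
})

test_that("p values are symmetric under swapping the groups", {
  set.seed(41)
  x <- rnorm(8, 1); y <- rnorm(5, 0.5)
  a <- ifcr:::.group_ttest(x, y, "A", "B", FALSE)
  b <- ifcr:::.group_ttest(y, x, "B", "A", FALSE)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$t, -b$t)
})

test_that("undersized or undefined groups are reported, not crashed on", {
  ev <- data.frame(
    event_id = c("a", "b", "c"),
    gene_a = "GX", gene_b = "GY",
    sample_class = c("tumor", "tumor", "normal"),
    recurrent = 0L, f = 1, n_a = 1, n_b = 1,
    ifcr_average = c(0.2, NA, 0.1), ifcr_max = 1, ifcr_min = 1)
  ev <- assign_groups(ev)
  cmp <- compare_groups(ev)
  expect_true(is.na(cmp$comparisons$p_value[1]))
  expect_equal(cmp$n_excluded, 1)
  expect_equal(cmp$summary$n_undefined[cmp$summary$group == "T"], 1)
})

test_that("scatter output tallies events with reads on both parents", {
  ev <- data.frame(event_id = c("a", "b", "c", "d"),
                   f = c(5, 3, 2, 8),
                   n_a = c(4, 0, 0, 0), n_b = c(2, 5, 0, 0),
                   sample_class = "tumor")
  sc <- read_scatter_table(ev)
  expect_equal(sc$table$overlap_total, c(6, 5, 0, 0))
  expect_equal(sc$both_parent_fraction$fraction, 0.25)
  ev0 <- ev; ev0$n_a <- 0; ev0$n_b <- 0
  expect_equal(read_scatter_table(ev0)$both_parent_fraction$fraction, 0)
  # brute-force tally on a randomized table
  set.seed(51)
  evr <- data.frame(event_id = sprintf("r%02d", 1:40),
                    f = rpois(40, 3), n_a = rpois(40, 1), n_b = rpois(40, 1),
                    sample_class = sample(c("tumor", "normal"), 40, TRUE))
  fr <- read_scatter_table(evr)$both_parent_fraction
  for (cl in fr$class) {
    sub <- evr[evr$sample_class == cl, ]
    expect_equal(fr$fraction[fr$class == cl],
                 sum(sub$n_a > 0 & sub$n_b > 0) / nrow(sub))
  }
})

test_that("expression joins one row per event-parent and flags gaps", {
  ev <- data.frame(event_id = c("e1", "e2"),
                   gene_a = c("GA", "GB"), gene_b = c("GC", "GD"),
                   ifcr_average = c(0.4, NA))
  expr <- data.frame(gene_id = c("GA", "GC"), rpkm = c(50, 10))
  out <- expression_vs_ifcr(ev, expr)
  expect_equal(nrow(out), 2)       # e2 excluded (undefined iFCR)
  expect_equal(attr(out, "n_excluded"), 1)
  expect_equal(out$ifcr_average, c(0.4, 0.4))
  expect_equal(out$rpkm, c(50, 10))
  # missing expression flagged, not dropped
  expr2 <- data.frame(gene_id = "GA", rpkm = 50)
  out2 <- expression_vs_ifcr(ev, expr2)
  expect_equal(out2$flag, c("", "MISSING_EXPRESSION"))
  # row count oracle on a larger fixture
  set.seed(61)
  evr <- data.frame(event_id = sprintf("e%02d", 1:30),
                    gene_a = sprintf("A%02d", 1:30),
                    gene_b = sprintf("B%02d", 1:30),
                    ifcr_average = c(runif(25), rep(NA, 5)))
  exprr <- data.frame(gene_id = c(evr$gene_a, evr$gene_b),
                      rpkm = runif(60, 0, 100))
  outr <- expression_vs_ifcr(evr, exprr)
  expect_equal(nrow(outr), 2 * 25)
})

test_that("fold change divides paired RPKM and flags zero counterparts", {
  tum <- data.frame(gene_id = c("GA", "GB", "GC"), rpkm = c(10, 7, 4))
  nor <- data.frame(gene_id = c("GA", "GB", "GC"), rpkm = c(5, 7, 0))
  fc <- parent_fold_change(tum, nor)
  expect_equal(fc$fold_change, c(2, 1, NA))
  expect_equal(fc$flag, c("", "", "UNDEFINED"))
  # element-wise division oracle with RPKM computed from components
  set.seed(71)
  genes <- sprintf("G%02d", 1:20)
  tum2 <- data.frame(gene_id = genes, mapped_reads = rpois(20, 500),
                     gene_length_bp = sample(500:5000, 20),
                     library_mapped_reads = 2e6)
  nor2 <- tum2
  nor2$mapped_reads <- rpois(20, 400) + 1
  fc2 <- parent_fold_change(tum2, nor2)
  expect_equal(fc2$fold_change,
               (tum2$mapped_reads / nor2$mapped_reads))
  expect_error(parent_fold_change(tum, nor[1:2, ]), "GC")
})

test_that("simulated cohorts preserve the clone-fraction ordering", {
  ev <- simulate_cohort(n_per_group = 30, depth = 150, seed = 81)
  ev <- assign_groups(ifcr_table(ev))
  cmp <- compare_groups(ev)
  med <- cmp$summary$median[match(c("C", "R", "T", "N"), cmp$summary$group)]
  expect_true(all(diff(med) < 0))
})
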