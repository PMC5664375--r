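---
title: "Estimating fusion subclone size from RNA-seq: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fusion subclone size from RNA-seq: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifcr)
```

## The model

A tumour is treated as a mixture of neoplastic clones. One subclone, at
fraction $p$ of the mixture, carries a gene fusion and transcribes the
chimeric transcript; the remaining clones transcribe the wild-type
transcripts of both parent genes. The quantity of interest is the clone
ratio

$$r = \frac{p}{1 - p},$$

the size of the fusion subclone relative to everything else.

With RNA-seq only, clone sizes are not observable directly. The working
assumption is that the chimeric transcript and the wild-type parent
transcripts are expressed at similar per-cell levels, so relative
transcript abundance is a proxy for relative clone size. A chimeric
transcript is distinguishable from its parents only at the breakpoint
junction, which leads to junction-anchored counting:

- $f_{a,b}$ — *fusion reads*, aligned across the chimeric junction;
- $n_a, n_b$ — *overlapping reads*, aligned across each parent's
  wild-type breakpoint position.

The internal Fusion Clone Ratio is then estimated three ways:

$$\mathrm{iFCR}_{average} = \frac{f_{a,b}}{\mathrm{avg}(n_a, n_b)},\qquad
  \mathrm{iFCR}_{max} = \frac{f_{a,b}}{\min(n_a, n_b)},\qquad
  \mathrm{iFCR}_{min} = \frac{f_{a,b}}{\max(n_a, n_b)}.$$

When all three are defined and $f > 0$,
$\mathrm{iFCR}_{min} \le \mathrm{iFCR}_{average} \le \mathrm{iFCR}_{max}$,
with equality exactly when $n_a = n_b$; the spread between min and max
brackets the estimate when the two parents are captured unequally. Under
the equal-expression assumption all three estimate $r$.

The assumption is strong: fusions frequently arise with copy-number
amplification, promoter swaps change expression of the fused allele, and
parent genes may be regulated differently across clones. The estimator
should be read as a transcript-weighted clone ratio, exact only when
per-cell expression really is balanced; the simulator (below) makes that
regime explicit.

## Zero counts and flags

Real events include parents with *no* overlapping reads, and those are
often the interesting ones (a fusion with no wild-type transcript on one
parent). `compute_ifcr()` therefore never drops a row:

- a variant whose denominator is 0 is `NA` with a flag
  (`ZERO_DENOM_A`/`ZERO_DENOM_B`, or `ALL_ZERO` when both counts are 0);
- $f = 0$ gives 0 for every defined variant, flagged
  `ZERO_FUSION_READS`;
- the average keeps zero terms: $\mathrm{avg}(n_a, 0) = n_a / 2$, so one
  silent parent still yields a finite iFCR-average.

The last point is a documented interpretation rather than an established
convention: whether the average should instead be taken over nonzero
counts only is unspecified in the procedure this estimator descends
from, but reported per-event values with one zero denominator are only
reproducible with zeros retained, so that is the package's behaviour.

## The junction-spanning rule

Coordinates: internally everything is 1-based, and a junction is encoded
as lying *between* reference base $j$ and $j+1$, which removes the
ambiguity of a single-base "breakpoint coordinate". All I/O is 1-based
inclusive.

A read supports a junction when one contiguous aligned stretch carries
at least `min_flank` (default **5**) aligned reference bases at
positions $\le j$ and at least `min_flank` at positions $\ge j+1$.
Consequences of "contiguous aligned stretch":

- spliced reads (CIGAR `N`) qualify only if a single block spans the
  junction; a skip whose boundary coincides with the junction
  disqualifies the read, since it carries no sequence across it;
- deletions (`D`) keep reference coverage contiguous and count toward a
  flank; insertions (`I`) and clips (`S`, `H`) consume no reference and
  do not;
- flanks are measured in genomic (reference) coordinates. Whether the
  original realignment procedure measured spliced flanks in transcript
  coordinates is unknown; genomic is this package's documented choice.

Defaults exposed in `overlap_rule()`: each read end counts
independently (`count_unit = "read"`; `"fragment"` collapses mates by
query name), no duplicate removal, no MAPQ floor. The upstream procedure
applies none of these filters, but library protocols differ, so all
three are parameters rather than constants. Secondary and supplementary
records are always excluded — counting units are primary read ends.

## Chimeric contigs and fusion-read counting

Published fusion-read counts, when available, are taken as given (they
come from the caller that discovered the event). When absent, the
package builds the chimeric contig — the 5' parent's transcript sequence
through its breakpoint joined to the 3' parent's from its breakpoint,
exonic bases only, minus-strand parents reverse-complemented — and
applies the same 5 bp spanning rule at the contig junction. When several
annotated transcripts contain a breakpoint, the one retaining the most
exonic sequence is used (first transcript id on ties) and recorded in
the result.

## RPKM refinement

`ifcr_rpkm_refined()` replaces each raw count by reads per kilobase per
million mapped reads before forming the ratio, making counts
commensurable across windows and libraries. The window for each count is
the span actually scanned around its junction (a read-length-wide
window), not the whole gene: fusion and parent counts then normalise
identically, and with equal windows and one library the refinement
cancels exactly. The refinement is off by default — raw counts are the
primary definition, the RPKM form an optional variant.

## Single-cell aggregation and the real ratio

For a sample sequenced as single cells, per-cell counts are **summed
first** and the estimator applied to the sums; this weights cells by
evidence rather than averaging noisy per-cell ratios.

Single-cell data also supports a direct, transcript-free measurement:
the *real ratio* = (cells in which the fusion is identified) / (cells in
which both parents have nonzero transcript counts). Choices made
explicit:

- "identified" means ≥ `min_fusion_reads` supporting reads in that cell
  (default 1) — the original identification is delegated to a fusion
  caller, so the threshold is a parameter;
- "nonzero transcript counts" uses whole-gene counts, not
  junction-restricted counts (whether the original used gene- or
  junction-level counts is unstated; whole-gene is the more sensitive
  detector of parent expression);
- `ifcr_vs_real_ratio()` regresses $\log(\mathrm{iFCR}_{average})$ on
  the real ratio with the **natural** logarithm, excluding (and
  counting) events whose iFCR is zero or undefined.

## Cohort comparison

Events are stratified by recurrence: cell-line events (`C`, a
near-homogeneous positive control), tumour events whose parents are
TMPRSS2 + ERG (its own group, being the most recurrent prostate-cancer
fusion), other recurrent tumour events (`R`), non-recurrent tumour
events (`T`), and normal-tissue events (`N`, negative control).
Recurrence is an input annotation from the source studies, never
computed.

`compare_groups()` tests each adjacent pair in the order C, TMPRSS2_ERG,
R, T, N with a two-sided two-sample t-test, Welch's unequal-variance
form by default (`var_equal = TRUE` switches to pooled variance; which
flavour, and which pairs, the original analysis used is unstated —
adjacent pairs under Welch is this package's reading). Significance
tiers are 10 % / 5 % / 1 %, with no multiple-testing correction across
the pairs, matching the original presentation. Groups with fewer than
two defined values yield `NA` comparisons rather than errors.

## The simulator

The generator exists so every claim above is testable without external
data. It emulates exactly the model's regime:

- a two-population mixture: fraction $p$ fusion cells expressing only
  the chimeric transcript, fraction $1-p$ wild-type cells expressing
  both parents; equal per-cell expression (`expr_chimeric` =
  `expr_wildtype` = 1). `residual_wildtype` (default 0) lets fusion
  cells retain a fraction of wild-type expression, e.g. an unfused
  allele; at the default the expected iFCR-average is exactly $r$;
- bulk mode draws Poisson junction-read counts with expectations
  `depth * p` (chimeric) and `depth * (1-p)` (each parent), places each
  read uniformly over the start positions compatible with its spanning
  status, and writes pre-aligned SAM plus FASTA/GTF/TSV truth files — no
  aligner in the loop. `background_frac` (default 0.1) adds
  near-junction reads that fail the 5 bp rule, exercising the filter;
- `depth` defaults to 6000 expected spanning reads per junction for a
  full-sample clone. The value is a power choice made at design time: at
  the smallest clone fraction studied ($p = 0.05$) it yields ~300
  expected fusion reads, whose Poisson coefficient of variation (~6 %)
  leaves comfortable margin inside the 15 % recovery band used in
  validation, so recovery failures indicate defects rather than shot
  noise;
- single-cell mode assigns clone identity per cell by Bernoulli($p$)
  with 96 cells per sample by default (the scale of a single-cell
  library plate), ~5 junction reads per cell per expressed junction and
  ~20 whole-gene counts per cell for parent detection;
- the cohort generator uses clone fractions C = 0.9, R = 0.3, T = 0.1,
  N = 0.02. Cell lines are modelled as *near*-homogeneous rather than
  $p = 1$: at exactly 1 no wild-type transcript exists, every
  denominator is zero and the iFCR is undefined, so 0.9 keeps the
  positive control on the estimator's scale while preserving the
  intended ordering. Reads: `depth = 200` per event, typical of a
  moderately expressed locus.

What the simulator does **not** emulate — and what passing its tests
therefore cannot show about real data: sequencing error, misalignment
and multimapping near junctions, fragment-length structure, expression
dispersion between cells beyond Poisson, copy-number amplification of
the fused locus, and chimeric reads partially mapping to parent genes in
single cells (fusion cells contribute nothing to parent counts under the
default model). It validates the estimator's arithmetic and the counting
machinery under the model's own assumptions, not the assumptions
themselves.

## Numerical and degenerate-input choices

- Undefined values propagate as `NA` plus a machine-readable flag
  column; rows are never dropped from output tables.
- Division thresholds are exact zero tests on counts (no epsilon):
  counts are integers or exact Poisson draws.
- `ifcr_vs_real_ratio()` requires ≥ 3 usable events and reports a
  degenerate-variance warning with `NA` correlation when either
  variable is constant.
- Group tests with fewer than 2 defined values per side produce `NA`
  rows. t = 0 on identical groups is reported as `NS`, not an error.
- All simulation is seeded; identical seeds give byte-identical output
  files (no timestamps in results, logs to stderr only).

## Validation problem sizes

The shipped tests validate: the estimator against independent arithmetic
over the full grid $f, n_a, n_b \in \{0..20\}$ (9261 cases); counting
against a brute-force per-read scan over 100 randomized 50-read SAM
fixtures including 4-vs-5 bp flank and splice-boundary edge cases;
clone-ratio recovery at $p \in \{0.05, 0.2, 0.5\}$ over 20 simulated
libraries each (relative error ≤ 15 %); the log-iFCR/real-ratio
correlation over 50 simulated single-cell samples of 96 cells; and the
four-group cohort ordering with 50 events per group. These sizes were
chosen so each check is decisively powered under the generator's
defaults while keeping the suite quick to run.

## Known limitations

- Equal-expression is untestable from a single bulk library; where it
  fails, iFCR is an expression-weighted ratio, not a clone fraction.
- Overlapping-read retrieval depends on the aligner producing spliced
  genomic alignments; junction-adjacent mapping bias (reads lost at
  high divergence or low complexity) biases $n_a, n_b$ downward and the
  iFCR upward.
- iFCR values above ~1 saturate quickly in $p$ ($r \to \infty$ as
  $p \to 1$), so comparisons among near-homogeneous samples are
  rank-stable but not linear.
- The cell-count real ratio requires both parents detectable per cell;
  dropout in shallow single-cell libraries deflates its denominator.
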