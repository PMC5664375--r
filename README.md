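# ifcr

Estimating the relative clonal size of fusion-bearing tumour subpopulations
from RNA-seq alone.

## The problem

Gene fusions are a major class of oncogenic alterations, but deciding which
of the many fusions called in a tumour transcriptome actually matter is
hard. Under the clonal evolution model, a fusion carried by a large
neoplastic subclone is a better oncogene candidate than one confined to a
small clone — yet fusion studies usually have RNA-seq only, with no paired
DNA sequencing from which to reconstruct subclone structure.

The **internal Fusion Clone Ratio (iFCR)** estimates the fusion subclone's
size relative to wild-type clones from transcript evidence alone. The only
part of a chimeric transcript that distinguishes it from its two parent
genes is the breakpoint junction, so the quantities are:

- **fusion reads** *f<sub>a,b</sub>* — reads aligned across the chimeric
  transcript's junction (typically reported by the fusion caller or the
  source publication);
- **overlapping reads** *n<sub>a</sub>*, *n<sub>b</sub>* — reads aligned
  across each parent gene's wild-type breakpoint position, retrieved by a
  realignment scan requiring at least 5 bp of aligned sequence on both
  sides of the junction.

Assuming chimeric and wild-type transcripts are expressed at similar
per-cell levels, the clone-size ratio is estimated three ways:

```
iFCR_average = f_ab / avg(n_a, n_b)
iFCR_max     = f_ab / min(n_a, n_b)
iFCR_min     = f_ab / max(n_a, n_b)
```

The package provides the full workflow around this statistic: SAM/BAM
junction-spanning read counting, chimeric contig construction from
GTF + FASTA, single-cell aggregation with a cell-count "real ratio"
cross-check, recurrence-group cohort comparisons (Welch t-tests), RPKM
expression summaries, and a seeded clone-mixture read simulator that
writes SAM/FASTA/GTF with ground truth, so the whole pipeline can be
exercised and validated without external data.

It is aimed at bioinformaticians doing downstream interpretation of
fusion calls (FusionCatcher, MapSplice, STAR-Fusion, ...) in bulk or
single-cell cancer RNA-seq.

## Worked example

Simulate a tumour in which one third of cells carry a fusion
(clone fraction p = 0.25, so the fusion/wild-type clone ratio is
r = p/(1−p) = 1/3), then recover it from the emitted alignments:

```r
library(ifcr)

sim <- simulate_bulk(clone_mixture_config(p = 0.25, seed = 5))
aln <- read_alignments(sim$paths$sam)
loc <- sim$locus

f   <- count_fusion_reads(aln, list(name = loc$contig_name,
                                    junction_offset = loc$contig_junction))
n_a <- count_overlapping_reads(aln, breakpoint(loc$chrom_a, loc$junction_a))
n_b <- count_overlapping_reads(aln, breakpoint(loc$chrom_b, loc$junction_b))
c(f = f, n_a = n_a, n_b = n_b)
#>    f  n_a  n_b
#> 1518 4526 4445

compute_ifcr(f, n_a, n_b)
#> iFCR  average: 0.3384  max: 0.3415  min: 0.3354
```

1518 fusion reads against ~4500 overlapping reads per parent estimate the
clone ratio at 0.338 — within 2 % of the simulated truth of 1/3. In
single-cell data the estimate can be cross-checked against a ratio built
from cell counts instead of read counts:

```r
ev  <- simulate_cell_events(n_events = 50, seed = 7)
fit <- ifcr_vs_real_ratio(ev)
#> cor: 0.877  slope: 2.355  n: 50
```

The log of the sample-level iFCR tracks the fraction of cells carrying
the fusion across 50 simulated samples.

The same workflow is scriptable from a shell via the bundled CLI
(`system.file("cli", "ifcr.R", package = "ifcr")`) with subcommands
`count`, `ifcr`, `singlecell`, `cohort` and `simulate`; results are TSV
files with a schema comment, logs go to stderr.

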