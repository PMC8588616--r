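# loopwise

Chromatin loops anchored by CTCF hold regulatory neighborhoods together.
When CTCF binding collapses at loop boundaries — as happens upon loss of the
chromatin remodeler ATRX in IDH-mutant glioma — whole loops' worth of genes
can shift expression together. `loopwise` is an R package for asking, in any
two-condition single-cell study, two questions:

1. **Which loops lost boundary binding?** Loops are classified *direct*
   (a condition-specific peak overlaps a boundary anchor), *indirect*
   (the loop span overlaps a direct loop), or *unaffected*.
2. **Which loops changed expression coherently?** For a loop containing
   *L* genes, the member-mean log2 fold-change
   `m = (1/L) Σ_g logFC(g)` is compared against a **sliding-window null**:
   the mean of every run of *L* consecutive genes (in TSS order) on the same
   chromosome. The loop is reported as an empirical percentile,
   `100 · #{window means ≤ m} / n_windows`, so coordinated shifts stand out
   regardless of the genome-wide fold-change distribution. Percentile sets
   are summarized by a Beta distribution fit (method of moments) to their
   inter-quartile range, giving Q-Q coordinates for enrichment diagnostics.

Supporting stages cover scATAC cell QC (fragments > 1000 and promoter ratio
> 0.2, both strict), peak-to-nearest-gene assignment within 25 kb,
differential peak-set subtraction, transposase cut-site meta-profiles
("reads per 10 bp in a 2 kb window"), and ligand–receptor pairing between
cell populations. A seeded synthetic-data generator (negative-binomial
counts, variance `μ + μ²/θ`, with loop-coordinated fold-changes and
condition-specific anchor-peak loss) produces every input format the
pipeline reads, so the whole analysis runs end to end with no downloads.

All coordinates are BED convention (0-based, half-open) throughout.

## Worked example

Simulate a study with ten 2-fold coordinated loops, then run the core
analysis:

```r
library(loopwise)

cfg   <- sim_config(seed = 7, n_effect_loops = 10)
study <- simulate_study(cfg)

lfc    <- cell_averaged_logfc(study$counts, "KO", "WT", "neoplastic")
dpk    <- differential_peaks(study$peaks$wt, study$peaks$ko)
cls    <- classify_loops(study$loops, dpk)
scores <- score_all_loops(study$loops, study$genes, lfc, labels = cls$labels)

head(scores[order(-scores$percentile), ], 5)
#>    loop_id chrom span_start span_end n_genes mean_logfc null_size percentile  label
#>  loop_0008  chr1    4328000  4454000       5  0.8742515       296  100.00000 direct
#>  loop_0029  chr2    7748000  7874000       5  0.8999358       296  100.00000 direct
#>  loop_0039  chr3    6848000  6974000       5  0.8649085       296  100.00000 direct
#>  loop_0050  chr4    2708000  2834000       5  0.9641070       296  100.00000 direct
#>  loop_0003  chr1    1988000  2114000       5  0.7813723       296   99.66216 direct

unlist(cls$summary$counts)
#>     direct   indirect unaffected
#>         16          0         44
```

Every top-scoring loop is a designated effect loop (`study$truth$effect_loops`),
its member-mean log2 fold-change sits near the injected `log2(2) = 1` (shrunk
slightly by the pseudocount), and each carries a lost boundary peak, hence
`direct`. The 16 direct loops are the 10 effect loops plus anchors lost at
random (`anchor_peak_loss_frac = 0.1`).

The same stages run from files via `run_pipeline(pipeline_config(indir, outdir))`
or the thin CLI in `inst/scripts/loopwise.R`
(`loopwise.R simulate|run-all|qc|logfc|classify|score|qq|pairs|profile`).

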