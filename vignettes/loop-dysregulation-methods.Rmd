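---
title: "Scoring coordinated loop-wide expression change against a sliding-window genomic null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring coordinated loop-wide expression change against a sliding-window genomic null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopwise)
```

## The question and the statistic

CTCF-anchored chromatin loops delimit regulatory neighborhoods. If a
perturbation (here the motivating case is ATRX loss in IDH-mutant glioma)
depletes CTCF from loop boundaries, genes inside affected loops may move
together rather than independently. `loopwise` measures that coordination.

For each gene the input signal is a **cell-averaged log2 fold-change**
between two conditions. For a loop whose span contains $L$ gene TSSs, the
loop statistic is the member mean
$m = \frac{1}{L}\sum_{g \in \text{loop}} \mathrm{logFC}(g).$
Its reference distribution is the **sliding-window null**: the mean of every
run of $L$ consecutive genes, in ascending TSS order, on the loop's own
chromosome — $n - L + 1$ values for a chromosome with $n$ scored genes,
retained with multiplicity. The loop is then reported as the empirical
percentile
$P = 100 \cdot \frac{\#\{\text{window means} \le m\}}{n_\text{windows}}.$

This design conditions on chromosome and on loop size (in genes), so it is
insensitive to chromosome-scale expression shifts and to the genome-wide
fold-change distribution. It is exactly shift-invariant: adding a constant
to every gene's logFC changes no percentile (a property the test suite
checks to $10^{-12}$).

Orthogonally, loops are classified from peak evidence: **direct** if a
condition-specific (differential) peak overlaps either boundary anchor,
**indirect** if the loop's span overlaps a direct loop's span, otherwise
**unaffected**. Labels are mutually exclusive with precedence
direct > indirect, and indirectness deliberately does not chain — a loop
touching only indirect loops stays unaffected, which keeps the two affected
categories an interpretable two-part accounting.

## The fold-change estimator

The per-gene signal is deliberately simple and deterministic: each cell is
depth-normalized to a fixed library size (default 10,000 counts), condition
means are taken per gene within one cell population, and
$\mathrm{logFC}(g) = \log_2\frac{\bar{x}_{\text{num}}(g) + c}{\bar{x}_{\text{den}}(g) + c}$
with pseudocount $c = 1$ on the normalized scale. A hurdle or mixed model
would give calibrated per-gene significance, but the loop statistic consumes
only a signed per-gene effect size, and the ratio-of-means estimator is
exactly antisymmetric under swapping conditions and invariant under common
depth rescaling — both properties the suite asserts at machine precision.

Two estimator caveats worth knowing:

* The pseudocount shrinks $|\mathrm{logFC}|$ toward zero when normalized
  means are small (a gene at normalized mean 5 under a true 2-fold effect
  reads $\log_2(11/6) \approx 0.87$, not 1). Percentiles are barely affected
  because null windows shrink comparably, but absolute loop means should be
  read with this in mind.
* Depth normalization is compositional: a large mass of up-regulated genes
  depresses everyone else's apparent fold-change by a common factor. The
  percentile representation absorbs exactly this kind of common shift.

The log base (2) and the pseudocount are recorded in the metadata header of
the written fold-change table.

## Numerical and tie-breaking choices

* **Ties count as ≤.** The percentile uses the weak inequality of the
  empirical CDF. With all fold-changes equal, every loop scores 100 — a
  degenerate but well-defined answer.
* **The loop's own window is part of its null** (default). Nothing in the
  construction excludes it, and keeping it bounds the percentile below by
  $100/n_\text{windows}$, preventing spurious "perfect" scores on short
  chromosomes. `include_own_window = FALSE` removes exactly one occurrence
  for users who prefer an exclusive null; the choice is echoed in the score
  output.
* **Window means and loop means are computed by the same `mean()` over the
  same vector slices**, so the own-window tie is bit-exact and oracle
  comparisons in the tests can demand identity rather than tolerance.
* **Gene order is ascending TSS**, strand-aware (`end − 1` on the minus
  strand), with gene id as the deterministic tie-break; all interval sorting
  uses radix (C-locale) ordering so results do not depend on the session
  locale.
* **Nearest-gene distance** is the gap between half-open intervals (0 for
  overlapping or abutting), strand ignored, ties broken by smallest gene
  id; the 25 kb cutoff is inclusive.
* **Windows never wrap** chromosome ends; a loop with more genes than its
  chromosome has scored genes is a hard error naming both.
* **Degenerate inputs**: loops with fewer than `min_genes` (default 2)
  resolvable members are skipped with a logged reason, not an error; an
  empty eligible set yields an empty table plus a warning.

## Beta Q-Q diagnostics

Under a well-calibrated null, loop percentiles divided by 100 are
approximately uniform, i.e. Beta(1, 1). `fit_beta_iqr()` restricts the
percentile sample to its own inter-quartile range, rescales that subsample
linearly onto $[0, 1]$, and fits a Beta by method of moments
($k = m(1-m)/v - 1$, $\alpha = mk$, $\beta = (1-m)k$). Fitting only the
central half makes the shape parameters insensitive to the enriched tails
that are the finding, while the Q-Q points (Beta quantiles at plotting
positions $(i - 0.5)/n$ against all sorted observed values) make those tails
visible. Method of moments is used because it is deterministic and
parameter-free; the alternative reading — matching Beta quantiles to the
sample IQR — is a two-parameter fit to two numbers and was rejected as
under-determined. Constant or near-constant percentile vectors (fewer than
8 distinct values, or zero variance inside the IQR) raise a "degenerate
percentile distribution" error rather than returning meaningless shapes.

## Cut-site meta-profiles

"Reads per 10 bp" around a reference point is computed from transposase cut
sites: both ends of each fragment (`start` and `end − 1`) are binned in a
window of ±1000 bp around each site's midpoint, 10 bp per bin. Cut-site
counting is the standard footprint view for ATAC/CUT&Tag; a whole-fragment
`"coverage"` mode is available by flag. Minus-strand sites have their bins
reversed (so rows read 5′→3′) unless orientation is disabled; overlapping
site windows each count the same fragment, matching per-site heatmap
semantics. The companion moving average (default span 5 bins) truncates at
the edges rather than padding.

## Ligand–receptor pairing

`detect_pairs()` calls a pair "expressed in both" populations when the
ligand's and receptor's detection fractions (cells with count > 0) each
reach `min_frac` (default 0.10). A detection-fraction rule was chosen over a
mean-expression cutoff because it is scale-free and monotone in the
threshold (raising `min_frac` can only shrink the set — a property under
test). The rule and threshold are attached to the result as metadata.

## What the generator emulates — and what it does not

`sim_config()` defines the synthetic study in one place; every generator is
a pure function of it (same config ⇒ byte-identical files).

| parameter | default | meaning |
|---|---|---|
| `genes_per_chrom` × `n_chroms` | 300 × 4 | evenly spaced genes, 30 kb apart |
| `n_loops`, `genes_per_loop` | 60, 5 | non-overlapping blocks of consecutive genes, ≥1 spacer gene apart, 2 kb anchors flanking the first/last member |
| `n_effect_loops`, `fold_change` | 10, 2 | member genes of effect loops multiplied in the second condition |
| `n_cells_per_condition` | 200 | a typical well-powered per-sample population |
| `mean_depth` | 7200 | expected counts/cell (≈6 per gene, a shallow 10x-like depth) |
| `dispersion` | 0.5 | NB size θ; variance μ + μ²/θ, strongly overdispersed |
| `mean_sdlog`, `cell_depth_sdlog` | 0.5, 0.2 | log-normal gene-abundance and cell-depth variation |
| `anchor_peak_loss_frac` | 0.1 | random anchor loss in condition 2; effect-loop anchors always lost |
| `fragment_enrichment` | 8 | site:background mixture weight (e−1)/e; Gaussian sd 50 bp pile-ups |

The coordinated effect is multiplicative and uniform across a loop's
members — the cleanest version of the biological claim under test. Real
data differ in ways the generator deliberately omits: genes are not evenly
spaced, loops overlap and nest, effects within a loop are heterogeneous,
counts carry batch structure, doublets and ambient RNA, and boundary peaks
can shift rather than vanish. Passing the package's recovery tests
therefore demonstrates that the *statistic and its implementation* behave
as designed under the assumed model, not that any particular biological
dataset will separate as cleanly.

## Test and acceptance problem sizes

The suite exercises the statistic at the scales it is designed for while
staying laptop-fast: oracle equivalence on 100 random instances of ≤60
genes and ≤10 loops (checked for exact equality against naive enumeration);
calibration on a 500-loop, 3000-gene, 400-cell no-effect study (mean
percentile expected in [45, 55], ≥95 tail in [1%, 10%]); and recovery on a
150-loop study with 50 two-fold loops (recall at percentile ≥95 expected
≥80%, null false positives ≤10%, all effect loops classified direct).
`scripts/acceptance.R` reruns the calibration and recovery studies from
scratch for any seed and writes the measured rates as JSON.

## Pipeline reproducibility

`run_pipeline()` executes qc → logfc → diffpeaks → classify → score → qq
(→ pairs, profile) from files, writing one table per stage plus a
`summary.json` that echoes the full configuration, its md5 hash, and the
package version. Progress messages on stderr carry timestamps; the run-log
file does not, so two runs of an identical configuration produce
byte-identical run directories — an invariant the test suite asserts with
checksums.

## Known limitations

* Loop membership is TSS-in-span; genes whose bodies straddle a boundary
  but start outside are not members.
* The sliding-window null preserves local gene order but not inter-gene
  correlation structure beyond what windows capture; strongly clustered
  gene families inflate null variance rather than invalidating it.
* Differential peaks are presence/absence by ≥1 bp overlap (configurable
  minimum overlap); there is no signal-strength test.
* Empirical two-sided p-values and BH q-values are available behind a flag
  but the percentile is the primary, and only calibrated, output.
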