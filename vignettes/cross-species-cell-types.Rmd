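---
title: "Comparing cell-type-specific expression within and across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing cell-type-specific expression within and across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthocell)
```

# The problem

Sorted-nuclei RNA-seq makes it possible to profile classically defined
neuronal and glial populations — cerebellar granule cells, basket cells,
astrocytes, oligodendrocytes — in species where transgenic labeling is
impossible, including postmortem human tissue. Two questions drive the
analyses this package implements:

1. **Within a species**: which genes are *specific* to a cell type, given
   biological replicates of each sorted population?
2. **Across species**: restricted to genes whose orthology is unambiguous,
   which genes have gained or lost expression in a cell type between, say,
   mouse and human — and are those differences corroborated by independent
   single-nucleus data and by chromatin accessibility and sequence
   conservation at their promoters?

Every stage is a deterministic, seeded function, and the package ships
generators that produce inputs with *planted* ground truth so each stage can
be benchmarked offline (sensitivity, precision, calibration) without any
sequencing data.

# The Specificity Index

For gene $g$ and target cell type $A$, expression is summarized per cell
type as the mean $m_{g,A}$ and standard deviation $s_{g,A}$ of floored
$\log_{10}(\mathrm{FPKM})$ across replicates. FPKM uses whole-gene lengths
(UTRs included) so long genes are not inflated by transcript annotation
differences; values of $\log_{10}(\mathrm{FPKM})$ below 0 are set to 0 so
long, unexpressed genes cannot dominate; genes under 1 kb are excluded to
avoid short-gene artifacts. FPKM normalization uses the full library before
the short-gene exclusion, so removing short genes does not perturb the
per-sample totals.

The deterministic index is a rank statistic: for each other cell type $B$,
genes are ranked by the difference $m_{g,A} - m_{g,B}$ in descending order
(rank 1 = most enriched toward $A$; ties get average ranks), and
$\mathrm{SI}(g, A)$ is the mean of $g$'s ranks over all $B \ne A$. The
*specificity rank* orders genes by ascending SI. Ranking the log-space
difference is equivalent to ranking the expression ratio and is safe at the
floor, where ratios are undefined. Because the index defers to rank
positions, it needs no distributional assumptions beyond exchangeability of
the comparison.

Replicate noise is propagated by resampling: in each of `iterations`
(default 1000) rounds, one value per (gene, cell type) is drawn from
$N(m_{g,A}, s_{g,A})$, draws are re-floored at 0 to stay on the support of
the inputs, the deterministic index is computed, and the specificity ranks
are averaged over rounds. Averaging the *rank* rather than the SI value
makes the output robust to a single extreme draw. With all $s = 0$ the
sampled index collapses exactly to the deterministic one (the test suite
asserts this identity), so the deterministic path is the degenerate case,
not a separate code path. Each iteration draws from its own named substream
of the seed, so results are independent of iteration order or batching.

Two points were genuinely open and decided here: ranks are computed over
*all retained genes*, not only expressed ones (retention is already
controlled by the length filter and the flooring), and negative draws are
floored rather than kept, because the floored input scale has no support
below zero. Both choices are surfaced in the documentation rather than
hidden.

# Ortholog harmonization

Cross-species comparisons are restricted to a high-confidence 1:1 gene
universe built by five filters applied in a fixed order: (1) remove rows
with any zero-confidence ortholog pair; (2) remove exact duplicate rows;
(3) enforce strict 1:1 orthology at the *transcript* level — any transcript
annotated as orthologous to more than one transcript in another species is
an offender, and every row touching an offender is removed; (4) collapse
rows to gene tuples, taking each gene's longest transcript as its
annotation — tuples that would leave a gene in more than one tuple are
dropped as ambiguous (a situation strict transcript-level 1:1 does not by
itself exclude); (5) remove tuples whose whole-gene genomic lengths differ
by more than two-fold across species or fall below 1 kb in any species.

Boundary semantics are deliberate: a length ratio of exactly 2 and a length
of exactly 1000 bp are both retained ("more than two-fold" and "smaller
than 1 kb" are strict inequalities). The audit log records the rows or
tuples removed at every step, so the effect of filter order is inspectable;
the whole cascade is idempotent, and the test suite checks the survivor set
against an independent set-theoretic oracle on hundreds of randomized
tables.

# The differential-expression engine

The engine is an intentionally transparent negative-binomial Wald test, not
a reimplementation of a shrinkage-based package:

* **Size factors** are median-of-ratios: the reference is the per-gene
  geometric mean over samples (genes with any zero excluded from the
  reference), and each sample's factor is the median count/reference ratio.
* **Dispersion** is method-of-moments around the design fit of normalized
  counts, per gene, floored at $10^{-8}$ and capped at 10, with no shrinkage
  and no outlier refitting.
* **The model** is a per-gene NB log-link regression with the log size
  factor as offset. For a plain two-group contrast the group means have a
  one-dimensional profile score equation, solved by vectorized Fisher
  scoring across all genes simultaneously; general designs (continuous
  covariates such as donor age in years or post-mortem delay in hours, used
  in raw units; additive blocking factors such as cell type) go through a
  per-gene GLM fit. Confounded designs are rejected by a rank check before
  any fitting.
* **Inference**: the Wald statistic for the contrast coefficient is
  referred to a *t* distribution with residual degrees of freedom
  ($n - p$). With moment-based plug-in dispersion the normal reference is
  anti-conservative at realistic replicate numbers; the residual-df *t* is
  the standard small-sample correction for estimated-variance Wald tests
  and restores null calibration (the acceptance suite checks a rejection
  rate of 0.05 ± 0.015 at $n = 8$ vs 8 over 2000 genes). Genes with no
  counts are reported with `NA` and excluded from the Benjamini–Hochberg
  adjustment.

The downstream threshold cascades only consume the table columns
(`base_mean`, `log2fc`, `pvalue`, `padj`), so DE tables computed by other
engines can be substituted directly.

Exploratory summaries follow common practice: `log2(normalized + 1)` as the
variance-stabilizing transform (a monotone transform is all that
clustering, correlations and PCA require), the top 250 most variable genes
for clustering (Euclidean distance, complete linkage; variable genes carry
the cell-type signal, while whole-transcriptome correlations between
related cell types are high), and centered, unscaled PCA returning both
scores and loadings so the genes driving a component can be listed.

# Species-enrichment calls and the housekeeping set

A gene is called enriched in species $S$ within a cell type iff all of:
adjusted $p < \alpha_1$; $|\log_2 \mathrm{FC}| \ge 2$ (at least 4-fold,
inclusive) with the sign toward $S$; mean normalized counts
(`base_mean`) > 400; and mean $\log_2(\mathrm{FPKM}) > 4$ in the
higher-expressing species. Genes that are species-biased *everywhere* —
significant at $\alpha_1$ with fold change > 2 (strict, i.e.
$|\log_2\mathrm{FC}| > 1$) in the all-cell-types contrast, with no
expression cutoff — are removed, leaving cell-type-specific species
differences. $\alpha_1$ defaults to $10^{-5}$; the source convention
"10e-5" is typographically ambiguous between $10^{-4}$ and $10^{-5}$, so
the stringent reading is the default and the threshold is a config value.
The pooled pan-species contrast uses cell type as an additive blocking
covariate.

The housekeeping reference set — used as the conservation baseline — is the
complement in spirit: raw $p > 0.2$ (raw, not adjusted: the set is defined
by *absence* of evidence at a lenient bar), `base_mean` > 400, and mean
$\log_2(\mathrm{FPKM}) > 4$ in every species.

## The donor-partition null

To ask whether a subgroup of donors with many DE genes could arise by
chance, the package enumerates *all* $\binom{n}{k}$ ways of splitting $n$
donors into groups of $k$ and $n-k$ (560 for 16 donors split 3 vs 13), runs
the two-group NB test for each split, and records the DE count at
adjusted $p < 0.01$. On homogeneous data the distribution hugs zero; a real
3-donor induction shows up as its own partition attaining the unique
maximum. The exhaustive enumeration is feasible because the two-group fast
path is vectorized across genes (all 560 partitions of a 2000-gene, 16-
sample matrix run in seconds).

# Single-nucleus validation

Bulk-derived gene sets are validated against single-nucleus/cell matrices
with the field's standard steps: genes detected in fewer than 3 cells and
cells with fewer than 300 or more than 5000 detected genes are removed
(boundaries inclusive for retention; gene filter first, applied once, not
iterated); expression is normalized per cell by global scaling
(`ln(1 + count/total × 10000)`, natural log — the stated toolchain's
convention, configurable); and each gene × cluster is summarized by mean
normalized expression and the *detection proportion*, the fraction of cells
strictly above a threshold (default 1.0). Distributions for two gene sets
(e.g. human-enriched vs mouse-enriched genes in a human cluster) are
compared by ECDFs with a two-sample Kolmogorov–Smirnov test; the source
analysis did not name its test, so KS is a documented choice here, not an
inherited one.

Sequencing-depth sensitivity uses multivariate hypergeometric downsampling
(reads drawn without replacement to each target depth — the exact model of
read subsampling, unlike binomial thinning), TPM recomputed with whole-gene
lengths, and a gene counted as expressed iff $\log_2(\mathrm{TPM}+1) >
1.1$, i.e. TPM > $2^{1.1}-1 \approx 1.143$.

# Peaks and conservation

Promoter peaks are accessible-chromatin intervals overlapping the window
from 1 kb upstream to 100 bp downstream of the TSS; the one-time
translation to the package's 0-based half-open convention makes the window
`[tss − 1000, tss + 101)` on the plus strand, mirrored on minus, 1101 bp
wide, clipped at contig start. Gene-body peaks overlap the whole-gene span
but no promoter window; everything else is `other`. Ties (a peak touching
two windows or genes) resolve by nearest TSS, then largest overlap for gene
bodies, then lexicographic gene id — determinism where the convention is
otherwise unspecified. The TSS used is that of the gene span (equivalently,
of the chosen longest transcript).

Per-peak conservation is the arithmetic mean of per-base scores in
`[0, 1]`; bases not covered by any track run score 0, the common convention
for missing PhastCons values, recorded here explicitly. Gene-group
comparisons use a one-sided Welch (unequal-variance) *t*-test with group
medians reported; identical constant groups return $p = 0.5$ by convention.
Metagene profiles rescale each peak to unit length over `n_bins` fractional
bins. Differentially accessible peaks are filtered at strictly greater than
two-fold (the fold estimate itself is consumed as input). SNPs are 1-bp
intervals; containment is half-open (`start <= pos < end`).

# What the generators emulate — and what they do not

`simulate_bulk_counts()` draws NB counts with mean `baseline × size factor
× 2^(planted effects)`:

| parameter | default | rationale |
|---|---|---|
| genes | 2000 | enough for stable FDR behavior, small enough for seconds-scale tests |
| design | 2 species × 3 cell types × 8 replicates | between the rodent and 16-donor human arms of such studies; gives the power the $\alpha_1 = 10^{-5}$ cascade presupposes |
| baseline | log-normal, median 300 counts | typical sorted-population library at desk scale |
| dispersion | log-normal, median 0.05 | biological-replicate NB dispersion typical of bulk RNA-seq |
| size factors | uniform 0.7–1.4 | moderate depth variation |
| species fold | 8 (log2 = 3) | comfortably above the 4-fold call threshold, so recovery tests measure method error, not threshold boundary effects |
| planted classes | markers, species-enriched (50/cell type), pan-species, housekeeping, nulls | one class per predicate of the calling cascade |

`simulate_single_cell()` uses log-normal library sizes and per-(gene, cell)
Bernoulli dropout — the simplest structure that reproduces
detection-proportion behavior — plus cells and genes engineered to violate
the quality filters, tagged in truth. `simulate_peaks_and_conservation()`
places promoter peaks inside the promoter windows of genes expressed in the
focal population and draws conservation so species-enriched genes' peaks
average `contrast` lower than housekeeping peaks.
`simulate_ortholog_table()` plants each harmonization violation at a
requested fraction and computes the surviving tuples by direct predicate
evaluation.

None of the generators simulate batch effects, GC or length biases,
isoform-level signal, ambient RNA, doublets, or realistic genome sequence.
A passing recovery test therefore shows that the *procedures* are correct
and calibrated under their own assumptions — it does not certify
performance on real libraries, where those nuisances exist.

# Numerical choices and degenerate inputs

* Dispersion floor $10^{-8}$ / cap 10 stabilize Wald standard errors at
  Poisson-like and at pathological genes respectively.
* The two-group Fisher scoring clamps group means to
  $[10^{-8}, 10^{12}]$; a group with all-zero counts lands on the floor and
  yields an enormous standard error, i.e. no significance — the honest
  answer absent shrinkage.
* Variable-gene selection and top-specific-gene lists break ties by
  lexicographic gene id, so outputs are reproducible across platforms.
* All generators and the sampled SI derive per-stage seeds from one user
  seed through named substreams; the pipeline manifest records the seed,
  thresholds and input/output checksums, and a rerun is byte-identical.
* Problem sizes in the test and acceptance runs (2000-gene fixtures, 16
  donors, 20 SI iterations in the marker-recovery property, 560-partition
  nulls) were chosen so the full suite completes in minutes on one CPU
  while leaving each statistical check adequately powered; the SI iteration
  default for real analyses remains 1000.

# Known limitations

* The DE engine deliberately omits dispersion shrinkage, independent
  filtering and outlier handling; with very few replicates its
  moment-based dispersions are noisy, and the $\alpha_1 = 10^{-5}$ cascade
  should then be read as conservative.
* The variance-stabilizing transform is `log2(norm + 1)`, not a
  regularized log; it is adequate for clustering and PCA but not for
  mean-variance-sensitive downstream modeling.
* Harmonization trusts the input orthology table; it filters but does not
  infer homology.
* Peak-level analysis consumes called peaks, per-base coverage and
  fold-change estimates; peak calling, blacklist curation and
  differential-accessibility estimation are out of scope.
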