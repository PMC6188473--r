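# orthocell

Comparing classically defined neuronal and glial cell types **within and
across species** from sorted-nuclei RNA-seq, with single-nucleus and
chromatin-accessibility validation. The package implements, as tested
reusable functions:

* a replicate-aware **Specificity Index**: per cell type $A$ and gene $g$,
  $\mathrm{SI}(g,A)$ is the mean over other cell types $B$ of the
  descending rank of $m_{g,A}-m_{g,B}$ (floored $\log_{10}$ FPKM means);
  replicate noise is propagated by drawing from
  $N(m_{g,\cdot}, s_{g,\cdot})$ over many iterations and averaging the
  specificity ranks;
* **1:1 ortholog harmonization**: confidence, duplicate, strict
  transcript-level 1:1, two-fold length-ratio and 1 kb filters with a
  per-step audit log;
* a transparent **negative-binomial Wald DE engine** (median-of-ratios size
  factors, method-of-moments dispersion, residual-df *t* reference,
  Benjamini–Hochberg adjustment) supporting factor contrasts, continuous
  covariates (age, post-mortem delay) and blocking;
* the **species-enrichment cascade** (padj < 10⁻⁵, ≥ 4-fold, baseMean >
  400, log₂ FPKM > 4 in the higher species, pan-species exclusion) and the
  **housekeeping** reference set (raw p > 0.2, same expression cutoffs);
* the exhaustive **donor-partition resampling null** (all C(n, k) splits,
  e.g. 560 for 16 donors split 3 vs 13);
* **single-nucleus validation**: detected-gene filters (< 3 cells, < 300 or
  > 5000 genes), global-scaling normalization, per-cluster detection
  proportions, ECDF/KS comparisons, hypergeometric depth-downsampling
  curves;
* **peak annotation and conservation**: strand-aware promoter windows
  (−1 kb…+100 bp of the TSS), per-peak mean conservation, one-sided Welch
  group comparisons, metagene profiles, > 2-fold differential-peak filter,
  SNP–peak intersection;
* **synthetic-data generators** with planted ground truth for every one of
  the above, and a seeded end-to-end pipeline (`run_pipeline()`) with a
  checksummed manifest.

## Worked example

Simulate the default cross-species study (2 species × 3 cell types × 8
replicates, 2000 genes, 50 planted 8-fold species-enriched genes per cell
type), run the per-cell-type and pooled species contrasts, and call
species-enriched genes:

```r
library(orthocell)

cfg <- sim_config(seed = 7)
b   <- simulate_bulk_counts(cfg)
lens <- setNames(b$models$genes$length_bp, b$models$genes$gene_id)
sf   <- size_factors(b$counts)

de_ct <- list(); lf_ct <- list()
for (ct in cfg$cell_types) {
  j <- b$samples$cell_type == ct
  de_ct[[ct]] <- nb_wald_test(b$counts[, j], b$samples[j, ], test = "species",
                              contrast = c("human", "mouse"), sf = sf[j])
  lf_ct[[ct]] <- mean_log2_fpkm(b$counts[, j], lens, b$samples$species[j])
}
de_pan <- nb_wald_test(b$counts, b$samples, test = "species",
                       contrast = c("human", "mouse"),
                       blocking = "cell_type", sf = sf)
call_species_enriched(de_ct, lf_ct, de_pan)
#> Species-enrichment calls
#>   granule: 25 human-enriched, 25 mouse-enriched
#>   basket: 25 human-enriched, 24 mouse-enriched
#>   glia: 25 human-enriched, 24 mouse-enriched
#>   pan-species excluded: 50 genes
```

The generator planted 25 human- and 25 mouse-enriched genes per cell type;
the cascade recovers 148 of the 150 (the `calls$calls` table carries each
gene's triggering statistics), and all 50 planted pan-species genes are
excluded. The Specificity Index on the human samples ranks the planted
granule markers and human-granule-enriched genes at the top for granule
cells:

```r
inp <- si_preprocess(b$counts[, b$samples$species == "human"], lens,
                     b$samples$cell_type[b$samples$species == "human"])
tb  <- si_sampled(inp, iterations = 100, seed = 1)
top_specific_genes(tb, "granule", k = 5)
#> [1] "g01347" "g00183" "g00641" "g00565" "g01225"
b$truth[match(top_specific_genes(tb, "granule", 5), b$truth$gene_id),
        c("class", "cell_type")]
#>               class cell_type
#> 1347         marker   granule
#> 183  species_enriched  granule
#> 641  species_enriched  granule
#> 565          marker   granule
#> 1225 species_enriched  granule
```

A complete fixture directory (per-species counts and gene models, ortholog
table with planted violations, peaks, conservation bedGraph, truth tables)
is written by `simulate_fixture()`, and `run_pipeline()` executes
harmonization → DE → SI → enrichment (plus optional partition-null and
conservation stages) from a YAML or list config, reproducibly under a
single seed.

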