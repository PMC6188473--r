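test_that("gene model generator honors its construction guarantees", {
  gm <- simulate_gene_models(100, seed = 1)
  expect_equal(nrow(gm$genes), 100)
  expect_true(any(gm$genes$length_bp < 1000))
  expect_setequal(unique(gm$genes$strand), c("+", "-"))
  # longest transcript spans the gene
  sp <- split(gm$transcripts, gm$transcripts$gene_id)
  for (g in sp[1:10]) {
    gi <- gm$genes[gm$genes$gene_id == g$gene_id[1], ]
    expect_true(any(g$start == gi$start & g$end == gi$end))
  }
  expect_identical(simulate_gene_models(100, seed = 1),
                   simulate_gene_models(100, seed = 1))
  expect_error(simulate_gene_models(0), "n_genes")
})

test_that("ortholog generator: clean tables survive, saturated tables do not", {
  ms <- list(mouse = simulate_gene_models(50, seed = 2, prefix = "m"),
             human = simulate_gene_models(50, seed = 3, prefix = "h"))
  clean <- simulate_ortholog_table(ms, 0, 0, 0, 0, seed = 4)
  expect_true(all(clean$truth$survives))
  expect_equal(nrow(harmonize(clean$table, ms)), nrow(unique(clean$table)))

  allbad <- simulate_ortholog_table(ms, frac_low_conf = 1, seed = 4)
  expect_false(any(allbad$truth$survives))
  expect_equal(nrow(harmonize(allbad$table, ms)), 0)

  expect_error(simulate_ortholog_table(ms, frac_low_conf = 1.2), "fractions")
  expect_identical(simulate_ortholog_table(ms, 0.1, 0.1, 0.1, 0.1, seed = 9),
                   simulate_ortholog_table(ms, 0.1, 0.1, 0.1, 0.1, seed = 9))
})

test_that("bulk generator plants the advertised effect sizes", {
  cfg <- sim_config(n_genes = 800, cell_types = c("granule", "basket"),
                    replicates = 16, size_factor_range = c(1, 1), seed = 10)
  b <- simulate_bulk_counts(cfg)
  expect_identical(b$counts, simulate_bulk_counts(cfg)$counts)

  tr <- b$truth
  sp <- which(tr$class == "species_enriched")
  lr_sp <- vapply(sp, function(g) {
    hi <- b$samples$species == tr$species[g] &
      b$samples$cell_type == tr$cell_type[g]
    lo <- b$samples$species != tr$species[g] &
      b$samples$cell_type == tr$cell_type[g]
    log2(mean(b$counts[g, hi]) / mean(b$counts[g, lo]))
  }, numeric(1))
  expect_equal(mean(lr_sp), 3, tolerance = 0.1)

  mk <- which(tr$class == "marker")
  lr_mk <- vapply(mk, function(g) {
    own <- b$samples$cell_type == tr$cell_type[g]
    log2(mean(b$counts[g, own]) / mean(b$counts[g, !own]))
  }, numeric(1))
  expect_equal(mean(lr_mk), 3, tolerance = 0.1)
  # near-degenerate generator: tiny dispersion, no effects, unit size factors
  cfg0 <- sim_config(n_genes = 300, cell_types = "granule", replicates = 8,
                     frac_marker = 0, frac_species = 0, frac_pan = 0,
                     frac_housekeeping = 0, dispersion_meanlog = log(1e-6),
                     dispersion_sdlog = 0, size_factor_range = c(1, 1),
                     seed = 11)
  b0 <- simulate_bulk_counts(cfg0)
  rel <- abs(rowMeans(b0$counts) - b0$truth$baseline) /
    (b0$truth$baseline + 1)
  expect_lt(median(rel), 0.15)
  expect_warning(simulate_bulk_counts(sim_config(n_genes = 50, replicates = 1,
                                                 seed = 1)),
                 "fewer than 2 replicates")
})

test_that("single-cell generator is deterministic with a high-mean gene fully detected", {
  a <- simulate_single_cell(n_genes = 2000, cells_per_cluster = 40, seed = 3)
  b <- simulate_single_cell(n_genes = 2000, cells_per_cluster = 40, seed = 3)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_error(simulate_single_cell(clusters = 1), "clusters")

  # no dropout, one high-mean marker: detection proportion about 1 in its own
  # cluster
  sc <- simulate_single_cell(n_genes = 2000, cells_per_cluster = 60,
                             dropout = 0, seed = 6)
  f <- filter_cells_genes(sc$counts, sc$clusters)
  nm <- normalize_global_scaling(f$counts)
  mk <- sc$truth$markers$gene_id[1]
  own <- f$clusters == sc$truth$markers$cluster[1]
  detected <- mean(nm[mk, own] > 0)
  expect_gt(detected, 0.95)
})

test_that("peak/conservation generator reproduces the requested contrast", {
  cfg <- sim_config(n_genes = 1200, seed = 12)
  b <- simulate_bulk_counts(cfg)
  for (ctr in c(0, 0.2)) {
    pc <- simulate_peaks_and_conservation(b$models, b$truth, contrast = ctr,
                                          focal_species = "mouse",
                                          focal_cell_type = "granule",
                                          seed = 13)
    means <- peak_conservation(pc$track, pc$peaks)
    enr <- pc$peak_truth$class == "species_enriched"
    diff <- mean(means[!enr]) - mean(means[enr])
    expect_equal(diff, ctr, tolerance = 0.03)
  }
  # every promoter peak overlaps its gene's promoter window
  pc <- simulate_peaks_and_conservation(b$models, b$truth, contrast = 0.2,
                                        focal_species = "mouse",
                                        focal_cell_type = "granule", seed = 13)
  pw <- promoter_windows(b$models)
  prom <- pc$peak_truth$kind == "promoter"
  i <- match(pc$peak_truth$gene_id[prom], pw$gene_id)
  expect_true(all(pc$peaks$start[prom] < pw$end[i] &
                    pc$peaks$end[prom] > pw$start[i]))
})

test_that("generated objects round-trip through file IO", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 120, replicates = 2, seed = 14)
  b <- simulate_bulk_counts(cfg)
  write_counts(b$counts, file.path(dir, "c.tsv"))
  expect_identical(read_counts(file.path(dir, "c.tsv")), b$counts)
  write_sample_table(b$samples, file.path(dir, "s.tsv"))
  got <- read_sample_table(file.path(dir, "s.tsv"))
  expect_equal(got, b$samples)
  write_gene_models(b$models, file.path(dir, "m.tsv"))
  back <- read_gene_models(file.path(dir, "m.tsv"))
  expect_equal(back$genes, b$models$genes)
  pc <- simulate_peaks_and_conservation(b$models, b$truth, 0.2,
                                        "mouse", "granule", seed = 15)
  write_intervals(pc$track, file.path(dir, "t.bedGraph"))
  tr <- read_intervals(file.path(dir, "t.bedGraph"), "bedgraph")
  expect_equal(tr$score, pc$track$score, tolerance = 1e-9)
  write_intervals(pc$peaks, file.path(dir, "p.bed"))
  pk <- read_intervals(file.path(dir, "p.bed"), "bed")
  expect_equal(pk$start, pc$peaks$start)
  expect_equal(pk$peak_id, pc$peaks$peak_id)
})
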