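# A minimal hand-built DE table exercising each predicate of the calling
# cascade. log2fc > 0 means higher in human.
fake_de <- function(df) {
  de <- data.frame(gene_id = df$gene_id, base_mean = df$base_mean,
                   log2fc = df$log2fc, se = 0.1,
                   stat = df$log2fc / 0.1, pvalue = df$p, padj = df$padj,
                   stringsAsFactors = FALSE)
  structure(de, class = c("de_result", "data.frame"),
            contrast = c(test = "species", numerator = "human",
                         denominator = "mouse"))
}

test_that("every predicate of the enrichment cascade is enforced", {
  genes <- c("pass", "weak_p", "small_fc", "low_bm", "low_fpkm", "pan_hit",
             "mouse_side")
  de <- fake_de(data.frame(
    gene_id = genes,
    base_mean = c(1000, 1000, 1000, 300, 1000, 1000, 1000),
    log2fc = c(3, 3, 1.5, 3, 3, 3, -2),     # -2: boundary, inclusive
    p = 1e-9, padj = c(1e-8, 1e-4, 1e-8, 1e-8, 1e-8, 1e-8, 1e-8)))
  lf <- matrix(6, 7, 2, dimnames = list(genes, c("human", "mouse")))
  lf["low_fpkm", "human"] <- 3.5
  pan <- fake_de(data.frame(gene_id = genes, base_mean = 1000,
                            log2fc = c(0, 0, 0, 0, 0, 2.5, 0),
                            p = 1, padj = c(1, 1, 1, 1, 1, 1e-8, 1)))
  calls <- call_species_enriched(list(granule = de), list(granule = lf), pan)
  expect_setequal(calls$sets$granule$human, "pass")
  expect_setequal(calls$sets$granule$mouse, "mouse_side")
  expect_equal(calls$pan_genes, "pan_hit")
  # every returned gene satisfies all recorded thresholds (self-audit)
  th <- calls$thresholds
  for (i in seq_len(nrow(calls$calls))) {
    r <- calls$calls[i, ]
    expect_lt(r$padj, th$alpha)
    expect_gte(abs(r$log2fc), th$min_log2fc)
    expect_gt(r$base_mean, th$min_base_mean)
    expect_gt(r$log2fpkm_higher, th$min_log2fpkm)
  }
})

test_that("swapping the species labels swaps the enriched sets exactly", {
  set.seed(31)
  cfg <- sim_config(n_genes = 600, cell_types = "granule", replicates = 8,
                    seed = 31)
  b <- simulate_bulk_counts(cfg)
  sf <- size_factors(b$counts)
  lens <- setNames(b$models$genes$length_bp, b$models$genes$gene_id)
  lf <- list(granule = mean_log2_fpkm(b$counts, lens, b$samples$species))
  de_hm <- nb_wald_test(b$counts, b$samples, test = "species",
                        contrast = c("human", "mouse"), sf = sf)
  de_mh <- nb_wald_test(b$counts, b$samples, test = "species",
                        contrast = c("mouse", "human"), sf = sf)
  c1 <- call_species_enriched(list(granule = de_hm), lf)
  c2 <- call_species_enriched(list(granule = de_mh), lf)
  expect_setequal(c1$sets$granule$human, c2$sets$granule$human)
  expect_setequal(c1$sets$granule$mouse, c2$sets$granule$mouse)
})

test_that("housekeeping selection uses raw p with expression cutoffs", {
  genes <- c("hk", "sig", "lowx")
  de <- fake_de(data.frame(gene_id = genes, base_mean = c(500, 500, 500),
                           log2fc = 0, p = c(0.5, 0.1, 0.5), padj = 1))
  lf <- matrix(5, 3, 2, dimnames = list(genes, c("human", "mouse")))
  lf["lowx", "mouse"] <- 3
  expect_equal(define_housekeeping(de, lf), "hk")
})

test_that("planted high-expression nulls are recovered at the null p rate", {
  cfg <- sim_config(n_genes = 1500, cell_types = "granule", replicates = 8,
                    frac_marker = 0, frac_species = 0, frac_pan = 0,
                    frac_housekeeping = 0.3, seed = 41)
  b <- simulate_bulk_counts(cfg)
  lens <- setNames(b$models$genes$length_bp, b$models$genes$gene_id)
  de <- nb_wald_test(b$counts, b$samples, test = "species",
                     contrast = c("human", "mouse"))
  lf <- mean_log2_fpkm(b$counts, lens, b$samples$species)
  hk <- define_housekeeping(de, lf)
  planted <- b$truth$gene_id[b$truth$class == "housekeeping"]
  # expression cutoffs pass by construction; raw p > 0.2 under the null
  # leaves about 80% of them
  expect_equal(mean(planted %in% hk), 0.8, tolerance = 0.08)
  # every selected gene satisfies the definition when re-checked
  i <- match(hk, de$gene_id)
  expect_true(all(de$pvalue[i] > 0.2 & de$base_mean[i] > 400))
  expect_true(all(lf[hk, ] > 4))
})

test_that("partition enumeration matches the closed form", {
  expect_length(enumerate_partitions(4, 2), 6)
  expect_equal(enumerate_partitions(3, 1), list(1L, 2L, 3L))
  for (n in c(5, 9, 12)) for (k in c(1, 3)) {
    p <- enumerate_partitions(n, k)
    expect_length(p, choose(n, k))
    expect_false(any(duplicated(p)))
  }
  expect_error(enumerate_partitions(4, 4), "0 < k < n")
  expect_error(enumerate_partitions(4, 0), "0 < k < n")
})

test_that("partition null output has one row per subset", {
  cfg <- sim_config(n_genes = 150, species = "human", cell_types = "granule",
                    replicates = 6, frac_marker = 0, frac_species = 0,
                    frac_pan = 0, frac_housekeeping = 0, seed = 43)
  b <- simulate_bulk_counts(cfg)
  pn <- partition_null(b$counts, k = 2)
  expect_equal(nrow(pn), choose(6, 2))
  expect_true(all(pn$n_de >= 0))
  bad <- b$counts; bad[, 2] <- 0L
  expect_error(partition_null(bad, k = 2), "degenerate")
})
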