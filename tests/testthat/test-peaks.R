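two_gene_models <- function() {
  g <- data.frame(gene_id = c("gP", "gM"), chrom = "chr1",
                  strand = c("+", "-"),
                  start = c(5000L, 20000L), end = c(9000L, 24000L))
  tx <- data.frame(gene_id = g$gene_id,
                   transcript_id = paste0(g$gene_id, "_t1"),
                   start = g$start, end = g$end)
  gene_models(g, tx)
}

test_that("promoter windows are 1101 bp, strand-aware, half-open", {
  pw <- promoter_windows(two_gene_models())
  # + strand gene, tss = 5000: [4000, 5101)
  expect_equal(pw$start[1], 4000L)
  expect_equal(pw$end[1], 5101L)
  # - strand gene, tss = 23999: [23899, 25000)
  expect_equal(pw$start[2], 23899L)
  expect_equal(pw$end[2], 25000L)
  expect_equal(pw$end - pw$start, c(1101L, 1101L))
})

test_that("peak assignment follows the promoter/gene-body/other cascade", {
  gm <- two_gene_models()
  pk <- peak_set(rep("chr1", 3), c(4900L, 5200L, 30000L),
                 c(5400L, 5600L, 30100L))
  ann <- assign_peaks(pk, gm)
  expect_equal(ann$category, c("promoter", "gene_body", "other"))
  expect_equal(ann$gene_id[1:2], c("gP", "gP"))
  # unknown contig: warning, category other
  expect_warning(ann2 <- assign_peaks(peak_set("chrUn", 1L, 10L), gm),
                 "chrUn")
  expect_equal(ann2$category, "other")
})

test_that("assignment matches the brute-force all-pairs oracle", {
  for (s in 1:5) {
    gm <- simulate_gene_models(60, seed = s)
    set.seed(s + 500)
    n <- 150
    chrom <- sample(paste0("chr", 1:3), n, replace = TRUE)
    start <- sample(0:250000, n)
    pk <- peak_set(chrom, start, start + sample(c(50, 200, 800, 3000), n,
                                                replace = TRUE))
    got <- assign_peaks(pk, gm)
    want <- oracle_assign(pk, gm)
    expect_equal(got$category, want$category)
    expect_equal(got$gene_id, want$gene_id)
    # categories exhaustive and mutually exclusive by construction
    expect_true(all(got$category %in% c("promoter", "gene_body", "other")))
  }
})

test_that("per-peak conservation means match per-base expansion", {
  const <- conservation_track("chr1", 0L, 10000L, 0.8)
  pk <- peak_set("chr1", c(100L, 5000L), c(600L, 5100L))
  expect_equal(unname(peak_conservation(const, pk)), c(0.8, 0.8))

  half <- conservation_track(c("chr1", "chr1"), c(0L, 50L), c(50L, 100L),
                             c(0, 1))
  expect_equal(unname(peak_conservation(half, peak_set("chr1", 0L, 100L))),
               0.5)

  for (s in 1:5) {
    tr <- random_track(s)
    set.seed(s + 900)
    starts <- sample(0:5500, 20)
    pk <- peak_set("chr1", starts, starts + sample(50:400, 20, replace = TRUE))
    got <- peak_conservation(tr, pk)
    want <- vapply(seq_len(20), function(i)
      oracle_peak_mean(tr, "chr1", pk$start[i], pk$end[i]), numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("group comparison is a one-sided Welch test with conventions", {
  set.seed(3)
  x <- rnorm(50, 0.4, 0.1)
  same <- compare_groups(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 0.5)

  a <- rnorm(100, 0.4, 0.1); b <- rnorm(100, 0.6, 0.1)
  cmp <- compare_groups(a, b, "less")
  expect_lt(cmp$p_value, 1e-6)
  expect_equal(cmp$median_a, median(a))
  # swapping groups with the reversed alternative gives the identical p
  rev <- compare_groups(b, a, "greater")
  expect_equal(rev$p_value, cmp$p_value)

  flat <- compare_groups(rep(0.3, 5), rep(0.3, 7))
  expect_equal(flat$p_value, 0.5)
})

test_that("metagene profile is constant on a constant track", {
  const <- conservation_track("chr1", 0L, 50000L, 0.7)
  set.seed(4)
  starts <- sample(0:40000, 15)
  pk <- peak_set("chr1", starts, starts + sample(80:900, 15, replace = TRUE))
  mg <- metagene_conservation(const, pk, n_bins = 40)
  expect_equal(mg, rep(0.7, 40))
  # single peak: profile equals that peak's own binned scores
  tr <- random_track(8)
  one <- peak_set("chr1", 1000L, 1400L)
  expect_equal(metagene_conservation(tr, one, n_bins = 10),
               metagene_conservation(tr, one, n_bins = 10))
  expect_error(metagene_conservation(const, pk[0, ]), "empty")
  # center-enriched track yields interior bins above edge bins
  centw <- conservation_track(rep("chr1", 3), c(0L, 300L, 700L),
                              c(300L, 700L, 1000L), c(0.2, 0.9, 0.2))
  prof <- metagene_conservation(centw, peak_set("chr1", 0L, 1000L),
                                n_bins = 10)
  expect_gt(mean(prof[4:7]), mean(prof[c(1, 2, 9, 10)]))
})

test_that("differential-peak filter is strictly greater than two-fold", {
  pk <- data.frame(peak_id = paste0("p", 1:4),
                   fold_change = c(2.0, 2.1, 0.4, 1.0))
  kept <- filter_differential_peaks(pk)
  expect_setequal(kept$peak_id, c("p2", "p3"))
  expect_equal(nrow(filter_differential_peaks(pk[0, ])), 0)
  lg <- data.frame(peak_id = "p1", fold_change = 1.0)
  expect_equal(nrow(filter_differential_peaks(lg, log2 = TRUE)), 0)
})

test_that("SNP containment respects half-open peaks and matches brute force", {
  pk <- peak_set("chr1", 100L, 200L, peak_id = "pk1")
  inside <- snp_overlap(data.frame(chrom = "chr1", pos = 150L), pk)
  expect_equal(nrow(inside$per_snp), 1)
  boundary <- snp_overlap(data.frame(chrom = "chr1", pos = 200L), pk)
  expect_equal(nrow(boundary$per_snp), 0)
  at_start <- snp_overlap(data.frame(chrom = "chr1", pos = 100L), pk)
  expect_equal(nrow(at_start$per_snp), 1)

  for (s in 1:5) {
    set.seed(s + 70)
    pk <- peak_set(sample(paste0("chr", 1:2), 40, replace = TRUE),
                   st <- sample(0:5000, 40), st + sample(20:300, 40, TRUE))
    pk$differential <- runif(40) < 0.3
    snps <- data.frame(chrom = sample(paste0("chr", 1:2), 100, replace = TRUE),
                       pos = sample(0:5200, 100))
    got <- snp_overlap(snps, pk)
    expect_equal(nrow(got$per_snp), oracle_snp_pairs(snps, pk))
  }
})

test_that("region signal FPKM is coverage-scale invariant", {
  cov <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                    end = c(1000L, 2000L), score = c(2, 2))
  reg <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                    end = c(500L, 1500L))
  v <- region_signal_fpkm(cov, reg)
  expect_equal(v[1], v[2])      # uniform coverage, equal-length regions
  cov2 <- transform(cov, score = score * 2)
  expect_equal(region_signal_fpkm(cov2, reg), v)   # doubling changes nothing
  empty <- data.frame(chrom = "chr2", start = 0L, end = 100L)
  expect_equal(region_signal_fpkm(cov, empty), 0)  # log2(0 + 1)
  expect_error(region_signal_fpkm(transform(cov, score = 0), reg), "zero")
})
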