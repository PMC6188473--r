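test_that("quality filters apply exact boundaries, gene filter first", {
  # gA detected in exactly 3 cells (boundary: retained); gB in 2 (removed);
  # gC..gF everywhere. After the gene filter c1..c3 detect 5 genes, c4
  # detects 4.
  m <- matrix(0L, 6, 4, dimnames = list(c("gA", "gB", "gC", "gD", "gE", "gF"),
                                        paste0("c", 1:4)))
  m["gA", 1:3] <- 1L
  m["gB", 1:2] <- 1L
  m[c("gC", "gD", "gE", "gF"), ] <- 1L
  f <- filter_cells_genes(m, min_cells = 3, min_genes = 5, max_genes = 5)
  expect_setequal(f$report$removed_genes, "gB")
  # cells at exactly min_genes are retained; one below is removed
  expect_setequal(f$report$removed_cells, "c4")
  f2 <- filter_cells_genes(m, min_cells = 3, min_genes = 4, max_genes = 4)
  # cells above max_genes are removed; exactly max_genes retained
  expect_setequal(f2$report$removed_cells, c("c1", "c2", "c3"))
})

test_that("planted filter violators are removed exactly", {
  sc <- simulate_single_cell(seed = 5)
  f <- filter_cells_genes(sc$counts, sc$clusters)
  expect_setequal(f$report$removed_cells, sc$truth$violator_cells)
  expect_setequal(f$report$removed_genes, sc$truth$violator_genes)
  expect_equal(length(f$clusters), ncol(f$counts))
})

test_that("global scaling normalization matches its formula", {
  m <- matrix(c(10L, 9990L, 0L, 5L), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  n <- normalize_global_scaling(m)
  expect_equal(n["g1", "c1"], log(11))   # 10/10000 * 1e4 -> ln(1 + 10)
  expect_equal(n["g1", "c2"], 0)
  # scale invariance per cell
  expect_equal(normalize_global_scaling(m * 3L), n)
  # sparse input stays sparse with identical values
  sm <- Matrix::Matrix(m, sparse = TRUE)
  ns <- normalize_global_scaling(sm)
  expect_s4_class(ns, "CsparseMatrix")
  expect_equal(as.matrix(ns), n, ignore_attr = TRUE)
  zero <- m; zero[, 2] <- 0L
  expect_error(normalize_global_scaling(zero), "all-zero cell")
})

test_that("cluster metrics compute means and strict detection proportions", {
  vals <- matrix(c(0, 0.5, 2.0, 3.1), 1, 4,
                 dimnames = list("g1", paste0("c", 1:4)))
  cm <- cluster_metrics(vals, "g1", rep("A", 4), threshold = 1)
  expect_equal(cm$detection_proportion, 0.5)
  expect_equal(cm$mean_expression, mean(c(0, 0.5, 2, 3.1)))

  zeros <- matrix(0, 1, 4, dimnames = list("g1", paste0("c", 1:4)))
  cz <- cluster_metrics(zeros, "g1", rep("A", 4))
  expect_equal(cz$mean_expression, 0)
  expect_equal(cz$detection_proportion, 0)

  # threshold 0 reduces to the detection rate
  c0 <- cluster_metrics(vals, "g1", rep("A", 4), threshold = 0)
  expect_equal(c0$detection_proportion, 0.75)

  # invariant to cell order; missing genes reported
  perm <- vals[, c(3, 1, 4, 2), drop = FALSE]
  cp <- cluster_metrics(perm, c("g1", "gX"), rep("A", 4), threshold = 1)
  expect_equal(cp$detection_proportion, 0.5)
  expect_equal(attr(cp, "missing_genes"), "gX")
})

test_that("marker genes show elevated detection in their own cluster", {
  sc <- simulate_single_cell(seed = 9)
  f <- filter_cells_genes(sc$counts, sc$clusters)
  nm <- normalize_global_scaling(f$counts)
  mk <- sc$truth$markers[sc$truth$markers$cluster == "cluster1", "gene_id"]
  cm <- cluster_metrics(nm, mk, f$clusters)
  own <- mean(cm$detection_proportion[cm$cluster == "cluster1"])
  other <- mean(cm$detection_proportion[cm$cluster != "cluster1"])
  expect_gt(own, other + 0.2)
})

test_that("ECDF comparison degenerates correctly and has power", {
  same <- ecdf_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  disj <- ecdf_compare(rep(0, 5), rep(1, 5))
  expect_equal(disj$D, 1)
  expect_error(ecdf_compare(numeric(), 1:3), "nonempty")
  set.seed(17)
  shifted <- ecdf_compare(rnorm(100), rnorm(100, mean = 1))
  expect_lt(shifted$p_value, 1e-4)
})

test_that("downsampling preserves expectations and boundary behavior", {
  set.seed(2)
  counts <- setNames(rpois(200, 40), paste0("g", 1:200))
  lens <- setNames(rep(2000, 200), names(counts))
  total <- sum(counts)

  full <- downsample_detection_curve(counts, depths = total, lengths = lens,
                                     seed = 1)
  t_full <- tpm(matrix(counts, ncol = 1,
                       dimnames = list(names(counts), "s")), lens)[, 1]
  expect_equal(full$genes_detected, sum(log2(t_full + 1) > 1.1))

  expect_error(downsample_detection_curve(counts, total + 1, lens), "exceeds")
  expect_error(downsample_detection_curve(counts, 0, lens), "depth 0")
  z <- downsample_detection_curve(counts, 0, lens, allow_zero_depth = TRUE)
  expect_equal(z$genes_detected, 0)

  # hypergeometric mean: per-gene downsampled counts scale by depth/total
  depth <- round(total / 4)
  draws <- sapply(1:60, function(s)
    orthocell:::downsample_counts(counts, depth))
  expect_equal(rowMeans(draws), counts * depth / total, tolerance = 0.12)
  expect_true(all(colSums(draws) == depth))

  # detection non-decreasing in depth on seed-averaged curves
  depths <- round(total * c(0.05, 0.2, 0.5, 1))
  curves <- sapply(1:5, function(s)
    downsample_detection_curve(counts, depths, lens, seed = s)$genes_detected)
  expect_true(all(diff(rowMeans(curves)) >= 0))
})
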