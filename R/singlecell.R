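# Validation of gene sets against single-nucleus / single-cell matrices.

#' Filter a single-cell matrix
#'
#' Removes genes detected (nonzero) in fewer than three cells, then cells
#' with fewer than 300 or more than 5000 detected genes (both boundaries
#' inclusive for retention). Applied once, gene filter first; not iterated.
#'
#' @param m Counts (genes x cells), dense or `Matrix` sparse.
#' @param clusters Optional cluster label per cell; subset alongside.
#' @param min_cells Gene retained if detected in at least this many cells.
#' @param min_genes,max_genes Cell retained if its detected-gene count lies
#'   in `[min_genes, max_genes]`.
#' @return List with `counts`, `clusters`, and a `report` of removed ids.
#' @export
filter_cells_genes <- function(m, clusters = NULL, min_cells = 3,
                               min_genes = 300, max_genes = 5000) {
  if (!nrow(m) || !ncol(m)) stop2("empty matrix")
  det_cells <- Matrix::rowSums(m > 0)
  keep_g <- det_cells >= min_cells
  m2 <- m[keep_g, , drop = FALSE]
  det_genes <- Matrix::colSums(m2 > 0)
  keep_c <- det_genes >= min_genes & det_genes <= max_genes
  if (!any(keep_c)) stop2("all cells removed by the detected-gene filter")
  if (!is.null(clusters)) clusters <- clusters[keep_c]
  list(counts = m2[, keep_c, drop = FALSE],
       clusters = clusters,
       report = list(removed_genes = rownames(m)[!keep_g],
                     removed_cells = colnames(m)[!keep_c]))
}

#' Global-scaling normalization
#'
#' Per cell: counts divided by the cell total, multiplied by `scale`, then
#' log-transformed (`log(1 + x)`, natural log). Invariant to per-cell
#' scaling of counts; zeros map to zero.
#'
#' @param m Counts (genes x cells), dense or sparse; no all-zero cells.
#' @param scale Scale factor (default 10000).
#' @return Normalized matrix of the same class.
#' @export
normalize_global_scaling <- function(m, scale = 10000) {
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) stop2("all-zero cell: ", colnames(m)[tot == 0][1])
  if (methods::is(m, "CsparseMatrix")) {
    m@x <- log1p(m@x / rep(tot, diff(m@p)) * scale)
    m
  } else {
    log1p(sweep(as.matrix(m), 2, tot, "/") * scale)
  }
}

#' Per-cluster expression metrics for a gene set
#'
#' For each gene and cluster: the mean normalized expression over the
#' cluster's cells, and the detection proportion — the fraction of cells with
#' expression strictly above `threshold`.
#'
#' @param norm Normalized matrix (genes x cells).
#' @param genes Gene set to quantify; genes absent from the matrix are
#'   reported in `attr(, "missing_genes")`, not silently dropped.
#' @param clusters Cluster label per cell (no empty clusters).
#' @param threshold Detection threshold (default 1.0, strict `>`).
#' @return data.frame with `gene_id`, `cluster`, `mean_expression`,
#'   `detection_proportion`.
#' @export
cluster_metrics <- function(norm, genes, clusters, threshold = 1.0) {
  if (length(clusters) != ncol(norm))
    stop2("clusters must label every cell")
  missing_genes <- setdiff(genes, rownames(norm))
  genes <- setdiff(genes, missing_genes)
  if (!length(genes)) stop2("none of the requested genes are in the matrix")
  lv <- unique(as.character(clusters))
  rows <- lapply(lv, function(cl) {
    cols <- which(as.character(clusters) == cl)
    if (!length(cols)) stop2("empty cluster: ", cl)
    sub <- norm[genes, cols, drop = FALSE]
    data.frame(gene_id = genes, cluster = cl,
               mean_expression = as.numeric(Matrix::rowMeans(sub)),
               detection_proportion =
                 as.numeric(Matrix::rowSums(sub > threshold)) / length(cols),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "missing_genes") <- missing_genes
  out
}

#' Compare two gene sets' expression distributions
#'
#' Empirical CDFs of a per-gene metric (e.g. mean expression or detection
#' proportion) for two gene sets, with the two-sample Kolmogorov-Smirnov
#' statistic and two-sided p-value.
#'
#' @param a,b Numeric vectors of per-gene metric values (both nonempty).
#' @return List with `ecdf_a`, `ecdf_b`, `D`, `p_value`.
#' @export
ecdf_compare <- function(a, b) {
  if (!length(a) || !length(b)) stop2("both sets must be nonempty")
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(ecdf_a = stats::ecdf(a), ecdf_b = stats::ecdf(b),
       D = unname(ks$statistic), p_value = ks$p.value)
}

#' Downsampled detection curves
#'
#' Reads are subsampled without replacement (multivariate hypergeometric
#' draw) to each target depth; TPM is recomputed with whole-gene lengths and
#' a gene is counted as expressed iff `log2(TPM + 1) > threshold`
#' (equivalently TPM > 2^threshold - 1).
#'
#' @param counts Count vector for one sample (named by gene), or a one-column
#'   matrix.
#' @param depths Target read depths (each `<=` the sample total).
#' @param lengths Whole-gene lengths in bp.
#' @param threshold Expression threshold on log2(TPM + 1) (default 1.1).
#' @param seed Integer seed for the subsampling draws.
#' @param allow_zero_depth Permit depth 0 (reported as 0 genes detected).
#' @return data.frame with `depth` and `genes_detected`.
#' @export
downsample_detection_curve <- function(counts, depths, lengths,
                                       threshold = 1.1, seed = 1,
                                       allow_zero_depth = FALSE) {
  if (is.matrix(counts)) counts <- counts[, 1]
  total <- sum(counts)
  if (any(depths > total)) stop2("depth exceeds the sample total (", total, ")")
  if (any(depths < 0)) stop2("negative depth")
  if (any(depths == 0) && !allow_zero_depth)
    stop2("depth 0 not allowed (set allow_zero_depth = TRUE)")
  lengths <- align_lengths(as.matrix(counts), lengths)
  detected <- vapply(seq_along(depths), function(j) {
    d <- depths[j]
    if (d == 0) return(0L)
    sub <- with_seed(substream_seed(seed, paste0("downsample_", j)),
                     downsample_counts(counts, d))
    t <- tpm(matrix(sub, ncol = 1, dimnames = list(names(counts), "s")),
             lengths)[, 1]
    sum(log2(t + 1) > threshold)
  }, integer(1))
  data.frame(depth = depths, genes_detected = detected)
}

# Multivariate hypergeometric draw via chained univariate draws.
downsample_counts <- function(counts, depth) {
  remaining <- sum(counts)
  left <- depth
  out <- integer(length(counts))
  names(out) <- names(counts)
  for (g in seq_along(counts)) {
    if (left == 0) break
    remaining <- remaining - counts[g]
    out[g] <- stats::rhyper(1, counts[g], remaining, left)
    left <- left - out[g]
  }
  out
}
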