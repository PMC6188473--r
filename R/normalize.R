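# Normalization and sample-level exploratory statistics.

#' Median-of-ratios size factors
#'
#' The reference for each gene is its geometric mean across samples (genes
#' with a zero in any sample are excluded from the reference); each sample's
#' factor is the median over genes of count/reference.
#'
#' @param counts Count matrix (genes x samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  validate_count_matrix(counts)
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  if (!any(use))
    stop2("cannot form reference: no gene has nonzero counts in every sample")
  sf <- apply(log(counts[use, , drop = FALSE]), 2,
              function(col) exp(stats::median(col - lg[use])))
  if (any(!is.finite(sf) | sf <= 0)) stop2("degenerate size factor")
  sf
}

#' Fragments per kilobase per million (FPKM)
#'
#' `fpkm = count / ((length/1e3) * (total/1e6))` with whole-gene lengths
#' (UTRs included), so long unexpressed genes are not inflated by transcript
#' annotation differences.
#'
#' @param counts Count matrix (genes x samples).
#' @param lengths Gene lengths in bp, in row order of `counts` (or named).
#' @return Matrix of FPKM values, same shape as `counts`.
#' @export
fpkm <- function(counts, lengths) {
  lengths <- align_lengths(counts, lengths)
  tot <- colSums(counts)
  if (any(tot == 0)) stop2("sample with zero total counts: ",
                           colnames(counts)[tot == 0][1])
  sweep(counts / (lengths / 1e3), 2, tot / 1e6, "/")
}

#' Transcripts per million (TPM)
#'
#' Length-normalized rates rescaled so every sample sums to 1e6. Invariant to
#' per-sample scaling of counts.
#'
#' @inheritParams fpkm
#' @return Matrix of TPM values; columns sum to 1e6.
#' @export
tpm <- function(counts, lengths) {
  lengths <- align_lengths(counts, lengths)
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop2("sample with zero total counts: ",
                           colnames(counts)[tot == 0][1])
  sweep(rate, 2, tot, "/") * 1e6
}

align_lengths <- function(counts, lengths) {
  if (!is.null(names(lengths))) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss)) stop2("no length for gene ", miss[1])
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts))
    stop2("lengths must match the number of genes")
  if (any(lengths < 1)) stop2("gene lengths must be >= 1 bp")
  lengths
}

#' Variance-stabilizing transform
#'
#' `log2(normalized count + 1)`: a simple monotone variance-stabilizing
#' transform used for clustering, correlations and PCA.
#'
#' @param counts Count matrix.
#' @param sf Size factors (computed with [size_factors()] when missing).
#' @return Matrix of stabilized values.
#' @export
variance_stabilize <- function(counts, sf = size_factors(counts)) {
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Top variable genes
#'
#' The `n` genes with the largest variance across samples; ties broken by
#' lexicographic gene id for determinism.
#'
#' @param x Stabilized expression matrix (genes x samples).
#' @param n Number of genes to return (default 250).
#' @return Character vector of gene ids.
#' @export
top_variable_genes <- function(x, n = 250) {
  if (n > nrow(x)) stop2("n exceeds the number of genes")
  v <- apply(x, 1, stats::var)
  ord <- order(-v, rownames(x))
  rownames(x)[ord][seq_len(n)]
}

#' Sample correlations and hierarchical clustering
#'
#' Pairwise Pearson correlation between samples over a gene subset, plus a
#' dendrogram from Euclidean distance with complete linkage.
#'
#' @param x Stabilized expression matrix (genes x samples).
#' @param genes Optional gene subset (default: [top_variable_genes()]).
#' @return List with `correlation` (samples x samples) and `hclust`.
#' @export
correlation_and_clustering <- function(x, genes = NULL) {
  if (ncol(x) < 2) stop2("need >= 2 samples")
  if (is.null(genes)) genes <- top_variable_genes(x, min(250L, nrow(x)))
  sub <- x[genes, , drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0))
    stop2("zero-variance sample over selected genes: ",
          colnames(sub)[sds == 0][1])
  corr <- stats::cor(sub)
  hc <- stats::hclust(stats::dist(t(sub)), method = "complete")
  list(correlation = corr, hclust = hc)
}

#' PCA scores and loadings
#'
#' Principal components of samples over a gene subset; genes are centered but
#' not scaled. Returns scores per sample, loadings per gene, and the
#' proportion of variance per component, so the highest-loading genes of each
#' component can be listed.
#'
#' @param x Stabilized expression matrix (genes x samples).
#' @param genes Optional gene subset (default: all genes).
#' @return List with `scores`, `loadings`, `proportion_variance`.
#' @export
pca_scores_loadings <- function(x, genes = NULL) {
  if (ncol(x) < 2) stop2("need >= 2 samples")
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  prop <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation,
       proportion_variance = stats::setNames(prop, colnames(p$x)))
}
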