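# Threshold cascades for species-enrichment calls, the housekeeping reference
# set, and the exhaustive donor-partition resampling null.

#' Threshold block for species-enrichment calling
#'
#' Defaults follow the stringent reading of the published cascade: adjusted
#' p below `1e-5`, at least 4-fold change (`|log2fc| >= 2`, inclusive), mean
#' normalized counts above 400, mean log2(FPKM) above 4 in the
#' higher-expressing species; the pan-species exclusion uses `|log2fc| > 1`
#' (strict, i.e. fold change > 2) with no expression cutoff; housekeeping
#' genes use raw `p > 0.2` with the same expression cutoffs.
#'
#' @param alpha Adjusted-p cutoff for per-cell-type calls.
#' @param min_log2fc Minimum |log2 fold change| (inclusive).
#' @param min_base_mean Minimum mean of normalized counts (strict `>`).
#' @param min_log2fpkm Minimum mean log2(FPKM) in the higher species
#'   (strict `>`).
#' @param pan_alpha,pan_log2fc Pan-species exclusion thresholds (strict
#'   `|log2fc| >` cutoff).
#' @param housekeeping_p Raw-p lower bound for the housekeeping set.
#' @return Named list of thresholds.
#' @export
enrichment_thresholds <- function(alpha = 1e-5, min_log2fc = 2,
                                  min_base_mean = 400, min_log2fpkm = 4,
                                  pan_alpha = 1e-5, pan_log2fc = 1,
                                  housekeeping_p = 0.2) {
  th <- list(alpha = alpha, min_log2fc = min_log2fc,
             min_base_mean = min_base_mean, min_log2fpkm = min_log2fpkm,
             pan_alpha = pan_alpha, pan_log2fc = pan_log2fc,
             housekeeping_p = housekeeping_p)
  if (any(unlist(th) <= 0)) stop2("all thresholds must be positive")
  th
}

#' Mean log2(FPKM) per group
#'
#' FPKM is computed over all samples (per-sample totals), log2-transformed,
#' then averaged within each group. Genes with zero counts in every sample of
#' a group have mean `-Inf`, which simply fails any expression cutoff.
#'
#' @param counts Count matrix.
#' @param lengths Whole-gene lengths in bp.
#' @param groups Group label per sample (e.g. species).
#' @return Matrix genes x groups of mean log2(FPKM).
#' @export
mean_log2_fpkm <- function(counts, lengths, groups) {
  lf <- suppressWarnings(log2(fpkm(counts, lengths)))
  lv <- unique(as.character(groups))
  out <- vapply(lv, function(g) {
    rowMeans(lf[, as.character(groups) == g, drop = FALSE])
  }, numeric(nrow(counts)))
  dimnames(out) <- list(rownames(counts), lv)
  out
}

#' Call species-enriched genes per cell type
#'
#' A gene is called enriched in species S within a cell type iff its
#' between-species adjusted p is below `alpha`, its |log2 fold change| is at
#' least `min_log2fc` with the sign toward S, its base mean exceeds
#' `min_base_mean`, and its mean log2(FPKM) in S (the higher-expressing
#' species) exceeds `min_log2fpkm`. Genes in the pan-species set (significant
#' in the all-cell-types contrast at `pan_alpha` with |log2fc| >
#' `pan_log2fc`) are then removed, so the calls are cell-type specific rather
#' than global species differences.
#'
#' @param de_by_celltype Named list of per-cell-type [nb_wald_test()] results
#'   (species contrast over that cell type's samples).
#' @param log2fpkm_by_celltype Named list (same names) of genes x species
#'   matrices of mean log2(FPKM), as from [mean_log2_fpkm()].
#' @param de_pan Optional all-cell-types species contrast used for the
#'   pan-species exclusion (skipped when `NULL`).
#' @param thresholds An [enrichment_thresholds()] list.
#' @return Object of class `enrichment_call`: a list with `calls` (one row
#'   per called gene with its triggering statistics), `sets` (nested
#'   list by cell type then species), `pan_genes`, and `thresholds`.
#' @export
call_species_enriched <- function(de_by_celltype, log2fpkm_by_celltype,
                                  de_pan = NULL,
                                  thresholds = enrichment_thresholds()) {
  if (inherits(de_by_celltype, "de_result"))
    de_by_celltype <- list(all = de_by_celltype)
  pan_genes <- character()
  if (!is.null(de_pan)) {
    ok <- !is.na(de_pan$padj)
    pan_genes <- de_pan$gene_id[ok & de_pan$padj < thresholds$pan_alpha &
                                  abs(de_pan$log2fc) > thresholds$pan_log2fc]
  }
  rows <- list(); sets <- list()
  for (ct in names(de_by_celltype)) {
    de <- de_by_celltype[[ct]]
    lf <- log2fpkm_by_celltype[[ct]]
    if (is.null(lf)) stop2("missing log2 FPKM summary for cell type ", ct)
    contrast <- attr(de, "contrast")
    i <- match(de$gene_id, rownames(lf))
    if (anyNA(i)) stop2("missing FPKM summary for gene ",
                        de$gene_id[is.na(i)][1], " (", ct, ")")
    sets[[ct]] <- list()
    for (side in c("numerator", "denominator")) {
      sp <- contrast[[side]]
      sgn <- if (side == "numerator") 1 else -1
      ok <- !is.na(de$padj) &
        de$padj < thresholds$alpha &
        sgn * de$log2fc >= thresholds$min_log2fc &
        de$base_mean > thresholds$min_base_mean &
        lf[i, sp] > thresholds$min_log2fpkm &
        !(de$gene_id %in% pan_genes)
      sets[[ct]][[sp]] <- de$gene_id[ok]
      if (any(ok)) {
        rows[[length(rows) + 1]] <- data.frame(
          cell_type = ct, species = sp, gene_id = de$gene_id[ok],
          padj = de$padj[ok], log2fc = de$log2fc[ok],
          base_mean = de$base_mean[ok],
          log2fpkm_higher = lf[i, sp][ok], stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_type = character(), species = character(),
               gene_id = character(), padj = numeric(), log2fc = numeric(),
               base_mean = numeric(), log2fpkm_higher = numeric())
  rownames(calls) <- NULL
  structure(list(calls = calls, sets = sets, pan_genes = pan_genes,
                 thresholds = thresholds),
            class = "enrichment_call")
}

#' @export
print.enrichment_call <- function(x, ...) {
  cat("Species-enrichment calls\n")
  for (ct in names(x$sets)) {
    cat("  ", ct, ": ", paste(vapply(names(x$sets[[ct]]), function(s)
      paste0(length(x$sets[[ct]][[s]]), " ", s, "-enriched"), character(1)),
      collapse = ", "), "\n", sep = "")
  }
  cat("  pan-species excluded:", length(x$pan_genes), "genes\n")
  invisible(x)
}

#' Define the housekeeping reference set
#'
#' Well-expressed genes that are not differentially expressed between species:
#' raw `p > housekeeping_p` in the all-samples species contrast, base mean
#' above `min_base_mean`, and mean log2(FPKM) above `min_log2fpkm` in every
#' species.
#'
#' @param de_all All-samples species-contrast [nb_wald_test()] result.
#' @param log2fpkm_by_species Genes x species matrix of mean log2(FPKM).
#' @param thresholds An [enrichment_thresholds()] list.
#' @return Character vector of housekeeping gene ids.
#' @export
define_housekeeping <- function(de_all, log2fpkm_by_species,
                                thresholds = enrichment_thresholds()) {
  i <- match(de_all$gene_id, rownames(log2fpkm_by_species))
  ok <- !is.na(de_all$pvalue) &
    de_all$pvalue > thresholds$housekeeping_p &
    de_all$base_mean > thresholds$min_base_mean &
    !is.na(i) &
    rowSums(log2fpkm_by_species[i, , drop = FALSE] >
              thresholds$min_log2fpkm) == ncol(log2fpkm_by_species)
  de_all$gene_id[which(ok)]
}

#' Enumerate all size-k subsets of n samples
#'
#' @param n Total number of samples.
#' @param k Size of the first group (`0 < k < n`).
#' @return List of integer vectors in lexicographic order, length
#'   `choose(n, k)`.
#' @export
enumerate_partitions <- function(n, k) {
  if (k <= 0 || k >= n) stop2("need 0 < k < n")
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Exhaustive partition-resampling null for differential expression
#'
#' For every way of splitting the samples into groups of size `k` and
#' `n - k`, runs the two-group negative-binomial test and records the number
#' of genes significant at the given adjusted-p cutoff. On homogeneous data
#' this is the null distribution of DE counts over arbitrary donor splits; a
#' real subgroup effect shows up as its own partition attaining an extreme
#' count.
#'
#' @param counts Count matrix for the samples of one cell type.
#' @param k Size of the small group.
#' @param alpha Adjusted-p cutoff for counting DE genes (default 0.01).
#' @param sf Optional size factors.
#' @return Object of class `partition_null`: data.frame with `partition_id`,
#'   `members` (comma-separated sample ids), `n_de`; quantiles in
#'   `attr(, "quantiles")`.
#' @export
partition_null <- function(counts, k, alpha = 0.01, sf = NULL) {
  validate_count_matrix(counts)
  n <- ncol(counts)
  if (any(colSums(counts) == 0))
    stop2("degenerate sample (all counts zero): ",
          colnames(counts)[colSums(counts) == 0][1])
  if (is.null(sf)) sf <- size_factors(counts)
  z <- sweep(counts, 2, sf, "/")
  tested <- rowSums(counts) > 0
  parts <- enumerate_partitions(n, k)
  df_t <- n - 2
  n_de <- integer(length(parts))
  for (j in seq_along(parts)) {
    ing <- seq_len(n) %in% parts[[j]]
    X <- cbind(1, as.numeric(ing))
    alpha_g <- mom_dispersion(z, X, sf)
    fit <- nb_two_group_fit(counts[tested, , drop = FALSE], sf, ing,
                            alpha_g[tested])
    pv <- 2 * stats::pt(-abs(fit$log2fc / fit$se), df = df_t)
    n_de[j] <- sum(bh_adjust(pv) < alpha, na.rm = TRUE)
  }
  out <- data.frame(
    partition_id = seq_along(parts),
    members = vapply(parts, function(ix)
      paste(colnames(counts)[ix], collapse = ","), character(1)),
    n_de = n_de, stringsAsFactors = FALSE)
  structure(out, class = c("partition_null", "data.frame"),
            alpha = alpha, k = k,
            quantiles = stats::quantile(n_de, c(0.5, 0.9, 0.95, 1)))
}

#' @export
print.partition_null <- function(x, ...) {
  cat("Partition-resampling null: ", nrow(x), " partitions (k = ",
      attr(x, "k"), ", padj < ", attr(x, "alpha"), ")\n", sep = "")
  print(attr(x, "quantiles"))
  invisible(x)
}
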