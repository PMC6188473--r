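# Replicate-aware Specificity Index.
#
# The SI of gene g in cell type A is the mean, over all other cell types B,
# of g's descending rank of the log-expression difference mean(g,A) -
# mean(g,B); the specificity rank orders genes by ascending SI (rank 1 =
# most specific). Replicate noise is propagated by resampling expression
# from a per-(gene, cell type) normal distribution and averaging the
# specificity ranks over iterations.

#' Construct Specificity Index input
#'
#' @param mean,sd Genes x cell-types matrices of means and standard
#'   deviations of floored log10(FPKM) across replicates; matching dimnames.
#' @return Object of class `specificity_input`.
#' @export
specificity_input <- function(mean, sd) {
  if (!all(dim(mean) == dim(sd))) stop2("mean and sd dimensions differ")
  if (ncol(mean) < 2) stop2("need >= 2 cell types")
  if (any(sd < 0)) stop2("sd must be >= 0")
  if (any(mean < 0)) stop2("means must be >= 0 after flooring")
  structure(list(mean = mean, sd = sd, gene_ids = rownames(mean),
                 cell_types = colnames(mean)),
            class = "specificity_input")
}

#' Prepare counts for the Specificity Index
#'
#' FPKM per sample, log10-transformed and floored at 0 (so long unexpressed
#' genes do not produce large negative values), then summarized per cell type
#' as mean and standard deviation across replicates. Genes shorter than 1 kb
#' are excluded to avoid biases from extremely short genes.
#'
#' @param counts Count matrix (genes x samples).
#' @param lengths Whole-gene lengths in bp (named or in row order).
#' @param cell_types Cell-type label per sample (column of `counts`).
#' @return A [specificity_input()] object.
#' @export
si_preprocess <- function(counts, lengths, cell_types) {
  if (length(cell_types) != ncol(counts))
    stop2("cell_types must label every sample")
  cts <- unique(as.character(cell_types))
  if (length(cts) < 2) stop2("need >= 2 cell types")
  lengths <- align_lengths(counts, lengths)
  # FPKM from the full library, then the short-gene exclusion
  lf <- suppressWarnings(log10(fpkm(counts, lengths)))
  lf <- lf[lengths >= 1000, , drop = FALSE]
  lf[lf < 0] <- 0
  counts <- counts[lengths >= 1000, , drop = FALSE]
  m <- s <- matrix(0, nrow(lf), length(cts),
                   dimnames = list(rownames(counts), cts))
  for (ct in cts) {
    cols <- which(as.character(cell_types) == ct)
    m[, ct] <- rowMeans(lf[, cols, drop = FALSE])
    s[, ct] <- if (length(cols) > 1)
      apply(lf[, cols, drop = FALSE], 1, stats::sd) else 0
  }
  specificity_input(m, s)
}

# Average-tie descending rank of x (rank 1 = largest).
rank_desc <- function(x) {
  length(x) + 1 - rank(x, ties.method = "average")
}

#' Deterministic Specificity Index
#'
#' @param means Genes x cell-types matrix of (floored log) expression means,
#'   or a [specificity_input()] (its means are used).
#' @return List with `si` (mean pairwise rank per gene per cell type) and
#'   `rank` (specificity rank: ascending order of SI, average ranks on ties).
#' @export
si_deterministic <- function(means) {
  if (inherits(means, "specificity_input")) means <- means$mean
  G <- nrow(means); C <- ncol(means)
  if (C < 2) stop2("need >= 2 cell types")
  acc <- matrix(0, G, C, dimnames = dimnames(means))
  for (a in seq_len(C - 1)) {
    for (b in (a + 1):C) {
      r_ab <- rank_desc(means[, a] - means[, b])
      acc[, a] <- acc[, a] + r_ab
      acc[, b] <- acc[, b] + (G + 1 - r_ab)
    }
  }
  si <- acc / (C - 1)
  rk <- apply(si, 2, rank, ties.method = "average")
  dimnames(rk) <- dimnames(means)
  list(si = si, rank = rk)
}

#' Sampled Specificity Index with replicate noise
#'
#' Per iteration, expression values are drawn independently per (gene, cell
#' type) from `Normal(mean, sd)`, re-floored at 0 to stay on the support of
#' the floored log10(FPKM) inputs, ranked with [si_deterministic()], and the
#' specificity ranks are averaged over iterations. Iteration i uses a
#' deterministic substream of `seed`, so results do not depend on execution
#' order.
#'
#' @param input A [specificity_input()].
#' @param iterations Number of resampling iterations (default 1000).
#' @param seed Integer seed.
#' @return Object of class `specificity_table` with `avg_rank` (genes x cell
#'   types, values in `[1, G]`), `iterations` and `seed`.
#' @export
si_sampled <- function(input, iterations = 1000, seed = 1) {
  stopifnot(inherits(input, "specificity_input"))
  if (iterations < 1) stop2("iterations must be >= 1")
  m <- input$mean; s <- input$sd
  G <- nrow(m); C <- ncol(m)
  acc <- matrix(0, G, C, dimnames = dimnames(m))
  for (i in seq_len(iterations)) {
    draws <- with_seed(substream_seed(seed, paste0("si_iter_", i)), {
      matrix(stats::rnorm(G * C, mean = as.vector(m), sd = as.vector(s)), G, C)
    })
    draws[draws < 0] <- 0
    acc <- acc + si_deterministic(draws)$rank
  }
  structure(list(avg_rank = acc / iterations, iterations = iterations,
                 seed = seed, gene_ids = rownames(m), cell_types = colnames(m)),
            class = "specificity_table")
}

#' @export
print.specificity_table <- function(x, ...) {
  cat("Specificity table: ", length(x$gene_ids), " genes x ",
      length(x$cell_types), " cell types, ", x$iterations,
      " iterations (seed ", x$seed, ")\n", sep = "")
  print(utils::head(x$avg_rank, 5))
  invisible(x)
}

si_rank_matrix <- function(table) {
  if (inherits(table, "specificity_table")) table$avg_rank
  else if (is.matrix(table)) table
  else stop2("expected a specificity_table or a rank matrix")
}

#' Most specific genes of a cell type
#'
#' @param table A `specificity_table` (or averaged-rank matrix).
#' @param cell_type Cell type (column) to rank.
#' @param k Number of genes (default 20).
#' @return Character vector of the `k` genes with the smallest averaged rank;
#'   ties broken by gene id.
#' @export
top_specific_genes <- function(table, cell_type, k = 20) {
  rk <- si_rank_matrix(table)
  if (!cell_type %in% colnames(rk)) stop2("unknown cell type: ", cell_type)
  if (k > nrow(rk)) stop2("k exceeds the number of genes")
  ord <- order(rk[, cell_type], rownames(rk))
  rownames(rk)[ord][seq_len(k)]
}

#' Cross-species concordance of specificity ranks
#'
#' Looks up the `top_n` most specific genes of one table (e.g. mouse) in
#' another (e.g. human, over the shared ortholog universe). Genes absent from
#' the second table are reported as missing rather than dropped.
#'
#' @param table_a,table_b Specificity tables (or rank matrices) sharing a
#'   gene universe.
#' @param cell_type Cell type to compare.
#' @param top_n Number of top genes of `table_a` to look up (default 100).
#' @return data.frame with `gene_id`, `rank_a`, `rank_b` (NA when missing)
#'   and `missing`.
#' @export
si_rank_concordance <- function(table_a, table_b, cell_type, top_n = 100) {
  ra <- si_rank_matrix(table_a); rb <- si_rank_matrix(table_b)
  if (!length(intersect(rownames(ra), rownames(rb))))
    stop2("tables share no genes; map to a common ortholog universe first")
  top <- top_specific_genes(ra, cell_type, k = min(top_n, nrow(ra)))
  i <- match(top, rownames(rb))
  has_ct <- cell_type %in% colnames(rb)
  if (!has_ct) stop2("cell type '", cell_type, "' absent from second table")
  data.frame(gene_id = top,
             rank_a = ra[top, cell_type],
             rank_b = ifelse(is.na(i), NA_real_, rb[i, cell_type]),
             missing = is.na(i),
             stringsAsFactors = FALSE)
}
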