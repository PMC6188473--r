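# Peak annotation, signal and conservation summaries, group comparisons, and
# SNP intersection. Intervals are 0-based half-open throughout; the
# 1-based-inclusive promoter definition (1 kb upstream to 100 bp downstream
# of the TSS) is translated to half-open exactly once, here.

# 0-based half-open intervals -> GRanges (1-based inclusive internally).
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}

#' Promoter windows of gene models
#'
#' Strand-aware window from 1 kb upstream to 100 bp downstream of the TSS,
#' expressed half-open: `[tss - 1000, tss + 101)` on the plus strand,
#' mirrored on the minus strand; 1101 bp wide unless clipped at the contig
#' start.
#'
#' @param models A [gene_models()] object.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `tss`.
#' @export
promoter_windows <- function(models) {
  g <- models$genes
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss - 1000L, g$tss - 100L)
  end <- ifelse(plus, g$tss + 101L, g$tss + 1001L)
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = pmax(start, 0L), end = end, tss = g$tss,
             stringsAsFactors = FALSE)
}

# Distance from a TSS base to a half-open interval (0 when inside).
tss_distance <- function(start, end, tss) {
  pmax(start - tss, tss - (end - 1L), 0L)
}

#' Annotate peaks as promoter, gene body, or other
#'
#' A peak is a promoter peak if it overlaps any promoter window by at least
#' one base (ties between windows broken by nearest TSS, then lexicographic
#' gene id); otherwise a gene-body peak if it overlaps any whole-gene span
#' (gene of largest overlap; ties by nearest TSS, then gene id); otherwise
#' `other`. Peaks on contigs absent from the models raise a warning and are
#' categorized `other`.
#'
#' @param peaks A [peak_set()].
#' @param models A [gene_models()] object.
#' @return The peak set with `category` and `gene_id` filled in.
#' @export
assign_peaks <- function(peaks, models) {
  g <- models$genes
  unknown <- !peaks$chrom %in% g$chrom
  if (any(unknown))
    warning("peaks on contigs absent from the gene models: ",
            paste(unique(peaks$chrom[unknown]), collapse = ", "))
  peaks$category <- "other"
  peaks$gene_id <- NA_character_

  pw <- promoter_windows(models)
  pr <- as_granges0(peaks$chrom, peaks$start, peaks$end)
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(pr, as_granges0(pw$chrom, pw$start, pw$end)))
  if (length(h)) {
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    d <- tss_distance(peaks$start[qi], peaks$end[qi], pw$tss[si])
    ord <- order(qi, d, pw$gene_id[si])
    best <- ord[!duplicated(qi[ord])]
    peaks$category[qi[best]] <- "promoter"
    peaks$gene_id[qi[best]] <- pw$gene_id[si[best]]
  }

  todo <- which(peaks$category == "other" & !unknown)
  if (length(todo)) {
    hb <- suppressWarnings(GenomicRanges::findOverlaps(
      as_granges0(peaks$chrom[todo], peaks$start[todo], peaks$end[todo]),
      as_granges0(g$chrom, g$start, g$end)))
    if (length(hb)) {
      qi <- S4Vectors::queryHits(hb); si <- S4Vectors::subjectHits(hb)
      ov <- pmin(peaks$end[todo][qi], g$end[si]) -
        pmax(peaks$start[todo][qi], g$start[si])
      d <- tss_distance(peaks$start[todo][qi], peaks$end[todo][qi], g$tss[si])
      ord <- order(qi, -ov, d, g$gene_id[si])
      best <- ord[!duplicated(qi[ord])]
      peaks$category[todo[qi[best]]] <- "gene_body"
      peaks$gene_id[todo[qi[best]]] <- g$gene_id[si[best]]
    }
  }
  peaks
}

# Weighted sum of track score over [start, end) per query; bases without a
# run score 0 (the usual convention for missing conservation values).
track_weighted_sum <- function(track, chrom, start, end) {
  out <- numeric(length(chrom))
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(chrom, start, end),
                                as_granges0(track$chrom, track$start,
                                            track$end)))
  if (length(h)) {
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    ov <- pmin(end[qi], track$end[si]) - pmax(start[qi], track$start[si])
    contrib <- tapply(ov * track$score[si], qi, sum)
    out[as.integer(names(contrib))] <- as.numeric(contrib)
  }
  out
}

#' Mean conservation score per peak
#'
#' Arithmetic mean of per-base scores over each peak; bases not covered by
#' any run score 0.
#'
#' @param track A [conservation_track()].
#' @param peaks A `peak_set` (or data.frame with `chrom`, `start`, `end`).
#' @return Numeric vector of per-peak means, named by `peak_id` when present.
#' @export
peak_conservation <- function(track, peaks) {
  s <- track_weighted_sum(track, peaks$chrom, peaks$start, peaks$end)
  out <- s / (peaks$end - peaks$start)
  if (!is.null(peaks$peak_id)) names(out) <- peaks$peak_id
  out
}

#' Region signal as log2(FPKM)
#'
#' Read-equivalents over each region from a per-base coverage track, scaled
#' per kilobase of region and per million track-total read-equivalents;
#' reported as `log2(FPKM + 1)`.
#'
#' @param coverage Coverage data.frame (`chrom`, `start`, `end`, `score`),
#'   e.g. from `read_intervals(kind = "bedgraph", conservation = FALSE)`.
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @return Numeric vector of log2(FPKM + 1) per region.
#' @export
region_signal_fpkm <- function(coverage, regions) {
  if (any(coverage$score < 0)) stop2("coverage must be non-negative")
  total <- sum((coverage$end - coverage$start) * coverage$score)
  if (total == 0) stop2("track has zero total signal")
  s <- track_weighted_sum(coverage, regions$chrom, regions$start, regions$end)
  fpkm <- s / (((regions$end - regions$start) / 1e3) * (total / 1e6))
  log2(fpkm + 1)
}

#' One-sided Welch comparison of per-peak conservation between gene groups
#'
#' Unequal-variance t-test of the per-peak mean scores of group A against
#' group B, one-sided for the stated alternative, with group medians (as
#' annotated on conservation boxplots). When both groups are constant with
#' equal means the test is undefined and `p = 0.5` is returned by convention.
#'
#' @param a,b Numeric vectors of per-peak mean scores (each `n >= 2`).
#' @param alternative `"less"` (A < B, the default for species-enriched vs
#'   housekeeping) or `"greater"`.
#' @return List of class `group_comparison` with `t`, `p_value`, `median_a`,
#'   `median_b`, `alternative`.
#' @export
compare_groups <- function(a, b, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2) stop2("each group needs n >= 2")
  res <- tryCatch(stats::t.test(a, b, alternative = alternative,
                                var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    t <- 0; p <- if (mean(a) == mean(b)) 0.5 else
      if ((alternative == "less") == (mean(a) < mean(b))) 0 else 1
  } else {
    t <- unname(res$statistic); p <- res$p.value
  }
  structure(list(t = t, p_value = p, median_a = stats::median(a),
                 median_b = stats::median(b), alternative = alternative),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Welch one-sided comparison (A ", x$alternative, " B): t = ",
      signif(x$t, 4), ", p = ", signif(x$p_value, 3),
      "; medians ", signif(x$median_a, 4), " vs ",
      signif(x$median_b, 4), "\n", sep = "")
  invisible(x)
}

#' Metagene conservation profile over normalized peak length
#'
#' Each peak is rescaled to `[0, 1]` and divided into `n_bins` fractional
#' bins; per-base scores falling in a bin are averaged within the peak, and
#' bin values are averaged across peaks.
#'
#' @param track A [conservation_track()].
#' @param peaks A nonempty `peak_set`.
#' @param n_bins Number of bins (default 100).
#' @return Numeric vector of length `n_bins`.
#' @export
metagene_conservation <- function(track, peaks, n_bins = 100) {
  if (!nrow(peaks)) stop2("empty peak set")
  prof <- matrix(NA_real_, nrow(peaks), n_bins)
  for (i in seq_len(nrow(peaks))) {
    sc <- per_base_scores(track, peaks$chrom[i], peaks$start[i], peaks$end[i])
    w <- length(sc)
    for (b in seq_len(n_bins)) {
      lo <- floor((b - 1) * w / n_bins)
      hi <- max(ceiling(b * w / n_bins) - 1, lo)
      prof[i, b] <- mean(sc[(lo + 1):(hi + 1)])
    }
  }
  colMeans(prof)
}

per_base_scores <- function(track, chrom, start, end) {
  sc <- numeric(end - start)
  runs <- track[track$chrom == chrom & track$end > start & track$start < end, ,
                drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    lo <- max(runs$start[i], start); hi <- min(runs$end[i], end)
    sc[(lo - start + 1):(hi - start)] <- runs$score[i]
  }
  sc
}

#' Filter differentially accessible peaks by fold change
#'
#' Retains peaks whose between-group accessibility fold change is strictly
#' greater than two-fold in either direction. The fold-change estimation
#' itself is upstream; it is consumed here as a column.
#'
#' @param peaks data.frame with a `fold_change` column (ratio scale, or
#'   signed log2 with `log2 = TRUE`).
#' @param log2 Is `fold_change` on the log2 scale?
#' @return The retained rows.
#' @export
filter_differential_peaks <- function(peaks, log2 = FALSE) {
  if (!"fold_change" %in% names(peaks)) stop2("no fold_change column")
  fc <- peaks$fold_change
  keep <- if (log2) abs(fc) > 1 else fc > 2 | fc < 0.5
  peaks[which(keep), , drop = FALSE]
}

#' Intersect SNPs with (annotated) peaks
#'
#' A SNP at 0-based position `pos` is contained in a peak `[start, end)` iff
#' `start <= pos < end`.
#'
#' @param snps data.frame with `chrom` and `pos` (0-based base position).
#' @param peaks A `peak_set`, optionally annotated and optionally carrying a
#'   logical `differential` column.
#' @return List with `per_snp` (one row per SNP-in-peak containment) and
#'   `summary` (counts per peak category, plus differential counts when the
#'   flag is present; `n_snps_in_peaks` counts distinct SNPs).
#' @export
snp_overlap <- function(snps, peaks) {
  h <- suppressWarnings(GenomicRanges::findOverlaps(
    as_granges0(snps$chrom, snps$pos, snps$pos + 1),
    as_granges0(peaks$chrom, peaks$start, peaks$end)))
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  per_snp <- data.frame(snp = qi, chrom = snps$chrom[qi], pos = snps$pos[qi],
                        peak_id = peaks$peak_id[si],
                        category = peaks$category[si],
                        stringsAsFactors = FALSE)
  if ("differential" %in% names(peaks))
    per_snp$differential <- peaks$differential[si]
  summ <- list(n_snps_in_peaks = length(unique(qi)),
               by_category = table(factor(per_snp$category,
                                          levels = c("promoter", "gene_body",
                                                     "other", "unassigned"))))
  if ("differential" %in% names(peaks))
    summ$n_snps_in_differential <-
      length(unique(per_snp$snp[per_snp$differential]))
  list(per_snp = per_snp, summary = summ)
}
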