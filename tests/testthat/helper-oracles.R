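# Independent brute-force oracles and small fixture builders. These must not
# share code with the implementation they check.

# Step-up Benjamini-Hochberg, written directly from the definition.
oracle_bh <- function(p) {
  ok <- !is.na(p)
  q <- p[ok]
  m <- length(q)
  ord <- order(q)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, q[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- adj
  out
}

# Specificity index by exhaustive enumeration of every pairwise comparison.
oracle_si <- function(means) {
  G <- nrow(means); C <- ncol(means)
  si <- matrix(0, G, C, dimnames = dimnames(means))
  for (a in seq_len(C)) {
    ranks <- matrix(0, G, 0)
    for (b in seq_len(C)) {
      if (b == a) next
      d <- means[, a] - means[, b]
      # descending average-tie rank, computed directly
      r <- vapply(seq_len(G), function(g) {
        higher <- sum(d > d[g])
        ties <- sum(d == d[g])
        higher + (ties + 1) / 2
      }, numeric(1))
      ranks <- cbind(ranks, r)
    }
    si[, a] <- rowMeans(ranks)
  }
  rk <- si
  for (a in seq_len(C)) {
    v <- si[, a]
    rk[, a] <- vapply(seq_len(G), function(g)
      sum(v < v[g]) + (sum(v == v[g]) + 1) / 2, numeric(1))
  }
  list(si = si, rank = rk)
}

# Harmonization survivors by independent application of the filter
# predicates.
oracle_harmonize_survivors <- function(table, models_by_species) {
  species <- sort(sub("_gene$", "", grep("_gene$", names(table), value = TRUE)))
  conf_cols <- grep("^conf_", names(table), value = TRUE)
  t <- table[rowSums(table[, conf_cols, drop = FALSE] == 0) == 0, , drop = FALSE]
  t <- t[!duplicated(t), , drop = FALSE]
  bad <- rep(FALSE, nrow(t))
  for (s1 in species) for (s2 in setdiff(species, s1)) {
    partners <- split(t[[paste0(s2, "_transcript")]],
                      t[[paste0(s1, "_transcript")]])
    multi <- names(partners)[vapply(partners,
                                    function(v) length(unique(v)) > 1,
                                    logical(1))]
    bad <- bad | t[[paste0(s1, "_transcript")]] %in% multi
  }
  t <- t[!bad, , drop = FALSE]
  tuples <- unique(t[, paste0(species, "_gene"), drop = FALSE])
  amb <- rep(FALSE, nrow(tuples))
  for (s in species) {
    g <- tuples[[paste0(s, "_gene")]]
    amb <- amb | g %in% g[duplicated(g)]
  }
  tuples <- tuples[!amb, , drop = FALSE]
  if (!nrow(tuples)) return(character())
  len <- sapply(species, function(s) {
    gm <- models_by_species[[s]]$genes
    gm$length_bp[match(tuples[[paste0(s, "_gene")]], gm$gene_id)]
  })
  len <- matrix(len, nrow = nrow(tuples))
  keep <- apply(len, 1, max) / apply(len, 1, min) <= 2 &
    apply(len, 1, min) >= 1000
  apply(tuples[keep, , drop = FALSE], 1, paste, collapse = "|")
}

# Promoter/gene-body assignment by an all-pairs scan.
oracle_assign <- function(peaks, models) {
  g <- models$genes
  cat_out <- rep("other", nrow(peaks))
  gene_out <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ps <- peaks$start[i]; pe <- peaks$end[i]; pc <- peaks$chrom[i]
    best <- NULL
    for (j in seq_len(nrow(g))) {
      if (g$chrom[j] != pc) next
      tss <- g$tss[j]
      if (g$strand[j] == "+") { ws <- max(tss - 1000, 0); we <- tss + 101 }
      else { ws <- max(tss - 100, 0); we <- tss + 1001 }
      if (ps < we && pe > ws) {
        d <- max(ps - tss, tss - (pe - 1), 0)  # distance TSS -> peak
        cand <- list(d = d, id = g$gene_id[j])
        if (is.null(best) || cand$d < best$d ||
            (cand$d == best$d && cand$id < best$id)) best <- cand
      }
    }
    if (!is.null(best)) {
      cat_out[i] <- "promoter"; gene_out[i] <- best$id
      next
    }
    for (j in seq_len(nrow(g))) {
      if (g$chrom[j] != pc) next
      ov <- min(pe, g$end[j]) - max(ps, g$start[j])
      if (ov > 0) {
        d <- max(ps - g$tss[j], g$tss[j] - (pe - 1), 0)
        cand <- list(ov = ov, d = d, id = g$gene_id[j])
        if (is.null(best) || cand$ov > best$ov ||
            (cand$ov == best$ov && (cand$d < best$d ||
                                    (cand$d == best$d && cand$id < best$id))))
          best <- cand
      }
    }
    if (!is.null(best)) { cat_out[i] <- "gene_body"; gene_out[i] <- best$id }
  }
  data.frame(category = cat_out, gene_id = gene_out, stringsAsFactors = FALSE)
}

# Mean conservation by naive per-base expansion (missing bases score 0).
oracle_peak_mean <- function(track, chrom, start, end) {
  sc <- numeric(end - start)
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] != chrom) next
    lo <- max(track$start[i], start); hi <- min(track$end[i], end)
    if (lo < hi) sc[(lo - start + 1):(hi - start)] <- track$score[i]
  }
  mean(sc)
}

# SNP containment by an all-pairs scan.
oracle_snp_pairs <- function(snps, peaks) {
  hits <- 0
  for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(peaks))) {
    if (snps$chrom[i] == peaks$chrom[j] &&
        snps$pos[i] >= peaks$start[j] && snps$pos[i] < peaks$end[j])
      hits <- hits + 1
  }
  hits
}

# Small deterministic count fixture.
tiny_counts <- function(values, genes, samples) {
  matrix(as.integer(values), length(genes), length(samples),
         dimnames = list(genes, samples))
}

tiny_sample_table <- function(ids, species, cell_type = "granule",
                              replicate = seq_along(ids)) {
  data.frame(sample_id = ids, species = species, cell_type = cell_type,
             donor_id = paste0("d", seq_along(ids)),
             sex = rep(c("M", "F"), length.out = length(ids)),
             age = 30 + seq_along(ids), pmd = 10,
             replicate = replicate, stringsAsFactors = FALSE)
}

# Random conservation track with gaps on one chromosome.
random_track <- function(seed, chrom = "chr1", span = 6000, n_runs = 30) {
  set.seed(seed)
  cuts <- sort(sample(seq_len(span - 1), 2 * n_runs))
  starts <- cuts[seq(1, length(cuts), 2)]
  ends <- cuts[seq(2, length(cuts), 2)]
  keep <- starts < ends
  conservation_track(rep(chrom, sum(keep)), starts[keep], ends[keep],
                     round(runif(sum(keep)), 3))
}
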