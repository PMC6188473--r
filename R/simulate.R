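# Synthetic-data generators with planted ground truth.
#
# Every generator is a pure function of (config, seed): the same inputs give
# byte-identical outputs. Truth labels are returned alongside the data so
# that sensitivity and precision of every downstream caller can be computed
# without re-reading configs.

#' Simulation configuration for bulk counts
#'
#' Defaults describe a typical sorted-nuclei cross-species design: 2 species
#' x 3 cell types x 8 replicates (between the rodent and the 16-donor human
#' arms of such studies), negative-binomial counts with per-gene
#' dispersion around 0.05, log-normal baselines around 300 counts, and
#' planted gene classes — cell-type markers (8-fold), species-enriched genes
#' (8-fold, comfortably above the 4-fold calling threshold), pan-species
#' genes (8-fold in one species in every cell type), well-expressed
#' housekeeping genes, and nulls.
#'
#' @param n_genes Number of genes.
#' @param species,cell_types Factor levels of the design.
#' @param replicates Replicates per (species, cell type).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean counts
#'   for marker/null genes.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal per-gene NB
#'   dispersion.
#' @param size_factor_range Uniform range of per-sample size factors.
#' @param marker_fold,species_fold Planted fold changes (must be > 1);
#'   `species_fold` defaults to 8 (log2 = 3).
#' @param frac_marker,frac_species,frac_pan,frac_housekeeping Fractions of
#'   genes per planted class (must sum to <= 1; the rest are nulls).
#' @param species_baseline Uniform range of the lower-species baseline for
#'   species-enriched genes.
#' @param housekeeping_baseline Uniform range of housekeeping baselines
#'   (high, so the class clears expression cutoffs).
#' @param n_age_genes,age_log2fc_per_year Optional continuous-covariate
#'   effect: this many null genes get a log2-per-year slope on donor age.
#' @param subgroup_samples,n_subgroup_genes,subgroup_fold Optional planted
#'   donor-subgroup effect (indices of samples within the design, number of
#'   induced genes, fold).
#' @param seed Integer seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       species = c("mouse", "human"),
                       cell_types = c("granule", "basket", "glia"),
                       replicates = 8,
                       baseline_meanlog = log(300), baseline_sdlog = 1,
                       dispersion_meanlog = log(0.05), dispersion_sdlog = 0.5,
                       size_factor_range = c(0.7, 1.4),
                       marker_fold = 8, species_fold = 8,
                       frac_marker = 0.03, frac_species = 0.075,
                       frac_pan = 0.025, frac_housekeeping = 0.1,
                       species_baseline = c(150, 400),
                       housekeeping_baseline = c(1500, 4000),
                       n_age_genes = 0, age_log2fc_per_year = 0.02,
                       subgroup_samples = NULL, n_subgroup_genes = 0,
                       subgroup_fold = 4,
                       seed = 1) {
  cfg <- as.list(environment())
  fr <- frac_marker + frac_species + frac_pan + frac_housekeeping
  if (fr > 1) stop2("class fractions sum to more than 1")
  if (marker_fold <= 1 || species_fold <= 1 || subgroup_fold <= 1)
    stop2("folds must be > 1")
  if (n_genes < 1) stop2("n_genes must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate gene models
#'
#' Gene lengths are log-uniform over 200 bp to 50 kb, so a realistic share of
#' genes falls below the 1 kb filters downstream; both strands occur, the
#' longest of 1-4 transcripts spans the whole gene, and genes are laid out
#' with 5 kb gaps on three contigs so promoter windows never collide.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param prefix Gene id prefix.
#' @return A [gene_models()] object.
#' @export
simulate_gene_models <- function(n_genes, seed = 1, prefix = "g") {
  if (n_genes < 1) stop2("n_genes must be >= 1")
  with_seed(substream_seed(seed, "gene_models"), {
    ids <- sprintf("%s%05d", prefix, seq_len(n_genes))
    len <- as.integer(round(exp(stats::runif(n_genes, log(200), log(50000)))))
    if (!any(len < 1000)) len[1] <- 800L
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    if (length(unique(strand)) == 1 && n_genes >= 2)
      strand[2] <- setdiff(c("+", "-"), strand[1])
    chrom <- paste0("chr", (seq_len(n_genes) - 1) %% 3 + 1)
    start <- integer(n_genes)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      start[i] <- 10000L + cumsum(c(0L, utils::head(len[i], -1) + 5000L))
    }
    genes <- data.frame(gene_id = ids, chrom = chrom, strand = strand,
                        start = start, end = start + len,
                        stringsAsFactors = FALSE)
    tx <- lapply(seq_len(n_genes), function(g) {
      k <- sample(1:4, 1)
      t_start <- c(start[g], if (k > 1)
        start[g] + sample.int(max(len[g] %/% 2, 1), k - 1, replace = TRUE))
      t_end <- c(start[g] + len[g], if (k > 1)
        pmin(t_start[-1] + pmax(len[g] %/% 3, 50L), start[g] + len[g]))
      data.frame(gene_id = ids[g],
                 transcript_id = sprintf("%s_t%d", ids[g], seq_len(k)),
                 start = as.integer(t_start), end = as.integer(t_end),
                 stringsAsFactors = FALSE)
    })
    gene_models(genes, do.call(rbind, tx))
  })
}

#' Simulate a cross-species ortholog table with planted filter violations
#'
#' Builds a clean 1:1 pairing of the (>= 1 kb, length-matched) genes of each
#' species, then injects violations at the requested fractions:
#' low-confidence pairs, exact duplicate rows, transcripts orthologous to
#' more than one transcript in another species, extreme cross-species length
#' ratios (by re-pairing short genes with long ones), and pairs involving
#' genes under 1 kb. The returned truth lists which gene tuples survive the
#' harmonization cascade, computed by direct application of the filter
#' predicates.
#'
#' @param models_by_species Named list (>= 2 species) of [gene_models()].
#' @param frac_low_conf,frac_duplicate,frac_non_one_to_one,frac_length_divergent
#'   Fractions in `[0, 1]` of base pairs receiving each violation
#'   (`frac_length_divergent` is split between ratio violations and sub-1 kb
#'   pairs).
#' @param seed Integer seed.
#' @return List with `table` (ortholog table), `truth` (data.frame of base
#'   tuples with planted violation flags and `survives`), and `species`.
#' @export
simulate_ortholog_table <- function(models_by_species, frac_low_conf = 0,
                                    frac_duplicate = 0,
                                    frac_non_one_to_one = 0,
                                    frac_length_divergent = 0, seed = 1) {
  fr <- c(frac_low_conf, frac_duplicate, frac_non_one_to_one,
          frac_length_divergent)
  if (any(fr < 0 | fr > 1)) stop2("fractions must lie in [0, 1]")
  species <- sort(names(models_by_species))
  if (length(species) < 2) stop2("need >= 2 species")
  with_seed(substream_seed(seed, "ortholog_table"), {
    longest <- lapply(models_by_species, function(m) {
      g <- m$genes
      tx <- vapply(g$gene_id, longest_transcript, character(1), models = m)
      data.frame(gene_id = g$gene_id, transcript_id = unname(tx),
                 length_bp = g$length_bp, stringsAsFactors = FALSE)
    })
    elig <- lapply(longest, function(d) {
      d <- d[d$length_bp >= 1000, , drop = FALSE]
      d[order(d$length_bp, d$gene_id), , drop = FALSE]
    })
    n <- min(vapply(elig, nrow, integer(1)))
    cols <- list()
    for (s in species) {
      e <- elig[[s]][seq_len(n), ]
      cols[[paste0(s, "_gene")]] <- e$gene_id
      cols[[paste0(s, "_transcript")]] <- e$transcript_id
      cols[[paste0(s, "_length")]] <- e$length_bp
    }
    tab <- as.data.frame(cols, stringsAsFactors = FALSE)
    # drop base pairs that violate the 2-fold rule by accident of pairing
    lenm <- as.matrix(tab[, paste0(species, "_length")])
    tab <- tab[apply(lenm, 1, max) / apply(lenm, 1, min) <= 2, , drop = FALSE]
    n <- nrow(tab)
    pairs <- utils::combn(species, 2)
    for (j in seq_len(ncol(pairs)))
      tab[[paste0("conf_", pairs[1, j], "_", pairs[2, j])]] <- rep(1, n)

    pick <- function(frac, avoid = integer()) {
      k <- floor(frac * n)
      pool <- setdiff(seq_len(n), avoid)
      if (k == 0 || !length(pool)) integer() else
        sort(sample(pool, min(k, length(pool))))
    }
    s1 <- species[1]; s2 <- species[2]

    i_low <- pick(frac_low_conf)
    i_dup <- pick(frac_duplicate, avoid = i_low)
    i_121 <- pick(frac_non_one_to_one, avoid = c(i_low, i_dup))
    i_div <- pick(frac_length_divergent / 2, avoid = c(i_low, i_dup, i_121))

    conf1 <- paste0("conf_", sort(c(s1, s2))[1], "_", sort(c(s1, s2))[2])
    tab[i_low, conf1] <- 0

    # length divergence: re-pair the selected tuples' second-species side so
    # short genes meet long ones
    if (length(i_div) >= 2) {
      ordA <- i_div[order(tab[i_div, paste0(s1, "_length")])]
      ordB <- i_div[order(-tab[i_div, paste0(s2, "_length")])]
      for (col in paste0(s2, c("_gene", "_transcript", "_length")))
        tab[ordA, col] <- tab[ordB, col]
    }

    extra <- list()
    # duplicates: exact copies of the selected rows
    if (length(i_dup)) extra[[length(extra) + 1]] <- tab[i_dup, , drop = FALSE]
    # non-1:1: cross rows pairing tuple i's first-species transcript with
    # tuple j's second-species transcript (both offenders die at the filter)
    if (length(i_121) >= 2) {
      j_121 <- c(i_121[-1], i_121[1])
      cross <- tab[i_121, , drop = FALSE]
      for (col in paste0(s2, c("_gene", "_transcript", "_length")))
        cross[[col]] <- tab[j_121, col]
      extra[[length(extra) + 1]] <- cross
    } else i_121 <- integer()

    # sub-1 kb pairs from the ineligible pool
    shorts <- lapply(longest, function(d) d[d$length_bp < 1000, , drop = FALSE])
    n_short <- min(c(vapply(shorts, nrow, integer(1)),
                     floor(frac_length_divergent / 2 * n)))
    if (n_short > 0) {
      sh <- tab[rep(1, n_short), , drop = FALSE]
      for (s in species) {
        d <- shorts[[s]][seq_len(n_short), ]
        sh[[paste0(s, "_gene")]] <- d$gene_id
        sh[[paste0(s, "_transcript")]] <- d$transcript_id
        sh[[paste0(s, "_length")]] <- d$length_bp
      }
      extra[[length(extra) + 1]] <- sh
    }

    truth <- tab[, paste0(species, "_gene"), drop = FALSE]
    truth$planted_low_conf <- seq_len(n) %in% i_low
    truth$planted_duplicate <- seq_len(n) %in% i_dup
    truth$planted_non_one_to_one <- seq_len(n) %in% c(i_121)
    lenm <- as.matrix(tab[, paste0(species, "_length")])
    truth$length_violation <- apply(lenm, 1, max) / apply(lenm, 1, min) > 2 |
      apply(lenm, 1, min) < 1000
    truth$survives <- !truth$planted_low_conf & !truth$planted_non_one_to_one &
      !truth$length_violation
    truth$tuple_id <- apply(truth[, paste0(species, "_gene"), drop = FALSE],
                            1, paste, collapse = "|")

    table <- do.call(rbind, c(list(tab), extra))
    table <- table[, setdiff(names(table), paste0(species, "_length"))]
    rownames(table) <- NULL
    # shuffle row order so nothing downstream can rely on it
    table <- table[sample(nrow(table)), , drop = FALSE]
    rownames(table) <- NULL
    list(table = table, truth = truth, species = species)
  })
}

#' Simulate bulk sorted-nuclei counts with planted gene classes
#'
#' Counts are negative-binomial with mean
#' `baseline x size_factor x 2^(planted effects)` and per-gene dispersion;
#' markers are elevated in one cell type across all species, species-enriched
#' genes in one species within one cell type, pan-species genes in one
#' species across all cell types. Optional continuous age effects and a
#' planted donor-subgroup induction support covariate and partition-null
#' tests.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (genes x samples), `samples` (metadata table),
#'   `truth` (per-gene class, target, log2 effect, baseline, dispersion) and
#'   `models` (gene models supplying whole-gene lengths).
#' @export
simulate_bulk_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  models <- simulate_gene_models(cf$n_genes, seed = substream_seed(cf$seed, "models"))
  with_seed(substream_seed(cf$seed, "bulk_counts"), {
    G <- cf$n_genes
    ids <- models$genes$gene_id
    design <- expand.grid(replicate = seq_len(cf$replicates),
                          cell_type = cf$cell_types, species = cf$species,
                          stringsAsFactors = FALSE)
    S <- nrow(design)
    if (cf$replicates < 2)
      warning("fewer than 2 replicates per condition: variance estimation ",
              "will be degenerate")
    donors <- paste0(design$species, "_d", design$replicate)
    ages <- stats::setNames(
      round(seq(22, 88, length.out = cf$replicates), 1)[design$replicate],
      NULL)
    samples <- data.frame(
      sample_id = paste(design$species, design$cell_type, design$replicate,
                        sep = "_"),
      species = design$species, cell_type = design$cell_type,
      donor_id = donors, sex = c("M", "F")[design$replicate %% 2 + 1],
      age = ages, pmd = round(stats::runif(S, 4, 30), 1),
      replicate = design$replicate, stringsAsFactors = FALSE)
    validate_sample_table(samples)

    ## gene classes
    n_mk <- floor(cf$frac_marker * G); n_sp <- floor(cf$frac_species * G)
    n_pan <- floor(cf$frac_pan * G); n_hk <- floor(cf$frac_housekeeping * G)
    cls <- rep("null", G)
    idx <- sample(G)
    take <- function(k) {
      if (k == 0) return(integer())
      out <- idx[seq_len(k)]; idx <<- idx[-seq_len(k)]; out
    }
    i_mk <- take(n_mk); i_sp <- take(n_sp); i_pan <- take(n_pan)
    i_hk <- take(n_hk)
    cls[i_mk] <- "marker"; cls[i_sp] <- "species_enriched"
    cls[i_pan] <- "pan_species"; cls[i_hk] <- "housekeeping"

    truth <- data.frame(gene_id = ids, class = cls,
                        cell_type = NA_character_, species = NA_character_,
                        log2_effect = 0, stringsAsFactors = FALSE)
    truth$cell_type[i_mk] <- rep_len(cf$cell_types, n_mk)
    truth$log2_effect[i_mk] <- log2(cf$marker_fold)
    truth$cell_type[i_sp] <- rep_len(cf$cell_types, n_sp)
    truth$species[i_sp] <- rep_len(rep(cf$species, each = length(cf$cell_types)),
                                   n_sp)
    truth$log2_effect[i_sp] <- log2(cf$species_fold)
    truth$species[i_pan] <- rep_len(cf$species, n_pan)
    truth$log2_effect[i_pan] <- log2(cf$species_fold)

    baseline <- exp(stats::rnorm(G, cf$baseline_meanlog, cf$baseline_sdlog))
    baseline[i_sp] <- stats::runif(n_sp, cf$species_baseline[1],
                                   cf$species_baseline[2])
    baseline[i_hk] <- stats::runif(n_hk, cf$housekeeping_baseline[1],
                                   cf$housekeeping_baseline[2])
    truth$baseline <- baseline
    alpha <- exp(stats::rnorm(G, cf$dispersion_meanlog, cf$dispersion_sdlog))
    truth$dispersion <- alpha

    ## optional planted age slopes (on null genes)
    i_age <- integer()
    if (cf$n_age_genes > 0) {
      i_age <- utils::head(which(cls == "null"), cf$n_age_genes)
      truth$class[i_age] <- "age"
      truth$log2_effect[i_age] <- cf$age_log2fc_per_year
    }
    ## optional planted subgroup induction (on null genes)
    i_sub <- integer()
    if (cf$n_subgroup_genes > 0) {
      if (is.null(cf$subgroup_samples)) stop2("subgroup_samples not set")
      i_sub <- utils::tail(which(truth$class == "null"), cf$n_subgroup_genes)
      truth$class[i_sub] <- "subgroup"
      truth$log2_effect[i_sub] <- log2(cf$subgroup_fold)
    }

    sf <- stats::runif(S, cf$size_factor_range[1], cf$size_factor_range[2])
    mu <- outer(baseline, sf)
    for (g in i_mk) {
      j <- samples$cell_type == truth$cell_type[g]
      mu[g, j] <- mu[g, j] * cf$marker_fold
    }
    for (g in i_sp) {
      j <- samples$cell_type == truth$cell_type[g] &
        samples$species == truth$species[g]
      mu[g, j] <- mu[g, j] * cf$species_fold
    }
    for (g in i_pan) {
      j <- samples$species == truth$species[g]
      mu[g, j] <- mu[g, j] * cf$species_fold
    }
    if (length(i_age)) {
      dev <- samples$age - mean(samples$age)
      for (g in i_age) mu[g, ] <- mu[g, ] * 2^(cf$age_log2fc_per_year * dev)
    }
    if (length(i_sub)) {
      for (g in i_sub)
        mu[g, cf$subgroup_samples] <- mu[g, cf$subgroup_samples] *
          cf$subgroup_fold
    }

    counts <- matrix(
      stats::rnbinom(G * S, mu = as.vector(mu), size = rep(1 / alpha, S)),
      G, S, dimnames = list(ids, samples$sample_id))
    storage.mode(counts) <- "integer"
    list(counts = counts, samples = samples, truth = truth, models = models)
  })
}

#' Simulate a sparse single-cell / single-nucleus matrix
#'
#' Poisson counts with log-normal per-cell library sizes, per-cluster marker
#' genes, and per-(gene, cell) Bernoulli dropout (zero inflation). Planted
#' violators of the downstream quality filters are included and tagged in
#' truth: cells with fewer than 300 or more than 5000 detected genes, and
#' genes detected in fewer than 3 cells; all other cells and genes are
#' guaranteed to pass the filters.
#'
#' @param n_genes Number of genes (>= 6000 recommended so the 5000
#'   detected-gene boundary can be exceeded).
#' @param clusters Number of clusters (>= 2).
#' @param cells_per_cluster Cells per cluster.
#' @param dropout Per-(gene, cell) zeroing probability in `[0, 1)`.
#' @param n_markers_per_cluster Planted cluster markers (8-fold).
#' @param seed Integer seed.
#' @return List with `counts` (sparse dgCMatrix), `clusters` (label per
#'   cell), and `truth` (violator cells/genes and marker table).
#' @export
simulate_single_cell <- function(n_genes = 6000, clusters = 3,
                                 cells_per_cluster = 100, dropout = 0.3,
                                 n_markers_per_cluster = 20, seed = 1) {
  if (clusters < 2) stop2("need >= 2 clusters")
  with_seed(substream_seed(seed, "single_cell"), {
    G <- n_genes
    cl_names <- paste0("cluster", seq_len(clusters))
    cl <- rep(cl_names, each = cells_per_cluster)
    n_cells <- length(cl)
    gene_ids <- sprintf("sc%05d", seq_len(G))
    cell_ids <- sprintf("cell%04d", seq_len(n_cells))

    base <- exp(stats::rnorm(G, log(0.5), 1.2))
    markers <- data.frame(gene_id = character(), cluster = character())
    mu <- outer(base, exp(stats::rnorm(n_cells, 0, 0.3)))
    mi <- 0
    for (k in seq_len(clusters)) {
      gi <- mi + seq_len(n_markers_per_cluster); mi <- mi + n_markers_per_cluster
      base[gi] <- pmax(base[gi], 1)
      mu[gi, cl == cl_names[k]] <- base[gi] * 8
      mu[gi, cl != cl_names[k]] <- base[gi] * 0.25
      markers <- rbind(markers, data.frame(gene_id = gene_ids[gi],
                                           cluster = cl_names[k]))
    }
    counts <- matrix(stats::rpois(G * n_cells, as.vector(mu)), G, n_cells)
    keep <- matrix(stats::rbinom(G * n_cells, 1, 1 - dropout), G, n_cells)
    counts <- counts * keep

    ## planted violators; cells exceeding the 5000 detected-gene boundary
    ## are only possible when the panel is large enough
    low_cells <- utils::tail(seq_len(n_cells), 3)
    high_cells <- if (G > 5100) utils::head(seq_len(n_cells), 2) else integer()
    for (j in low_cells) counts[-seq_len(100), j] <- 0L
    for (j in high_cells)
      counts[seq_len(5500), j] <- pmax(counts[seq_len(5500), j], 1L)
    low_genes <- (G - 9):G
    counts[low_genes, ] <- 0L
    mid <- setdiff(seq_len(n_cells), c(low_cells, high_cells))
    for (g in low_genes) counts[g, mid[seq_len(2)]] <- 1L

    ## guarantee that non-planted entities pass the filters
    normal_cells <- setdiff(seq_len(n_cells), c(low_cells, high_cells))
    det_cells <- rowSums(counts[, , drop = FALSE] > 0)
    fix_g <- setdiff(which(det_cells < 3), low_genes)
    for (g in fix_g) counts[g, normal_cells[1:3]] <- pmax(counts[g, normal_cells[1:3]], 1L)
    keep_g <- setdiff(seq_len(G), low_genes)
    det_genes <- colSums(counts[keep_g, , drop = FALSE] > 0)
    for (j in normal_cells) {
      if (det_genes[j] < 300) {
        zero <- keep_g[counts[keep_g, j] == 0][seq_len(300 - det_genes[j])]
        counts[zero, j] <- 1L
      } else if (det_genes[j] > 5000) {
        nz <- keep_g[counts[keep_g, j] > 0]
        counts[nz[seq_len(det_genes[j] - 5000)], j] <- 0L
      }
    }

    dimnames(counts) <- list(gene_ids, cell_ids)
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         clusters = stats::setNames(cl, cell_ids),
         truth = list(violator_cells = cell_ids[c(low_cells, high_cells)],
                      low_detection_cells = cell_ids[low_cells],
                      high_detection_cells = cell_ids[high_cells],
                      violator_genes = gene_ids[low_genes],
                      markers = markers))
  })
}

#' Simulate ATAC peaks and a conservation track tied to expression truth
#'
#' Promoter peaks (400 bp, inside the promoter window) are placed for genes
#' expressed in the focal (species, cell type): housekeeping genes, markers
#' of the focal cell type, and genes species-enriched in the focal pair.
#' Gene-body peaks (300 bp) are placed at the span midpoint of the same genes
#' when the gene is long enough to keep them outside the promoter window.
#' Conservation scores are drawn so peaks of species-enriched genes average
#' `contrast` lower than peaks of housekeeping/marker genes.
#'
#' @param models A [gene_models()] object.
#' @param truth Truth table from [simulate_bulk_counts()].
#' @param contrast Mean conservation deficit of species-enriched peaks.
#' @param focal_species,focal_cell_type The profiled population.
#' @param seed Integer seed.
#' @return List with `peaks` (annotated-by-construction classes in
#'   `peak_truth`), `track`, and `peak_truth` (peak_id, gene_id, class).
#' @export
simulate_peaks_and_conservation <- function(models, truth, contrast = 0.2,
                                            focal_species, focal_cell_type,
                                            seed = 1) {
  if (contrast < 0 || contrast > 0.5) stop2("contrast must lie in [0, 0.5]")
  with_seed(substream_seed(seed, "peaks_conservation"), {
    g <- models$genes
    expressed <- truth$class == "housekeeping" |
      (truth$class == "marker" & truth$cell_type == focal_cell_type) |
      (truth$class == "species_enriched" & truth$species == focal_species &
         truth$cell_type == focal_cell_type)
    expressed[is.na(expressed)] <- FALSE
    gi <- match(truth$gene_id[expressed], g$gene_id)
    cls <- truth$class[expressed]

    plus <- g$strand[gi] == "+"
    p_start <- ifelse(plus, g$tss[gi] - 700L, g$tss[gi] + 300L)
    p_end <- p_start + 400L
    peaks <- data.frame(chrom = g$chrom[gi], start = pmax(p_start, 0L),
                        end = p_end,
                        gene_id = g$gene_id[gi], class = cls,
                        kind = "promoter", stringsAsFactors = FALSE)
    long <- g$length_bp[gi] >= 1500
    if (any(long)) {
      centre <- (g$start[gi][long] + g$end[gi][long]) %/% 2L
      peaks <- rbind(peaks, data.frame(
        chrom = g$chrom[gi][long], start = centre - 150L, end = centre + 150L,
        gene_id = g$gene_id[gi][long], class = cls[long], kind = "gene_body",
        stringsAsFactors = FALSE))
    }
    peaks$peak_id <- sprintf("pk%05d", seq_len(nrow(peaks)))

    mu0 <- 0.65
    level <- ifelse(peaks$class == "species_enriched", mu0 - contrast, mu0)
    score <- pmin(pmax(stats::rnorm(nrow(peaks), level, 0.03), 0.01), 0.99)
    ## split each peak into 4 equal runs with small per-run jitter around the
    ## peak level, keeping the per-peak mean at the drawn level
    runs <- lapply(seq_len(nrow(peaks)), function(i) {
      w <- peaks$end[i] - peaks$start[i]
      b <- round(seq(peaks$start[i], peaks$end[i], length.out = 5))
      jit <- stats::rnorm(4, 0, 0.01); jit <- jit - mean(jit)
      data.frame(chrom = peaks$chrom[i], start = b[-5], end = b[-1],
                 score = pmin(pmax(score[i] + jit, 0), 1),
                 stringsAsFactors = FALSE)
    })
    runs <- do.call(rbind, runs)
    track <- conservation_track(runs$chrom, runs$start, runs$end, runs$score)

    ps <- peak_set(peaks$chrom, peaks$start, peaks$end, peak_id = peaks$peak_id)
    list(peaks = ps, track = track,
         peak_truth = data.frame(peak_id = peaks$peak_id,
                                 gene_id = peaks$gene_id, class = peaks$class,
                                 kind = peaks$kind, level = score,
                                 stringsAsFactors = FALSE))
  })
}
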