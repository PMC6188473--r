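# Configuration-driven orchestration of the cross-species analysis, plus the
# fixture writer that produces a complete synthetic input directory.

#' Write a complete synthetic fixture directory
#'
#' Simulates a bulk cross-species study from a [sim_config()], re-expresses
#' it as the on-disk inputs the pipeline consumes (per-species counts and
#' gene models with species-prefixed identifiers, sample metadata, an
#' ortholog table with planted filter violations, peaks and a conservation
#' bedGraph for the focal population, and the truth table), and writes them
#' under `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param orth_frac Fraction used for each planted ortholog violation class.
#' @param contrast Conservation deficit of species-enriched peaks.
#' @return Invisibly, the list of written paths.
#' @export
simulate_fixture <- function(dir, config = sim_config(), orth_frac = 0.05,
                             contrast = 0.2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bulk <- simulate_bulk_counts(config)
  seed <- config$seed
  species <- config$species

  rename_models <- function(models, sp) {
    g <- models$genes; tx <- models$transcripts
    g$gene_id <- paste0(sp, ":", g$gene_id)
    tx$gene_id <- paste0(sp, ":", tx$gene_id)
    tx$transcript_id <- paste0(sp, ":", tx$transcript_id)
    gene_models(g[, c("gene_id", "chrom", "strand", "start", "end")], tx)
  }
  models_by_species <- lapply(stats::setNames(species, species),
                              function(sp) rename_models(bulk$models, sp))
  orth <- simulate_ortholog_table(models_by_species,
                                  frac_low_conf = orth_frac,
                                  frac_duplicate = orth_frac,
                                  frac_non_one_to_one = orth_frac,
                                  frac_length_divergent = orth_frac,
                                  seed = seed)
  pk <- simulate_peaks_and_conservation(bulk$models, bulk$truth,
                                        contrast = contrast,
                                        focal_species = species[1],
                                        focal_cell_type = config$cell_types[1],
                                        seed = seed)

  paths <- list()
  for (sp in species) {
    cm <- bulk$counts[, bulk$samples$species == sp, drop = FALSE]
    rownames(cm) <- paste0(sp, ":", rownames(cm))
    paths[[paste0("counts_", sp)]] <- file.path(dir, paste0("counts_", sp, ".tsv"))
    write_counts(cm, paths[[paste0("counts_", sp)]], seed = seed)
    paths[[paste0("models_", sp)]] <- file.path(dir, paste0("models_", sp, ".tsv"))
    write_gene_models(models_by_species[[sp]], paths[[paste0("models_", sp)]],
                      seed = seed)
  }
  paths$samples <- file.path(dir, "samples.tsv")
  write_sample_table(bulk$samples, paths$samples, seed = seed)
  paths$orthologs <- file.path(dir, "orthologs.tsv")
  write_ortholog_table(orth$table, paths$orthologs, seed = seed)
  paths$truth <- file.path(dir, "truth.tsv")
  write_tsv_commented(bulk$truth, paths$truth, seed = seed)
  paths$ortholog_truth <- file.path(dir, "ortholog_truth.tsv")
  write_tsv_commented(orth$truth, paths$ortholog_truth, seed = seed)
  paths$peaks <- file.path(dir, "peaks.bed")
  write_intervals(pk$peaks, paths$peaks)
  paths$conservation <- file.path(dir, "conservation.bedGraph")
  write_intervals(pk$track, paths$conservation)
  paths$peak_truth <- file.path(dir, "peak_truth.tsv")
  write_tsv_commented(pk$peak_truth, paths$peak_truth, seed = seed)
  invisible(paths)
}

pipeline_known_keys <- c("counts", "sample_table", "gene_models", "orthologs",
                         "out_dir", "seed", "thresholds", "si",
                         "partition_null", "peaks", "single_cell")

#' Validate a pipeline configuration
#'
#' Required keys: `counts` and `gene_models` (named per-species path lists),
#' `sample_table`, `orthologs`, `out_dir`, `seed`. Optional blocks:
#' `thresholds` (arguments to [enrichment_thresholds()]), `si`
#' (`iterations`), `partition_null` (`species`, `cell_type`, `k`), `peaks`
#' (`peaks`, `conservation`). Unknown keys are rejected; all referenced
#' input files must exist before any computation starts.
#'
#' @param config List, or path to a YAML file.
#' @return The validated config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown)) stop2("unknown config key(s): ",
                             paste(unknown, collapse = ", "))
  need <- c("counts", "sample_table", "gene_models", "orthologs", "out_dir",
            "seed")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop2("config is missing: ", paste(miss, collapse = ", "))
  files <- c(unlist(config$counts), config$sample_table,
             unlist(config$gene_models), config$orthologs,
             config$peaks$peaks, config$peaks$conservation)
  absent <- files[!file.exists(files)]
  if (length(absent)) stop2("input file does not exist: ", absent[1])
  if (!setequal(names(config$counts), names(config$gene_models)))
    stop2("counts and gene_models must name the same species")
  config
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop2("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
}

#' Run the cross-species comparison pipeline
#'
#' Executes ortholog harmonization, normalization, per-cell-type and pooled
#' species differential expression, specificity-index ranking per species,
#' species-enrichment and housekeeping calls, and (when configured) the
#' donor-partition null and peak conservation comparison. All randomness
#' derives from the single config seed through named substreams, so a rerun
#' with the same config reproduces every output byte-identically; the
#' manifest records versions, seed, thresholds, and input/output checksums.
#'
#' @param config A [pipeline_config()] list or YAML path.
#' @return Invisibly, a list with the principal in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  species <- names(config$counts)
  counts_by_species <- run_stage("read_counts", lapply(config$counts, read_counts))
  samples <- run_stage("read_samples", read_sample_table(config$sample_table))
  models_by_species <- run_stage("read_models",
                                 lapply(config$gene_models, read_gene_models))
  orth <- run_stage("read_orthologs", read_ortholog_table(config$orthologs))

  universe <- run_stage("harmonize", harmonize(orth, models_by_species))
  cross <- run_stage("subset_counts",
                     subset_counts_to_universe(counts_by_species, universe))
  samples <- samples[match(colnames(cross), samples$sample_id), ]
  sf <- run_stage("size_factors", size_factors(cross))

  th <- do.call(enrichment_thresholds, config$thresholds %||% list())
  lens <- lapply(stats::setNames(species, species), function(sp) {
    g <- models_by_species[[sp]]$genes
    stats::setNames(g$length_bp, g$gene_id)[universe[[paste0(sp, "_gene")]]]
  })

  log2fpkm_ct <- list(); de_ct <- list()
  cts <- unique(samples$cell_type)
  two_sp <- sort(unique(samples$species))[1:2]
  for (ct in cts) {
    j <- samples$cell_type == ct
    de_ct[[ct]] <- run_stage(
      paste0("differential_expression_", ct),
      nb_wald_test(cross[, j, drop = FALSE], samples[j, ], test = "species",
                   contrast = c(two_sp[2], two_sp[1]), sf = sf[j]))
    log2fpkm_ct[[ct]] <- run_stage(
      paste0("fpkm_summary_", ct),
      vapply(species, function(sp) {
        jj <- samples$cell_type == ct & samples$species == sp
        rowMeans(suppressWarnings(
          log2(fpkm(cross[, jj, drop = FALSE],
                    stats::setNames(lens[[sp]], rownames(cross))))))
      }, numeric(nrow(cross))))
  }
  de_pan <- run_stage("pan_species_de",
                      nb_wald_test(cross, samples, test = "species",
                                   contrast = c(two_sp[2], two_sp[1]),
                                   blocking = "cell_type", sf = sf))
  calls <- run_stage("species_enrichment",
                     call_species_enriched(de_ct, log2fpkm_ct, de_pan, th))
  lf_all <- vapply(species, function(sp) {
    jj <- samples$species == sp
    rowMeans(suppressWarnings(
      log2(fpkm(cross[, jj, drop = FALSE],
                stats::setNames(lens[[sp]], rownames(cross))))))
  }, numeric(nrow(cross)))
  housekeeping <- run_stage("housekeeping",
                            define_housekeeping(de_pan, lf_all, th))

  si_iter <- config$si$iterations %||% 1000
  si_tables <- run_stage("specificity_index", {
    lapply(stats::setNames(species, species), function(sp) {
      cm <- counts_by_species[[sp]]
      g <- models_by_species[[sp]]$genes
      ct_labels <- samples$cell_type[match(colnames(cm), samples$sample_id)]
      inp <- si_preprocess(cm, stats::setNames(g$length_bp, g$gene_id),
                           ct_labels)
      si_sampled(inp, iterations = si_iter,
                 seed = substream_seed(seed, paste0("si_", sp)))
    })
  })

  pn <- NULL
  if (!is.null(config$partition_null)) {
    pc <- config$partition_null
    j <- samples$cell_type == pc$cell_type & samples$species == pc$species
    pn <- run_stage("partition_null",
                    partition_null(cross[, j, drop = FALSE], k = pc$k,
                                   alpha = pc$alpha %||% 0.01))
  }
  cons <- NULL
  if (!is.null(config$peaks)) {
    cons <- run_stage("peaks_conservation", {
      pk <- read_intervals(config$peaks$peaks, kind = "bed")
      track <- read_intervals(config$peaks$conservation, kind = "bedgraph")
      focal_sp <- config$peaks$focal_species %||% species[1]
      models0 <- models_by_species[[focal_sp]]
      pk <- assign_peaks(pk, models0)
      means <- peak_conservation(track, pk)
      ## map tuple ids from the calls back to the focal species' gene ids
      focal_gene <- function(tuples) {
        i <- match(tuples, universe$tuple_id)
        universe[[paste0(focal_sp, "_gene")]][i[!is.na(i)]]
      }
      enr <- focal_gene(unique(unlist(lapply(calls$sets,
                                             function(x) x[[focal_sp]]))))
      hk <- focal_gene(housekeeping)
      grp_a <- means[!is.na(pk$gene_id) & pk$gene_id %in% enr]
      grp_b <- means[!is.na(pk$gene_id) & pk$gene_id %in% hk]
      list(peaks = pk, means = means,
           comparison = if (length(grp_a) >= 2 && length(grp_b) >= 2)
             compare_groups(grp_a, grp_b, "less") else NULL)
    })
  }

  ## outputs
  run_stage("write_outputs", {
    write_tsv_commented(as.data.frame(universe), file.path(out, "universe.tsv"),
                        seed = seed)
    write_tsv_commented(attr(universe, "audit"), file.path(out, "audit.tsv"),
                        seed = seed)
    for (ct in names(de_ct))
      write_tsv_commented(as.data.frame(de_ct[[ct]]),
                          file.path(out, paste0("de_", ct, ".tsv")), seed = seed)
    write_tsv_commented(calls$calls, file.path(out, "enriched_calls.tsv"),
                        seed = seed)
    write_tsv_commented(data.frame(gene_id = housekeeping),
                        file.path(out, "housekeeping.tsv"), seed = seed)
    for (sp in species) {
      tb <- si_tables[[sp]]
      write_tsv_commented(data.frame(gene_id = tb$gene_ids, tb$avg_rank,
                                     check.names = FALSE),
                          file.path(out, paste0("si_", sp, ".tsv")), seed = seed)
    }
    if (!is.null(pn))
      write_tsv_commented(as.data.frame(pn),
                          file.path(out, "partition_null.tsv"), seed = seed)
  })

  inputs <- c(unlist(config$counts), config$sample_table,
              unlist(config$gene_models), config$orthologs)
  outputs <- list.files(out, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out, "manifest.json"))
  manifest <- list(tool = "orthocell", version = pkg_version_string(),
                   seed = seed, thresholds = th,
                   si_iterations = si_iter,
                   input_checksums = as.list(tools::md5sum(inputs)),
                   output_checksums = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(universe = universe, de_by_celltype = de_ct, de_pan = de_pan,
                 calls = calls, housekeeping = housekeeping,
                 si_tables = si_tables, partition_null = pn,
                 conservation = cons, manifest = manifest))
}
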