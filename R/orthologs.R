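# Harmonization of cross-species ortholog annotations into a high-confidence
# 1:1 gene universe.

#' Harmonize an ortholog table into a high-confidence 1:1 gene universe
#'
#' Filters applied in order, with per-step removals recorded in an audit log:
#' \enumerate{
#'   \item drop rows containing any low-confidence pair (confidence = 0);
#'   \item drop exact-duplicate rows;
#'   \item drop every row of any transcript annotated as orthologous to more
#'     than one transcript in another species (strict 1:1 at transcript
#'     level; all participating rows are removed);
#'   \item collapse rows to gene tuples, choosing each gene's longest
#'     transcript as its annotation; gene tuples that leave a gene in more
#'     than one tuple are dropped as ambiguous;
#'   \item drop tuples whose whole-gene genomic lengths (UTRs included)
#'     differ by more than two-fold across species (ratio exactly 2 is
#'     retained) or fall below 1 kb in any species (exactly 1000 bp is
#'     retained).
#' }
#'
#' @param table Ortholog table (see [validate_ortholog_table()]).
#' @param models_by_species Named list of [gene_models()] objects, one per
#'   species in the table; every transcript in the table must resolve.
#' @return data.frame of class `harmonized_universe`: one row per surviving
#'   gene tuple with `<species>_gene`, `<species>_transcript` (longest) and
#'   `<species>_length` columns; the audit log is in `attr(, "audit")` and
#'   per-step removed rows in `attr(, "removed")`.
#' @export
harmonize <- function(table, models_by_species) {
  species <- validate_ortholog_table(table)
  miss <- setdiff(species, names(models_by_species))
  if (length(miss)) stop2("no gene models for species: ", miss[1])
  for (s in species) {
    tx_ids <- models_by_species[[s]]$transcripts$transcript_id
    bad <- setdiff(table[[paste0(s, "_transcript")]], tx_ids)
    if (length(bad)) stop2("unresolvable transcript id: ", bad[1],
                           " (", s, ")")
  }

  audit <- list(); removed <- list()
  note <- function(step, unit, n_in, drop_idx, ids) {
    audit[[length(audit) + 1]] <<- data.frame(
      step = step, unit = unit, n_input = n_in,
      n_removed = length(drop_idx), n_output = n_in - length(drop_idx))
    removed[[step]] <<- ids
  }

  ## 1. low-confidence pairs
  conf_cols <- grep("^conf_", names(table), value = TRUE)
  low <- which(rowSums(table[, conf_cols, drop = FALSE] == 0) > 0)
  note("low_confidence", "rows", nrow(table), low, row_labels(table, low, species))
  if (length(low)) table <- table[-low, , drop = FALSE]

  ## 2. exact duplicates
  dup <- which(duplicated(table))
  note("duplicates", "rows", nrow(table), dup, row_labels(table, dup, species))
  if (length(dup)) table <- table[-dup, , drop = FALSE]

  ## 3. strict 1:1 at transcript level
  offenders <- lapply(stats::setNames(species, species), function(s) character())
  for (s1 in species) for (s2 in setdiff(species, s1)) {
    t1 <- table[[paste0(s1, "_transcript")]]
    t2 <- table[[paste0(s2, "_transcript")]]
    npart <- tapply(t2, t1, function(v) length(unique(v)))
    offenders[[s1]] <- union(offenders[[s1]], names(npart)[npart > 1])
  }
  hit <- rep(FALSE, nrow(table))
  for (s in species)
    hit <- hit | table[[paste0(s, "_transcript")]] %in% offenders[[s]]
  note("non_one_to_one", "rows", nrow(table), which(hit),
       row_labels(table, which(hit), species))
  table <- table[!hit, , drop = FALSE]

  ## 4. collapse to gene tuples with the longest transcript as annotation
  gene_cols <- paste0(species, "_gene")
  tuples <- unique(table[, gene_cols, drop = FALSE])
  rownames(tuples) <- NULL
  ambiguous <- rep(FALSE, nrow(tuples))
  for (s in species)
    ambiguous <- ambiguous | duplicated(tuples[[paste0(s, "_gene")]]) |
      duplicated(tuples[[paste0(s, "_gene")]], fromLast = TRUE)
  note("ambiguous_gene", "tuples", nrow(tuples), which(ambiguous),
       apply(tuples[ambiguous, , drop = FALSE], 1, paste, collapse = "|"))
  tuples <- tuples[!ambiguous, , drop = FALSE]

  for (s in species) {
    mods <- models_by_species[[s]]
    tuples[[paste0(s, "_transcript")]] <-
      vapply(tuples[[paste0(s, "_gene")]], longest_transcript,
             character(1), models = mods)
    gi <- match(tuples[[paste0(s, "_gene")]], mods$genes$gene_id)
    if (anyNA(gi)) stop2("gene absent from models: ",
                         tuples[[paste0(s, "_gene")]][is.na(gi)][1])
    tuples[[paste0(s, "_length")]] <- mods$genes$length_bp[gi]
  }

  ## 5. length filters on whole-gene spans
  len <- as.matrix(tuples[, paste0(species, "_length"), drop = FALSE])
  ratio <- apply(len, 1, max) / apply(len, 1, min)
  short <- apply(len, 1, min) < 1000
  drop5 <- which(ratio > 2 | short)
  note("length_filters", "tuples", nrow(tuples), drop5,
       apply(tuples[drop5, gene_cols, drop = FALSE], 1, paste, collapse = "|"))
  if (length(drop5)) tuples <- tuples[-drop5, , drop = FALSE]

  tuples$tuple_id <- apply(tuples[, gene_cols, drop = FALSE], 1,
                           paste, collapse = "|")
  rownames(tuples) <- NULL
  structure(tuples, class = c("harmonized_universe", "data.frame"),
            species = species, audit = do.call(rbind, audit),
            removed = removed)
}

row_labels <- function(table, idx, species) {
  if (!length(idx)) return(character())
  apply(table[idx, paste0(species, "_transcript"), drop = FALSE], 1,
        paste, collapse = "|")
}

longest_transcript <- function(gene_id, models) {
  tx <- models$transcripts[models$transcripts$gene_id == gene_id, , drop = FALSE]
  if (!nrow(tx)) stop2("gene without transcripts: ", gene_id)
  w <- tx$end - tx$start
  tx$transcript_id[order(-w, tx$transcript_id)][1]
}

#' Re-express a harmonized universe as an ortholog table
#'
#' Useful for idempotence checks and for writing the surviving annotation in
#' the input format.
#'
#' @param universe A `harmonized_universe`.
#' @return An ortholog table with all confidences set to 1.
#' @export
universe_as_table <- function(universe) {
  species <- attr(universe, "species")
  out <- universe[, c(paste0(species, "_gene"), paste0(species, "_transcript"))]
  pairs <- utils::combn(sort(species), 2)
  for (j in seq_len(ncol(pairs)))
    out[[paste0("conf_", pairs[1, j], "_", pairs[2, j])]] <- 1
  out
}

#' Align per-species counts to a harmonized universe
#'
#' Builds one cross-species count matrix with one row per ortholog tuple and
#' the samples of every species as columns.
#'
#' @param counts_by_species Named list of count matrices (names = species).
#' @param universe A `harmonized_universe`.
#' @return Integer matrix (tuples x all samples) with rownames set to the
#'   tuple ids; the universe is attached as `attr(, "universe")`.
#' @export
subset_counts_to_universe <- function(counts_by_species, universe) {
  if (!nrow(universe)) stop2("empty universe")
  species <- attr(universe, "species")
  blocks <- lapply(species, function(s) {
    cm <- counts_by_species[[s]]
    if (is.null(cm)) stop2("no counts for species ", s)
    g <- universe[[paste0(s, "_gene")]]
    miss <- setdiff(g, rownames(cm))
    if (length(miss)) stop2("universe gene absent from ", s, " counts: ",
                            miss[1])
    cm[g, , drop = FALSE]
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- universe$tuple_id
  attr(out, "universe") <- universe
  out
}
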