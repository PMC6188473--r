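# File formats. All interval-like structures use BED-style 0-based half-open
# coordinates, in memory and on disk; this is the single place where the
# convention is enforced.

comment_header <- function(seed = NULL) {
  paste0("# orthocell ", pkg_version_string(),
         if (!is.null(seed)) paste0(" seed=", seed))
}

write_tsv_commented <- function(df, path, seed = NULL, col_names = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment_header(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col_names)
  invisible(path)
}

read_tsv_commented <- function(path, header = TRUE, ...) {
  utils::read.delim(path, header = header, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

## ---- count matrices ---------------------------------------------------------

#' Validate a gene-by-sample count matrix
#'
#' Checks the invariants of the raw count container: unique gene and sample
#' identifiers and non-negative integer entries.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @return The matrix, invisibly, with integer storage.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop2("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("counts must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop2("duplicated gene id: ",
          rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop2("duplicated sample id: ",
          colnames(counts)[duplicated(colnames(counts))][1])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stop2("count entry is not a non-negative integer at gene '",
          rownames(counts)[i[1]], "', sample '", colnames(counts)[i[2]],
          "' (value ", counts[bad[1]], ")")
  }
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read a gene-level count matrix
#'
#' `tsv` expects genes as rows and samples as columns with the gene id in the
#' first column. `mtx` expects a MatrixMarket triplet file with sidecar
#' row/column id files (`<path>.rows`, `<path>.cols`, one id per line);
#' omitted cells are zeros by the sparse convention.
#'
#' @param path Path to the file.
#' @param format One of `"tsv"` or `"mtx"`.
#' @param row_ids,col_ids Optional paths to the id sidecars for `mtx` input.
#' @return An integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        row_ids = paste0(path, ".rows"),
                        col_ids = paste0(path, ".cols")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("no such file: ", path)
  if (format == "tsv") {
    df <- read_tsv_commented(path)
    if (ncol(df) < 2) stop2("counts TSV needs a gene_id column plus samples")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    validate_count_matrix(m)
    storage.mode(m) <- "integer"
    m
  } else {
    sm <- Matrix::readMM(path)
    m <- as.matrix(sm)
    rownames(m) <- readLines(row_ids)
    colnames(m) <- readLines(col_ids)
    validate_count_matrix(m)
    storage.mode(m) <- "integer"
    m
  }
}

#' Write a count matrix
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @param format `"tsv"` (dense) or `"mtx"` (MatrixMarket triplet plus
#'   `.rows`/`.cols` sidecars).
#' @param seed Optional seed recorded in the commented header (tsv only).
#' @return The path, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx"), seed = NULL) {
  format <- match.arg(format)
  validate_count_matrix(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv_commented(df, path, seed = seed)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(counts), paste0(path, ".rows"))
    writeLines(colnames(counts), paste0(path, ".cols"))
  }
  invisible(path)
}

## ---- sample metadata --------------------------------------------------------

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `species`, `cell_type`, `donor_id`, `sex`,
#' `replicate`; optional `age` (years) and `pmd` (post-mortem delay, hours).
#'
#' @param samples data.frame of sample metadata.
#' @return The table, invisibly.
#' @export
validate_sample_table <- function(samples) {
  need <- c("sample_id", "species", "cell_type", "donor_id", "sex", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop2("sample table is missing column(s): ",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop2("duplicated sample_id: ",
          samples$sample_id[duplicated(samples$sample_id)][1])
  key <- interaction(samples$species, samples$cell_type, samples$donor_id,
                     samples$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop2("duplicated (species, cell_type, donor_id, replicate) combination")
  if (!all(samples$species %in% c("mouse", "rat", "human")))
    stop2("species must be one of mouse, rat, human")
  if (!all(samples$sex %in% c("M", "F"))) stop2("sex must be M or F")
  for (col in c("age", "pmd")) {
    if (col %in% names(samples)) {
      v <- samples[[col]]
      if (any(!is.na(v) & v < 0)) stop2(col, " must be non-negative")
    }
  }
  if (any(samples$replicate < 1 | samples$replicate != round(samples$replicate)))
    stop2("replicate must be a positive integer")
  invisible(samples)
}

#' @rdname validate_sample_table
#' @param path Path to a sample metadata TSV.
#' @export
read_sample_table <- function(path) {
  df <- read_tsv_commented(path)
  validate_sample_table(df)
  df
}

#' @rdname validate_sample_table
#' @param samples Sample table to write.
#' @param seed Optional seed recorded in the header.
#' @export
write_sample_table <- function(samples, path, seed = NULL) {
  validate_sample_table(samples)
  write_tsv_commented(samples, path, seed = seed)
}

## ---- gene models ------------------------------------------------------------

#' Construct a gene-model set
#'
#' A gene model is the whole-gene genomic span (UTRs included) plus its
#' transcript spans. The TSS is the 5' end of the span: position `start` on
#' the plus strand and `end - 1` on the minus strand (0-based half-open).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`.
#' @param transcripts data.frame with columns `gene_id`, `transcript_id`,
#'   `start`, `end`; every transcript span must be nested in its gene span.
#' @return An object of class `gene_models`: a list with elements `genes`
#'   (with derived `tss` and `length_bp`) and `transcripts`.
#' @export
gene_models <- function(genes, transcripts) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop2("gene table missing column(s): ",
                          paste(miss, collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop2("strand must be '+' or '-' (gene ",
          genes$gene_id[!genes$strand %in% c("+", "-")][1], ")")
  bad <- genes$start >= genes$end
  if (any(bad)) stop2("gene span must satisfy start < end (gene ",
                      genes$gene_id[bad][1], ")")
  if (anyDuplicated(genes$gene_id))
    stop2("duplicated gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$length_bp <- genes$end - genes$start
  if (!missing(transcripts) && !is.null(transcripts) && nrow(transcripts)) {
    i <- match(transcripts$gene_id, genes$gene_id)
    if (anyNA(i)) stop2("transcript refers to unknown gene: ",
                        transcripts$gene_id[is.na(i)][1])
    nest <- transcripts$start >= genes$start[i] &
      transcripts$end <= genes$end[i] & transcripts$start < transcripts$end
    if (!all(nest)) stop2("transcript span not nested in gene span: ",
                          transcripts$transcript_id[!nest][1])
  } else {
    transcripts <- data.frame(gene_id = character(), transcript_id = character(),
                              start = integer(), end = integer())
  }
  structure(list(genes = genes, transcripts = transcripts),
            class = "gene_models")
}

#' Read gene models from a flat TSV
#'
#' One row per transcript with columns `gene_id`, `chrom`, `strand`,
#' `gene_start`, `gene_end`, `transcript_id`, `tx_start`, `tx_end`.
#'
#' @param path Path to the TSV.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("gene_id", "chrom", "strand", "gene_start", "gene_end",
            "transcript_id", "tx_start", "tx_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("gene model TSV missing column(s): ",
                          paste(miss, collapse = ", "))
  genes <- unique(df[, c("gene_id", "chrom", "strand", "gene_start", "gene_end")])
  names(genes) <- c("gene_id", "chrom", "strand", "start", "end")
  rownames(genes) <- NULL
  tx <- df[, c("gene_id", "transcript_id", "tx_start", "tx_end")]
  names(tx) <- c("gene_id", "transcript_id", "start", "end")
  rownames(tx) <- NULL
  gene_models(genes, tx)
}

#' Write gene models to the flat TSV layout read by [read_gene_models()]
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @export
write_gene_models <- function(models, path, seed = NULL) {
  g <- models$genes
  tx <- models$transcripts
  i <- match(tx$gene_id, g$gene_id)
  df <- data.frame(gene_id = tx$gene_id, chrom = g$chrom[i],
                   strand = g$strand[i], gene_start = g$start[i],
                   gene_end = g$end[i], transcript_id = tx$transcript_id,
                   tx_start = tx$start, tx_end = tx$end)
  write_tsv_commented(df, path, seed = seed)
  invisible(path)
}

## ---- peaks and tracks -------------------------------------------------------

#' Construct a peak set
#'
#' @param chrom,start,end Peak intervals (0-based half-open).
#' @param peak_id Peak identifiers (generated when missing).
#' @param score Optional numeric score.
#' @return data.frame of class `peak_set` with `category = "unassigned"` until
#'   [assign_peaks()] runs.
#' @export
peak_set <- function(chrom, start, end, peak_id = NULL, score = NA_real_) {
  if (any(start >= end)) stop2("peak intervals must satisfy start < end")
  if (is.null(peak_id)) peak_id <- sprintf("peak_%d", seq_along(chrom))
  structure(data.frame(chrom = as.character(chrom), start = as.integer(start),
                       end = as.integer(end), peak_id = as.character(peak_id),
                       score = as.numeric(score),
                       category = "unassigned", gene_id = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("peak_set", "data.frame"))
}

#' Construct a conservation track
#'
#' Run-length encoded per-base scores in `[0, 1]`; runs must be sorted and
#' non-overlapping within each chromosome.
#'
#' @param chrom,start,end Run intervals (0-based half-open).
#' @param score Per-base score of each run, in `[0, 1]`.
#' @return data.frame of class `conservation_track`.
#' @export
conservation_track <- function(chrom, start, end, score) {
  if (any(start >= end)) stop2("track runs must satisfy start < end")
  if (any(score < 0 | score > 1))
    stop2("conservation score outside [0,1]: ", score[score < 0 | score > 1][1])
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  sp <- split(df, df$chrom)
  for (runs in sp) {
    if (nrow(runs) > 1 && any(runs$start[-1] < runs$end[-nrow(runs)]))
      stop2("overlapping track runs on ", runs$chrom[1])
  }
  structure(df, class = c("conservation_track", "data.frame"))
}

#' Read interval files
#'
#' Supports BED4+ (`bed`), ENCODE narrowPeak (`narrowPeak`) and bedGraph
#' (`bedgraph`). BED dialect throughout: tab-separated, 0-based half-open.
#' bedGraph input is validated as a conservation track (scores in `[0, 1]`,
#' non-overlapping runs) unless `conservation = FALSE`, in which case it is
#' returned as a plain coverage data.frame.
#'
#' @param path Path to the file.
#' @param kind One of `"bed"`, `"narrowPeak"`, `"bedgraph"`.
#' @param conservation For `bedgraph`: validate as conservation scores.
#' @return A `peak_set`, a `conservation_track`, or a coverage data.frame.
#' @export
read_intervals <- function(path, kind = c("bed", "narrowPeak", "bedgraph"),
                           conservation = TRUE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop2("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (kind == "bed") {
    ps <- peak_set(df[[1]], df[[2]], df[[3]],
                   peak_id = if (ncol(df) >= 4) df[[4]] else NULL,
                   score = if (ncol(df) >= 5) df[[5]] else NA_real_)
    ps
  } else if (kind == "narrowPeak") {
    if (ncol(df) < 10) stop2("narrowPeak requires 10 columns")
    peak_set(df[[1]], df[[2]], df[[3]], peak_id = df[[4]], score = df[[7]])
  } else {
    if (ncol(df) < 4) stop2("bedGraph requires 4 columns")
    if (conservation) {
      conservation_track(df[[1]], df[[2]], df[[3]], df[[4]])
    } else {
      data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                 end = as.integer(df[[3]]), score = as.numeric(df[[4]]),
                 stringsAsFactors = FALSE)
    }
  }
}

#' Write interval objects
#'
#' Peak sets are written as BED4 (plus a score column when present); tracks
#' and coverage as bedGraph. No comment header: these files follow the plain
#' BED dialect.
#'
#' @param x A `peak_set`, `conservation_track`, or coverage data.frame.
#' @param path Output path.
#' @export
write_intervals <- function(x, path) {
  if (inherits(x, "peak_set")) {
    df <- x[, c("chrom", "start", "end", "peak_id")]
    if (!all(is.na(x$score))) df$score <- x$score
  } else {
    df <- x[, c("chrom", "start", "end", "score")]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- ortholog tables --------------------------------------------------------

#' Validate an ortholog table
#'
#' The table has one row per cross-species transcript pairing, with per-species
#' columns `<species>_gene` and `<species>_transcript` and a 0/1 confidence
#' column `conf_<sp1>_<sp2>` for every species pair.
#'
#' @param table data.frame as described.
#' @return Character vector of species names, invisibly.
#' @export
validate_ortholog_table <- function(table) {
  sp <- sub("_gene$", "", grep("_gene$", names(table), value = TRUE))
  if (length(sp) < 2) stop2("ortholog table needs >= 2 species (*_gene columns)")
  for (s in sp) {
    if (!paste0(s, "_transcript") %in% names(table))
      stop2("missing column ", s, "_transcript")
  }
  pairs <- utils::combn(sort(sp), 2)
  for (j in seq_len(ncol(pairs))) {
    cn <- paste0("conf_", pairs[1, j], "_", pairs[2, j])
    if (!cn %in% names(table)) stop2("missing confidence column ", cn)
    if (!all(table[[cn]] %in% c(0, 1)))
      stop2("confidence values must be 0 or 1 in ", cn)
  }
  invisible(sort(sp))
}

#' @rdname validate_ortholog_table
#' @param path Path to an ortholog TSV.
#' @export
read_ortholog_table <- function(path) {
  df <- read_tsv_commented(path)
  validate_ortholog_table(df)
  df
}

#' @rdname validate_ortholog_table
#' @param seed Optional seed recorded in the header.
#' @export
write_ortholog_table <- function(table, path, seed = NULL) {
  validate_ortholog_table(table)
  write_tsv_commented(table, path, seed = seed)
}
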