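#' Read a 10x-style sparse count matrix
#'
#' Reads a Matrix-Market coordinate file of raw gene-by-cell counts together
#' with its features and barcodes sidecar files. Duplicate coordinate entries
#' are summed, following the Matrix-Market convention. Sidecars carry one
#' identifier per line; tab-delimited sidecars (for example 10x
#' `features.tsv` with id/name/type columns) contribute their first column.
#'
#' @param matrix_path Path to the `.mtx` file (plain or gzipped).
#' @param features_path Path to the gene-identifier sidecar (matrix rows).
#' @param barcodes_path Path to the cell-barcode sidecar (matrix columns).
#'
#' @return A [`Matrix::dgCMatrix-class`] of non-negative integer counts with
#'   genes as rownames and barcodes as colnames.
#' @export
#' @examples
#' dir <- tempfile()
#' sim <- simulate_parabiosis(sim_config(n_genes = 50, cell_types = c(Hep = 10)))
#' write_bundle(sim, dir)
#' counts <- read_counts(
#'   file.path(dir, "matrix.mtx"),
#'   file.path(dir, "features.tsv"),
#'   file.path(dir, "barcodes.tsv")
#' )
#' dim(counts)
read_counts <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  if (methods::is(m, "nsparseMatrix")) {
    stop("matrix file is a pattern Matrix-Market file; integer counts are required",
         call. = FALSE)
  }
  if (length(m@x) && any(m@x < 0)) {
    stop("count matrix contains negative values", call. = FALSE)
  }
  if (length(m@x) && any(m@x != round(m@x))) {
    stop("count matrix contains non-integer values", call. = FALSE)
  }
  genes <- read_id_column(features_path)
  barcodes <- read_id_column(barcodes_path)
  if (length(genes) != nrow(m)) {
    stop(sprintf(
      "features file lists %d identifiers but the matrix header declares %d rows",
      length(genes), nrow(m)
    ), call. = FALSE)
  }
  if (length(barcodes) != ncol(m)) {
    stop(sprintf(
      "barcodes file lists %d identifiers but the matrix header declares %d columns",
      length(barcodes), ncol(m)
    ), call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers in features file", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("duplicate cell barcodes in barcodes file", call. = FALSE)
  }
  # Tsparse -> Csparse conversion sums duplicated (i, j) triplets
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, barcodes)
  m
}

read_id_column <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(character(0))
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a count matrix as Matrix-Market triplets with sidecars
#'
#' Inverse of [read_counts()]: writes `matrix.mtx` (coordinate integer
#' format, column-major entry order), `features.tsv` and `barcodes.tsv`
#' into `dir`.
#'
#' @param counts Gene-by-cell count matrix with dimnames.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the three file paths.
#' @export
write_counts <- function(counts, dir) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(as_sparse(counts), "TsparseMatrix")
  ord <- order(m@j, m@i)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  writeLines(
    c(
      "%%MatrixMarket matrix coordinate integer general",
      sprintf("%d %d %d", nrow(m), ncol(m), length(m@x)),
      sprintf("%d %d %d", m@i[ord] + 1L, m@j[ord] + 1L, as.integer(m@x[ord]))
    ),
    paths[[1]]
  )
  writeLines(rownames(m), paths[[2]])
  writeLines(colnames(m), paths[[3]])
  invisible(paths)
}

#' Read and validate a cell annotation table
#'
#' The annotation assigns each barcode a sample, an experimental group, an
#' organ and a cell type. Group labels must come from
#' [parabiosis_groups()] and organs from [parabiosis_organs()]; barcodes
#' must be unique.
#'
#' @param path Tab-separated file with header columns `barcode`,
#'   `sample_id`, `group`, `organ`, `cell_type`.
#' @return A validated tibble with those five character columns.
#' @export
read_cell_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_annotation(ann)
}

#' Validate an in-memory cell annotation
#'
#' @param annotation Data frame with columns `barcode`, `sample_id`,
#'   `group`, `organ`, `cell_type`.
#' @return The annotation as a tibble, unchanged, if valid.
#' @export
validate_annotation <- function(annotation) {
  required <- c("barcode", "sample_id", "group", "organ", "cell_type")
  missing <- setdiff(required, names(annotation))
  if (length(missing)) {
    stop("annotation is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- unique(annotation$barcode[duplicated(annotation$barcode)])
  if (length(dup)) {
    stop("duplicate barcode(s) in annotation: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  bad_group <- setdiff(unique(annotation$group), parabiosis_groups())
  if (length(bad_group)) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         "; expected one of ", paste(parabiosis_groups(), collapse = ", "),
         call. = FALSE)
  }
  bad_organ <- setdiff(unique(annotation$organ), parabiosis_organs())
  if (length(bad_organ)) {
    stop("unknown organ label(s): ", paste(bad_organ, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(annotation)
}

#' Quality-control thresholds
#'
#' Cells are kept when their detected-feature count and total count both lie
#' strictly inside the stated bounds ("fewer than"/"more than" are read as
#' strict, so a cell at exactly `min_features` is retained). Genes whose
#' identifier starts with `mito_prefix` (case-insensitive; `"mt-"` is the
#' mouse convention) are removed after cell filtering.
#'
#' @param min_features,max_features Detected-feature bounds (defaults 500 and
#'   8000).
#' @param min_counts,max_counts Total-count bounds (defaults 500 and 20000).
#' @param mito_prefix Identifier prefix marking mitochondrial genes.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 500, max_features = 8000,
                          min_counts = 500, max_counts = 20000,
                          mito_prefix = "mt-") {
  stopifnot(min_features <= max_features, min_counts <= max_counts)
  structure(
    list(
      min_features = min_features, max_features = max_features,
      min_counts = min_counts, max_counts = max_counts,
      mito_prefix = mito_prefix
    ),
    class = "qc_thresholds"
  )
}

#' Filter cells and mitochondrial genes
#'
#' Removes cells whose detected-feature or total-count values fall outside
#' the (strict) thresholds, optionally removes an explicit barcode exclusion
#' list, then removes mitochondrial genes. Gene and cell order is preserved.
#'
#' @param counts Gene-by-cell count matrix with dimnames.
#' @param thresholds A [qc_thresholds()] object.
#' @param exclude_barcodes Optional character vector (or path to a
#'   one-barcode-per-line file) of cells to drop regardless of metrics,
#'   standing in for manual low-quality-cell curation.
#' @return A list of class `qc_result` with elements `counts` (the filtered
#'   matrix) and `report`, a tibble with columns `rule` and `n_removed`.
#'   Removing every cell raises a warning, not an error.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(),
                      exclude_barcodes = NULL) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  counts <- as_sparse(counts)
  if (is.character(exclude_barcodes) && length(exclude_barcodes) == 1 &&
      file.exists(exclude_barcodes)) {
    exclude_barcodes <- readLines(exclude_barcodes)
  }
  n_feat <- Matrix::colSums(counts > 0)
  n_count <- Matrix::colSums(counts)
  low_f <- n_feat < thresholds$min_features
  high_f <- n_feat > thresholds$max_features
  low_c <- n_count < thresholds$min_counts
  high_c <- n_count > thresholds$max_counts
  excluded <- colnames(counts) %in% (exclude_barcodes %||% character(0))
  drop_cell <- low_f | high_f | low_c | high_c | excluded
  mito <- startsWith(tolower(rownames(counts)), tolower(thresholds$mito_prefix))
  report <- tibble::tibble(
    rule = c("low_features", "high_features", "low_counts", "high_counts",
             "excluded_barcode", "cells_removed", "mito_genes"),
    n_removed = c(sum(low_f), sum(high_f), sum(low_c), sum(high_c),
                  sum(excluded), sum(drop_cell), sum(mito))
  )
  if (all(drop_cell)) {
    warning("QC filtering removed every cell", call. = FALSE)
  }
  structure(
    list(counts = counts[!mito, !drop_cell, drop = FALSE], report = report),
    class = "qc_result"
  )
}

#' Log-normalize a count matrix
#'
#' Each cell's counts are divided by the cell total, multiplied by
#' `scale_factor`, and `log1p`-transformed — the standard global-scaling
#' log-normalization for droplet data. A cell with zero total counts maps to
#' an all-zero column.
#'
#' @param counts Gene-by-cell count matrix.
#' @param scale_factor Per-cell total after scaling (default 10000).
#' @return A [`Matrix::dgCMatrix-class`] of log-normalized expression, same
#'   dimnames as the input.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  stopifnot(scale_factor > 0)
  m <- as_sparse(counts)
  tot <- Matrix::colSums(m)
  sf <- ifelse(tot > 0, scale_factor / tot, 0)
  m@x <- log1p(m@x * rep.int(sf, diff(m@p)))
  m
}
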