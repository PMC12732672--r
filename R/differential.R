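#' Define a two-group contrast
#'
#' A contrast names the two experimental groups being compared (positive
#' log2 fold changes mean higher expression in `group_a`) within an optional
#' (organ, cell type) scope. The two named study contrasts are provided by
#' [sea_contrast()] (Iso-P8 vs Iso-R1, senescence acceleration) and
#' [rej_contrast()] (Het-P8 vs Iso-P8, rejuvenation).
#'
#' @param group_a,group_b Distinct group labels from [parabiosis_groups()];
#'   `group_a` is the direction reference.
#' @param name Contrast name (e.g. `"SEA"`, `"REJ"`).
#' @param cell_type,organ Optional scope restriction; `NULL` pools all cells.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(group_a, group_b, name = NULL,
                          cell_type = NULL, organ = NULL) {
  stopifnot(length(group_a) == 1, length(group_b) == 1)
  if (identical(group_a, group_b)) {
    stop("contrast groups must differ", call. = FALSE)
  }
  bad <- setdiff(c(group_a, group_b), parabiosis_groups())
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      name = name %||% paste0(group_a, "_vs_", group_b),
      group_a = group_a, group_b = group_b,
      cell_type = cell_type, organ = organ
    ),
    class = "contrast_spec"
  )
}

#' @rdname contrast_spec
#' @export
sea_contrast <- function(cell_type = NULL, organ = NULL) {
  contrast_spec("Iso-P8", "Iso-R1", name = "SEA",
                cell_type = cell_type, organ = organ)
}

#' @rdname contrast_spec
#' @export
rej_contrast <- function(cell_type = NULL, organ = NULL) {
  contrast_spec("Het-P8", "Iso-P8", name = "REJ",
                cell_type = cell_type, organ = organ)
}

#' Detection gate for differential testing
#'
#' A gene is tested when it is detected (value > 0) in at least `min_pct` of
#' the cells of at least one group, and in at least `min_cells_feature`
#' cells across the two groups combined (the combined-detection reading of
#' the marker-test gate).
#'
#' @param norm Log-normalized gene-by-cell matrix.
#' @param cells_a,cells_b Barcodes of the two groups (non-empty, present in
#'   `norm`).
#' @param min_pct Minimum detection fraction in at least one group.
#' @param min_cells_feature Minimum detecting cells across both groups.
#' @return Character vector of gene identifiers passing the gate, in matrix
#'   row order.
#' @export
test_gate <- function(norm, cells_a, cells_b, min_pct = 0.1,
                      min_cells_feature = 5) {
  check_group_cells(norm, cells_a, "group_a")
  check_group_cells(norm, cells_b, "group_b")
  det_a <- Matrix::rowSums(norm[, cells_a, drop = FALSE] > 0)
  det_b <- Matrix::rowSums(norm[, cells_b, drop = FALSE] > 0)
  keep <- (det_a / length(cells_a) >= min_pct |
             det_b / length(cells_b) >= min_pct) &
    (det_a + det_b) >= min_cells_feature
  rownames(norm)[keep]
}

check_group_cells <- function(norm, cells, label) {
  if (!length(cells)) {
    stop(sprintf("contrast group '%s' contains no cells", label), call. = FALSE)
  }
  missing <- setdiff(cells, colnames(norm))
  if (length(missing)) {
    stop(sprintf("%d barcode(s) of '%s' absent from the matrix", length(missing),
                 label), call. = FALSE)
  }
  invisible(TRUE)
}

# avg_log2FC over rows of two dense group slices.
# "expm1": log2(mean(expm1(x_a)) + 1) - log2(mean(expm1(x_b)) + 1), the
# pseudocount-1 ratio-of-mean-unlogged-expression dialect reported by the
# standard marker test. "meanlog": difference of mean log-normalized values
# rescaled to log2.
fold_change_rows <- function(dense_a, dense_b, method = c("expm1", "meanlog")) {
  method <- match.arg(method)
  if (method == "expm1") {
    log2(rowMeans(expm1(dense_a)) + 1) - log2(rowMeans(expm1(dense_b)) + 1)
  } else {
    (rowMeans(dense_a) - rowMeans(dense_b)) / log(2)
  }
}

#' Average log2 fold change between two groups
#'
#' Computes the marker-test `avg_log2FC` dialect: the log2 ratio of the
#' per-group means of un-logged (expm1) normalized expression, each with a
#' pseudocount of 1. A `"meanlog"` alternative (difference of mean
#' log-normalized values, rescaled to log2) is available.
#'
#' @inheritParams test_gate
#' @param genes Genes to compute; default all rows.
#' @param method Fold-change dialect.
#' @return Named numeric vector of log2 fold changes (`group_a` over
#'   `group_b`).
#' @export
fold_change <- function(norm, cells_a, cells_b, genes = NULL,
                        method = c("expm1", "meanlog")) {
  method <- match.arg(method)
  check_group_cells(norm, cells_a, "group_a")
  check_group_cells(norm, cells_b, "group_b")
  genes <- genes %||% rownames(norm)
  da <- as.matrix(norm[genes, cells_a, drop = FALSE])
  db <- as.matrix(norm[genes, cells_b, drop = FALSE])
  setNames(fold_change_rows(da, db, method), genes)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both groups have at most `exact_limit`
#' observations and the pooled values are tie-free; otherwise the
#' tie-corrected normal approximation with continuity correction. Fully
#' degenerate input (every value identical) returns p = 1.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_limit Largest group size for the exact null distribution.
#' @return A two-sided p-value in (0, 1].
#' @export
wilcoxon_test <- function(a, b, exact_limit = 25) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  pooled <- c(a, b)
  if (max(pooled) == min(pooled)) return(1)
  exact <- !anyDuplicated(pooled) &&
    length(a) <= exact_limit && length(b) <= exact_limit
  p <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
  if (!is.finite(p)) p <- 1
  min(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over exactly the supplied
#' p-values (the tested gene set), order-preserving with the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Per-cell-type differential expression between two groups
#'
#' Runs the full marker-style test for one contrast: detection gating
#' ([test_gate()]), per-gene [fold_change()] and [wilcoxon_test()],
#' [bh_adjust()] over the tested genes, and DEG flagging at
#' `|avg_log2FC| > lfc_threshold` with `p_adj < alpha`.
#'
#' @param norm Log-normalized gene-by-cell matrix.
#' @param annotation Cell annotation tibble (see [validate_annotation()]).
#' @param contrast A [contrast_spec()]; its `cell_type`/`organ` scope the
#'   cells used.
#' @param min_pct,min_cells_feature Detection gate (defaults 0.1 and 5).
#' @param lfc_threshold Absolute log2 fold-change gate for DEG calls
#'   (default 0.25).
#' @param alpha Adjusted-significance gate (default 0.05).
#' @param fc_method Fold-change dialect, see [fold_change()].
#' @param exact_limit Passed to [wilcoxon_test()].
#' @return A `deg_table`: a tibble with one row per tested gene and columns
#'   `gene`, `avg_log2FC`, `pct_a`, `pct_b`, `p_value`, `p_adj`, `is_deg`,
#'   `direction` (`up`/`down`/`none`), ordered by `p_adj` then gene. The
#'   contrast and parameters are attached as attributes.
#' @export
#' @examples
#' sim <- simulate_parabiosis(sim_config(
#'   n_genes = 200, cell_types = c(Hep = 60),
#'   n_planted_up = 20, n_planted_down = 20, seed = 1
#' ))
#' norm <- normalize_counts(sim$counts)
#' degs <- find_degs(norm, sim$annotation, sea_contrast(cell_type = "Hep"))
#' head(degs)
find_degs <- function(norm, annotation, contrast,
                      min_pct = 0.1, min_cells_feature = 5,
                      lfc_threshold = 0.25, alpha = 0.05,
                      fc_method = c("expm1", "meanlog"), exact_limit = 25) {
  stopifnot(inherits(contrast, "contrast_spec"))
  fc_method <- match.arg(fc_method)
  cells_a <- intersect(
    scope_cells(annotation, contrast$group_a, contrast$cell_type, contrast$organ),
    colnames(norm)
  )
  cells_b <- intersect(
    scope_cells(annotation, contrast$group_b, contrast$cell_type, contrast$organ),
    colnames(norm)
  )
  if (!length(cells_a)) {
    stop(sprintf("contrast %s: group '%s' has no cells in scope",
                 contrast$name, contrast$group_a), call. = FALSE)
  }
  if (!length(cells_b)) {
    stop(sprintf("contrast %s: group '%s' has no cells in scope",
                 contrast$name, contrast$group_b), call. = FALSE)
  }
  genes <- test_gate(norm, cells_a, cells_b, min_pct, min_cells_feature)
  da <- as.matrix(norm[genes, cells_a, drop = FALSE])
  db <- as.matrix(norm[genes, cells_b, drop = FALSE])
  lfc <- fold_change_rows(da, db, fc_method)
  p <- vapply(seq_along(genes), function(i) {
    wilcoxon_test(da[i, ], db[i, ], exact_limit = exact_limit)
  }, numeric(1))
  p_adj <- bh_adjust(p)
  is_deg <- abs(lfc) > lfc_threshold & p_adj < alpha
  tbl <- tibble::tibble(
    gene = genes,
    avg_log2FC = unname(lfc),
    pct_a = unname(rowSums(da > 0) / ncol(da)),
    pct_b = unname(rowSums(db > 0) / ncol(db)),
    p_value = p,
    p_adj = p_adj,
    is_deg = is_deg,
    direction = dplyr::case_when(
      is_deg & lfc > 0 ~ "up",
      is_deg & lfc < 0 ~ "down",
      .default = "none"
    )
  )
  tbl <- dplyr::arrange(tbl, .data$p_adj, .data$gene)
  new_deg_table(
    tbl, contrast,
    params = list(min_pct = min_pct, min_cells_feature = min_cells_feature,
                  lfc_threshold = lfc_threshold, alpha = alpha,
                  fc_method = fc_method)
  )
}

new_deg_table <- function(tbl, contrast, params) {
  structure(tbl, class = c("deg_table", class(tbl)),
            contrast = contrast, params = params)
}

#' Write a DEG table as TSV
#'
#' @param degs A `deg_table` from [find_degs()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(degs, path) {
  readr::write_tsv(tibble::as_tibble(degs), path, progress = FALSE)
  invisible(path)
}
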