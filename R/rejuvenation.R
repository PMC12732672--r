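#' Classify aging DEGs as reversed or rescued by the intervention
#'
#' Every SEA DEG (a gene altered by accelerated aging) is checked against
#' the REJ contrast. A gene is *reversed* when its REJ estimate has the
#' opposite sign with `|avg_log2FC| > reverse_lfc` (and, by default, REJ
#' adjusted significance); it is *rescued* when the opposite-sign REJ
#' estimate exceeds `rescue_lfc` with adjusted significance — i.e. it is an
#' opposite-direction REJ DEG. Rescued genes are always a subset of
#' reversed genes. SEA DEGs absent from the REJ tested set are
#' `not_reversed`.
#'
#' @param sea,rej `deg_table`s from [find_degs()] for the SEA and REJ
#'   contrasts of the same (organ, cell type) scope.
#' @param reverse_lfc Effect-size gate for "reversed" (default 0.1).
#' @param rescue_lfc Effect-size gate for "rescued" (default 0.25); must be
#'   at least `reverse_lfc`.
#' @param alpha REJ adjusted-significance gate (default 0.05).
#' @param require_rej_significance When `TRUE` (default) "reversed" also
#'   requires `rej_p_adj < alpha`; set `FALSE` to use the effect-size gate
#'   alone (sensitivity analysis).
#' @return A `reversal_status` tibble with columns `gene`, `sea_direction`,
#'   `sea_lfc`, `rej_lfc`, `rej_p_adj`, `status`
#'   (`not_reversed`/`reversed`/`rescued`).
#' @export
classify_reversal <- function(sea, rej, reverse_lfc = 0.1, rescue_lfc = 0.25,
                              alpha = 0.05, require_rej_significance = TRUE) {
  stopifnot(reverse_lfc > 0, reverse_lfc <= rescue_lfc)
  check_matching_scope(sea, rej)
  sea_degs <- dplyr::filter(tibble::as_tibble(sea), .data$is_deg)
  rej_tbl <- dplyr::select(tibble::as_tibble(rej), "gene",
                           rej_lfc = "avg_log2FC", rej_p_adj = "p_adj")
  out <- dplyr::left_join(
    dplyr::select(sea_degs, "gene", sea_direction = "direction",
                  sea_lfc = "avg_log2FC"),
    rej_tbl,
    by = "gene"
  )
  opposite <- !is.na(out$rej_lfc) & sign(out$rej_lfc) == -sign(out$sea_lfc) &
    out$rej_lfc != 0
  sig <- !is.na(out$rej_p_adj) & out$rej_p_adj < alpha
  reversed <- opposite & abs(out$rej_lfc) > reverse_lfc &
    (sig | !require_rej_significance)
  rescued <- opposite & abs(out$rej_lfc) > rescue_lfc & sig
  out$status <- factor(
    dplyr::case_when(rescued ~ "rescued", reversed ~ "reversed",
                     .default = "not_reversed"),
    levels = c("not_reversed", "reversed", "rescued")
  )
  structure(out, class = c("reversal_status", class(out)))
}

check_matching_scope <- function(sea, rej) {
  ca <- attr(sea, "contrast")
  cb <- attr(rej, "contrast")
  if (is.null(ca) || is.null(cb)) return(invisible(TRUE))
  if (!identical(ca$cell_type, cb$cell_type) || !identical(ca$organ, cb$organ)) {
    stop("SEA and REJ tables come from different (organ, cell type) scopes",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Display rounding for reversal percentages
#'
#' Converts a count pair to an integer percentage using round-half-up,
#' the convention of the published reversal ratios (e.g. 203 of 424 is
#' 47.88, displayed as 48). A zero denominator yields `NA`.
#'
#' @param k Numerator count(s).
#' @param n Denominator count(s).
#' @return Integer-valued percentage(s), `NA` where `n` is 0.
#' @export
pct_display <- function(k, n) {
  ifelse(n > 0, floor(100 * k / n + 0.5), NA_real_)
}

#' Reversal-ratio summary
#'
#' Counts, per direction, the SEA DEGs classified reversed and rescued,
#' with exact and display (round-half-up integer) percentages. A direction
#' with no SEA DEGs reports `NA` percentages.
#'
#' @param statuses A `reversal_status` tibble from [classify_reversal()].
#' @param scope Label for the summarized scope (e.g. `"liver"` or
#'   `"liver/Hep"`).
#' @return A one-row `reversal_report` tibble with columns `scope`, `n_up`,
#'   `n_up_reversed`, `n_up_rescued`, `pct_up_reversed_exact`,
#'   `pct_up_reversed`, `pct_up_rescued`, and the `down` analogues.
#' @export
reversal_ratio <- function(statuses, scope = NA_character_) {
  if (!nrow(statuses)) {
    stop("no SEA DEGs to summarize for this scope", call. = FALSE)
  }
  dir_counts <- function(d) {
    s <- statuses[statuses$sea_direction == d, , drop = FALSE]
    list(
      n = nrow(s),
      rev = sum(s$status %in% c("reversed", "rescued")),
      res = sum(s$status == "rescued")
    )
  }
  up <- dir_counts("up")
  down <- dir_counts("down")
  pct_exact <- function(k, n) ifelse(n > 0, 100 * k / n, NA_real_)
  out <- tibble::tibble(
    scope = scope,
    n_up = up$n, n_up_reversed = up$rev, n_up_rescued = up$res,
    pct_up_reversed_exact = pct_exact(up$rev, up$n),
    pct_up_reversed = pct_display(up$rev, up$n),
    pct_up_rescued = pct_display(up$res, up$n),
    n_down = down$n, n_down_reversed = down$rev, n_down_rescued = down$res,
    pct_down_reversed_exact = pct_exact(down$rev, down$n),
    pct_down_reversed = pct_display(down$rev, down$n),
    pct_down_rescued = pct_display(down$res, down$n)
  )
  structure(out, class = c("reversal_report", class(out)))
}

#' Select highly variable genes
#'
#' Variance-stabilizing ranking: a trend of log10 variance against log10
#' mean is fitted across expressed genes (loess; a quadratic fit when fewer
#' than 32 genes have positive variance), each gene's values are
#' standardized by its trend-expected standard deviation with clipping at
#' `sqrt(n_cells)`, and genes are ranked by the variance of the
#' standardized values. Ties break by gene identifier; constant genes are
#' never selected.
#'
#' @param norm Log-normalized gene-by-cell matrix.
#' @param cells Optional barcodes restricting the computation.
#' @param n Number of genes to return (default 1500). When fewer genes have
#'   positive variance, all of them are returned with a warning.
#' @param span Loess span for the mean-variance trend (default 0.3).
#' @return Character vector of gene identifiers, highest standardized
#'   variance first.
#' @export
select_hvg <- function(norm, cells = NULL, n = 1500, span = 0.3) {
  if (!is.null(cells)) norm <- norm[, cells, drop = FALSE]
  if (ncol(norm) < 2) {
    stop("highly variable gene selection needs at least 2 cells", call. = FALSE)
  }
  x <- as.matrix(norm)
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  pos <- v > 0
  if (!any(pos)) stop("no gene has positive variance", call. = FALSE)
  lm_mu <- log10(mu[pos])
  lm_v <- log10(v[pos])
  fitted_v <- if (sum(pos) < 32) {
    predict(lm(lm_v ~ stats::poly(lm_mu, degree = min(2, sum(pos) - 1))))
  } else {
    predict(loess(lm_v ~ lm_mu, span = span, degree = 2))
  }
  exp_sd <- sqrt(10^fitted_v)
  clip <- sqrt(ncol(x))
  z <- sweep(sweep(x[pos, , drop = FALSE], 1, mu[pos]), 1, exp_sd, "/")
  z <- pmin(pmax(z, -clip), clip)
  std_var <- apply(z, 1, var)
  ord <- order(-std_var, rownames(x)[pos])
  ranked <- rownames(x)[pos][ord]
  if (length(ranked) < n) {
    warning(sprintf("only %d genes have positive variance; returning all",
                    length(ranked)), call. = FALSE)
    return(ranked)
  }
  ranked[seq_len(n)]
}

#' Coefficient of variation of between-group expression differences
#'
#' For each highly variable gene the absolute difference of the two group
#' means of log-normalized expression is taken; the CV is the sample
#' standard deviation of these differences times the reciprocal of their
#' mean. Used as a transcriptional change/noise measure: a zero mean
#' difference vector yields `NA` (undefined).
#'
#' @param norm Log-normalized gene-by-cell matrix.
#' @param annotation Cell annotation tibble.
#' @param group_a,group_b Group labels to compare.
#' @param hvgs Character vector of highly variable genes to use.
#' @param cell_type,organ Optional scope restriction.
#' @return A single CV value (or `NA` when undefined).
#' @export
cv_statistic <- function(norm, annotation, group_a, group_b, hvgs,
                         cell_type = NULL, organ = NULL) {
  if (!length(hvgs)) stop("empty highly-variable gene set", call. = FALSE)
  cells_a <- intersect(scope_cells(annotation, group_a, cell_type, organ),
                       colnames(norm))
  cells_b <- intersect(scope_cells(annotation, group_b, cell_type, organ),
                       colnames(norm))
  if (length(cells_a) < 2 || length(cells_b) < 2) {
    stop("both groups need at least 2 cells for the CV statistic",
         call. = FALSE)
  }
  d <- abs(Matrix::rowMeans(norm[hvgs, cells_a, drop = FALSE]) -
             Matrix::rowMeans(norm[hvgs, cells_b, drop = FALSE]))
  m <- mean(d)
  if (m == 0) return(NA_real_)
  sd(d) / m
}

#' Transcriptional-noise CV delta for one cell type
#'
#' Computes `cv(Iso-R1 vs Iso-P8) - cv(Iso-R1 vs Het-P8)` on a single
#' shared highly-variable-gene set; a positive delta means the intervened
#' animals sit closer (in this dispersion sense) to the young controls
#' than the aged controls do.
#'
#' @inheritParams cv_statistic
#' @param hvgs Optional HVG set; when `NULL`, [select_hvg()] is run on the
#'   pooled cells of the three groups involved.
#' @param n_hvg HVG count when selecting internally (default 1500).
#' @return A one-row tibble with columns `cell_type`, `cv_aged`,
#'   `cv_intervened`, `delta_cv`, `n_hvg`. Either CV undefined makes
#'   `delta_cv` `NA`.
#' @export
cv_delta <- function(norm, annotation, cell_type = NULL, organ = NULL,
                     hvgs = NULL, n_hvg = 1500) {
  needed <- c("Iso-R1", "Iso-P8", "Het-P8")
  cells <- lapply(needed, function(g) {
    intersect(scope_cells(annotation, g, cell_type, organ), colnames(norm))
  })
  names(cells) <- needed
  empty <- needed[lengths(cells) == 0]
  if (length(empty)) {
    stop("group(s) absent for CV delta: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(hvgs)) {
    hvgs <- select_hvg(norm, cells = unlist(cells), n = n_hvg)
  }
  cv_aged <- cv_statistic(norm, annotation, "Iso-R1", "Iso-P8", hvgs,
                          cell_type = cell_type, organ = organ)
  cv_int <- cv_statistic(norm, annotation, "Iso-R1", "Het-P8", hvgs,
                         cell_type = cell_type, organ = organ)
  tibble::tibble(
    cell_type = cell_type %||% NA_character_,
    cv_aged = cv_aged,
    cv_intervened = cv_int,
    delta_cv = cv_aged - cv_int,
    n_hvg = length(hvgs)
  )
}

#' Pearson similarity between experimental groups
#'
#' Builds per-group mean-expression vectors over a gene set (typically the
#' DEG union) and returns their pairwise Pearson correlation matrix.
#' Zero-variance vectors produce `NA` entries.
#'
#' @param norm Log-normalized gene-by-cell matrix.
#' @param annotation Cell annotation tibble.
#' @param gene_set At least two genes over which groups are compared.
#' @param cell_type,organ Optional scope restriction.
#' @param groups Groups to include; defaults to all groups present in scope.
#' @param scale_rows Return the row-scaled (z-scored by row) copy for
#'   display instead of the raw correlations.
#' @return A symmetric correlation matrix of class `group_similarity` with
#'   unit diagonal (unless a vector was degenerate).
#' @export
group_similarity <- function(norm, annotation, gene_set, cell_type = NULL,
                             organ = NULL, groups = NULL, scale_rows = FALSE) {
  gene_set <- intersect(gene_set, rownames(norm))
  if (length(gene_set) < 2) {
    stop("group similarity needs at least 2 genes present in the matrix",
         call. = FALSE)
  }
  groups <- groups %||% intersect(parabiosis_groups(), unique(annotation$group))
  vecs <- vapply(groups, function(g) {
    cells <- intersect(scope_cells(annotation, g, cell_type, organ),
                       colnames(norm))
    if (!length(cells)) {
      stop(sprintf("group '%s' has no cells in scope", g), call. = FALSE)
    }
    Matrix::rowMeans(norm[gene_set, cells, drop = FALSE])
  }, numeric(length(gene_set)))
  r <- suppressWarnings(cor(vecs, method = "pearson"))
  if (scale_rows) {
    r <- t(scale(t(r)))
    attr(r, "scaled:center") <- NULL
    attr(r, "scaled:scale") <- NULL
  }
  structure(r, class = c("group_similarity", class(r)))
}
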