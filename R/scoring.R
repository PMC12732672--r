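#' Assign shared-DEG modules across subtypes
#'
#' Each (gene, direction) pair is mapped to the subset of subtypes in which
#' the gene is a DEG with that direction. Modules enumerate direction ×
#' non-empty subtype subsets canonically — up-modules first, subsets in
#' binary order over the subtype list (subtype i contributes bit `2^(i-1)`)
#' — so for `S` subtypes there are at most `2 * (2^S - 1)` modules (14 for
#' three subtypes). A gene can hold one up- and one down-assignment (from
#' different subtypes), never two of the same direction.
#'
#' @param deg_tables Named list (length >= 2) of `deg_table`s, one per
#'   subtype, in the canonical subtype order.
#' @return A tibble with columns `gene`, `direction`, `member_subtypes`
#'   (comma-separated), `module_id`, ordered by module then gene.
#' @export
assign_modules <- function(deg_tables) {
  if (length(deg_tables) < 2) {
    stop("module assignment needs at least 2 subtype DEG tables", call. = FALSE)
  }
  if (is.null(names(deg_tables)) || any(!nzchar(names(deg_tables)))) {
    stop("deg_tables must be a named list of subtypes", call. = FALSE)
  }
  subtypes <- names(deg_tables)
  s_count <- length(subtypes)
  one_direction <- function(dir) {
    sets <- lapply(deg_tables, function(tbl) {
      tbl <- tibble::as_tibble(tbl)
      tbl$gene[tbl$is_deg & tbl$direction == dir]
    })
    genes <- sort(unique(unlist(sets)))
    if (!length(genes)) return(NULL)
    mask <- Reduce(`+`, lapply(seq_len(s_count), function(i) {
      as.integer(genes %in% sets[[i]]) * 2^(i - 1)
    }))
    members <- vapply(mask, function(m) {
      paste(subtypes[bitwAnd(m, 2^(seq_len(s_count) - 1)) > 0], collapse = ",")
    }, character(1))
    tibble::tibble(
      gene = genes,
      direction = dir,
      member_subtypes = members,
      module_id = as.integer(if (dir == "up") mask else (2^s_count - 1) + mask)
    )
  }
  out <- dplyr::bind_rows(one_direction("up"), one_direction("down"))
  if (is.null(out) || !nrow(out)) {
    return(tibble::tibble(gene = character(), direction = character(),
                          member_subtypes = character(), module_id = integer()))
  }
  dplyr::arrange(out, .data$module_id, .data$gene)
}

#' Per-cell gene-set identity score
#'
#' The standard expression-matched module score: genes are binned by
#' dataset-wide mean expression into `n_bins` equal-frequency bins; for
#' each set gene, `n_ctrl` control genes are drawn with replacement
#' (seeded) from its bin; a cell's score is its mean set expression minus
#' its mean control expression (duplicated control draws keep their
#' multiplicity). The score is invariant to adding a constant to all genes
#' of a cell.
#'
#' @param norm Log-normalized gene-by-cell matrix.
#' @param gene_set Non-empty character vector of genes, all present in
#'   `norm`.
#' @param n_bins Number of expression bins (default 24, reduced to the
#'   gene count when larger).
#' @param n_ctrl Control genes drawn per set gene (default 100).
#' @param seed Seed for the control draw; `NULL` uses the current RNG
#'   state.
#' @param ctrl_genes Optional explicit control pool (with multiplicity),
#'   bypassing the binned draw.
#' @return A tibble with columns `barcode` and `score`.
#' @export
identity_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100,
                           seed = NULL, ctrl_genes = NULL) {
  if (!length(gene_set)) stop("empty gene set", call. = FALSE)
  missing <- setdiff(gene_set, rownames(norm))
  if (length(missing)) {
    stop("gene set member(s) absent from matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  stopifnot(n_bins >= 1)
  if (is.null(ctrl_genes)) {
    avg <- Matrix::rowMeans(norm)
    n_bins <- min(n_bins, length(avg))
    bin <- ceiling(n_bins * rank(avg, ties.method = "first") / length(avg))
    names(bin) <- rownames(norm)
    draw <- function() {
      unlist(lapply(gene_set, function(g) {
        pool <- rownames(norm)[bin == bin[[g]]]
        pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
      }), use.names = FALSE)
    }
    ctrl_genes <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  }
  set_mean <- Matrix::colMeans(norm[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl_genes, , drop = FALSE])
  tibble::tibble(barcode = colnames(norm), score = unname(set_mean - ctrl_mean))
}
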