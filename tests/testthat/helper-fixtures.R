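# shared fixture builders; everything is generated in code

make_norm <- function(mat, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(mat)))
  m <- Matrix::Matrix(mat, sparse = TRUE)
  dimnames(m) <- list(genes, cells)
  m
}

toy_ann <- function(barcodes, groups, cell_type = "Hep", organ = "liver") {
  tibble::tibble(
    barcode = barcodes, sample_id = "s1", group = groups,
    organ = organ, cell_type = cell_type
  )
}

# a DEG-table-shaped tibble with flags derived from the published gates
fake_degs <- function(gene, lfc, p_adj, lfc_threshold = 0.25, alpha = 0.05) {
  deg <- abs(lfc) > lfc_threshold & p_adj < alpha
  tibble::tibble(
    gene = gene, avg_log2FC = lfc, pct_a = 0.5, pct_b = 0.5,
    p_value = p_adj, p_adj = p_adj, is_deg = deg,
    direction = ifelse(deg & lfc > 0, "up", ifelse(deg & lfc < 0, "down", "none"))
  )
}

write_mm_fixture <- function(dir, dims, entries, genes, barcodes) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  writeLines(
    c("%%MatrixMarket matrix coordinate integer general",
      paste(dims[1], dims[2], nrow(entries)),
      apply(entries, 1, paste, collapse = " ")),
    paths[[1]]
  )
  writeLines(genes, paths[[2]])
  writeLines(barcodes, paths[[3]])
  paths
}

# permissive QC for small synthetic matrices (defaults assume 10x-scale cells)
toy_qc <- function() {
  qc_thresholds(min_features = 1, max_features = 1e6,
                min_counts = 1, max_counts = 1e9)
}

# exact two-sided rank-sum p by full enumeration of group assignments;
# independent of the implementation under test
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  splits <- utils::combn(length(pooled), n)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mn <- n * length(b)
  p <- if (u_obs > mn / 2) {
    2 * mean(u_all >= u_obs)
  } else {
    2 * mean(u_all <= u_obs)
  }
  min(p, 1)
}
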