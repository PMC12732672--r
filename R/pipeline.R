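#' Configure an end-to-end rejuvenation-quantification run
#'
#' Bundles the input source and every stage parameter for
#' [run_pipeline()]. Exactly one of `sim`, `counts`+`annotation`, or
#' `input_paths` must be supplied.
#'
#' @param out_dir Output directory for all stage tables.
#' @param sim A [sim_config()] to simulate input data.
#' @param counts,annotation In-memory count matrix and annotation tibble.
#' @param input_paths Named list with paths `matrix`, `features`,
#'   `barcodes`, `metadata` (10x-style bundle plus annotation TSV).
#' @param qc A [qc_thresholds()] object.
#' @param min_pct,min_cells_feature,lfc_threshold,alpha Differential
#'   expression parameters, see [find_degs()].
#' @param reverse_lfc,rescue_lfc,require_rej_significance Reversal
#'   classification parameters, see [classify_reversal()].
#' @param n_hvg Highly-variable-gene count for the CV stage.
#' @param scale_factor Normalization scale, see [normalize_counts()].
#' @param identity_sets Optional named list of gene sets to score with
#'   [identity_score()].
#' @param organ_level Also run each contrast on all cells of an organ
#'   pooled across cell types (default `TRUE`).
#' @param exclude_barcodes Optional manual exclusion list for QC.
#' @param seed Seed for the seeded stages (identity-score control draws).
#' @return A validated `run_config` object.
#' @export
run_config <- function(out_dir, sim = NULL, counts = NULL, annotation = NULL,
                       input_paths = NULL, qc = qc_thresholds(),
                       min_pct = 0.1, min_cells_feature = 5,
                       lfc_threshold = 0.25, alpha = 0.05,
                       reverse_lfc = 0.1, rescue_lfc = 0.25,
                       require_rej_significance = TRUE,
                       n_hvg = 1500, scale_factor = 1e4,
                       identity_sets = NULL, organ_level = TRUE,
                       exclude_barcodes = NULL, seed = 1L) {
  sources <- c(!is.null(sim), !is.null(counts) || !is.null(annotation),
               !is.null(input_paths))
  if (sum(sources) != 1) {
    stop("supply exactly one input source: sim, counts+annotation, or input_paths",
         call. = FALSE)
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (!is.null(counts) && is.null(annotation)) {
    stop("counts supplied without annotation", call. = FALSE)
  }
  if (!is.null(input_paths)) {
    needed <- c("matrix", "features", "barcodes", "metadata")
    missing <- setdiff(needed, names(input_paths))
    if (length(missing)) {
      stop("input_paths is missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    absent <- unlist(input_paths[needed])[!file.exists(unlist(input_paths[needed]))]
    if (length(absent)) {
      stop("input file(s) not found: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  stopifnot(inherits(qc, "qc_thresholds"))
  structure(
    list(
      out_dir = out_dir, sim = sim, counts = counts, annotation = annotation,
      input_paths = input_paths, qc = qc, min_pct = min_pct,
      min_cells_feature = min_cells_feature, lfc_threshold = lfc_threshold,
      alpha = alpha, reverse_lfc = reverse_lfc, rescue_lfc = rescue_lfc,
      require_rej_significance = require_rej_significance, n_hvg = n_hvg,
      scale_factor = scale_factor, identity_sets = identity_sets,
      organ_level = organ_level, exclude_barcodes = exclude_barcodes,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

slug <- function(...) {
  gsub("[^[:alnum:]]+", "_", paste(c(...), collapse = "_"))
}

#' Run the full rejuvenation-quantification pipeline
#'
#' Executes QC, normalization, SEA and REJ differential expression per
#' (organ, cell type) scope (plus pooled per-organ scopes), reversal
#' classification and ratios, the transcriptional-noise CV delta,
#' Pearson group similarity over the DEG union, cross-subtype DEG module
#' assignment, and optional gene-set identity scoring. Every stage table
#' is written as a TSV under `cfg$out_dir` together with a summary table
#' (per scope: Rev-Up %, Rev-Down %) and a machine-readable run manifest;
#' the run is deterministic given the config.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list of class `rejuv_run` with elements
#'   `qc_report`, `degs` (nested per scope), `statuses`, `summary`,
#'   `noise`, `similarity`, `modules`, `scores` and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$sim)) {
    sim <- simulate_parabiosis(cfg$sim)
    counts <- sim$counts
    annotation <- sim$annotation
    readr::write_tsv(sim$truth, file.path(cfg$out_dir, "truth.tsv"),
                     progress = FALSE)
  } else if (!is.null(cfg$counts)) {
    counts <- cfg$counts
    annotation <- validate_annotation(cfg$annotation)
  } else {
    counts <- read_counts(cfg$input_paths$matrix, cfg$input_paths$features,
                          cfg$input_paths$barcodes)
    annotation <- read_cell_annotation(cfg$input_paths$metadata)
  }

  qc <- qc_filter(counts, cfg$qc, exclude_barcodes = cfg$exclude_barcodes)
  readr::write_tsv(qc$report, file.path(cfg$out_dir, "qc_report.tsv"),
                   progress = FALSE)
  norm <- normalize_counts(qc$counts, cfg$scale_factor)
  annotation <- annotation[annotation$barcode %in% colnames(norm), , drop = FALSE]

  scopes <- dplyr::distinct(annotation, .data$organ, .data$cell_type)
  scopes <- dplyr::arrange(scopes, .data$organ, .data$cell_type)
  if (cfg$organ_level) {
    pooled <- dplyr::distinct(scopes, .data$organ)
    pooled$cell_type <- NA_character_
    scopes <- dplyr::bind_rows(pooled, scopes)
  }

  degs <- list()
  statuses <- list()
  reports <- list()
  noise <- list()
  similarity <- list()
  for (i in seq_len(nrow(scopes))) {
    organ <- scopes$organ[[i]]
    ct <- scopes$cell_type[[i]]
    if (is.na(ct)) ct <- NULL
    label <- paste(c(organ, ct), collapse = "/")
    sub <- annotation[annotation$organ == organ, , drop = FALSE]
    if (!is.null(ct)) sub <- sub[sub$cell_type == ct, , drop = FALSE]
    present <- unique(sub$group)
    for (need in list(c("Iso-P8", "SEA"), c("Iso-R1", "SEA"),
                      c("Het-P8", "REJ"))) {
      if (!need[[1]] %in% present) {
        stop(sprintf(
          "scope %s: group %s absent, %s contrast cannot be formed",
          label, need[[1]], need[[2]]
        ), call. = FALSE)
      }
    }
    sea <- find_degs(norm, annotation, sea_contrast(cell_type = ct, organ = organ),
                     min_pct = cfg$min_pct,
                     min_cells_feature = cfg$min_cells_feature,
                     lfc_threshold = cfg$lfc_threshold, alpha = cfg$alpha)
    rej <- find_degs(norm, annotation, rej_contrast(cell_type = ct, organ = organ),
                     min_pct = cfg$min_pct,
                     min_cells_feature = cfg$min_cells_feature,
                     lfc_threshold = cfg$lfc_threshold, alpha = cfg$alpha)
    write_deg_table(sea, file.path(cfg$out_dir, sprintf("deg_SEA_%s.tsv", slug(organ, ct))))
    write_deg_table(rej, file.path(cfg$out_dir, sprintf("deg_REJ_%s.tsv", slug(organ, ct))))
    st <- classify_reversal(sea, rej, reverse_lfc = cfg$reverse_lfc,
                            rescue_lfc = cfg$rescue_lfc, alpha = cfg$alpha,
                            require_rej_significance = cfg$require_rej_significance)
    degs[[label]] <- list(SEA = sea, REJ = rej)
    statuses[[label]] <- st
    reports[[label]] <- if (nrow(st)) reversal_ratio(st, scope = label)
    if (!is.null(ct)) {
      noise[[label]] <- dplyr::mutate(
        cv_delta(norm, annotation, cell_type = ct, organ = organ,
                 n_hvg = cfg$n_hvg),
        scope = label, .before = 1
      )
    }
    deg_union <- union(sea$gene[sea$is_deg], rej$gene[rej$is_deg])
    if (length(deg_union) >= 2) {
      sim_mat <- group_similarity(norm, annotation, deg_union,
                                  cell_type = ct, organ = organ,
                                  groups = intersect(parabiosis_groups(), present))
      similarity[[label]] <- sim_mat
      readr::write_tsv(
        dplyr::bind_cols(tibble::tibble(group = rownames(sim_mat)),
                         tibble::as_tibble(unclass(sim_mat))),
        file.path(cfg$out_dir, sprintf("similarity_%s.tsv", slug(organ, ct))),
        progress = FALSE
      )
    }
  }

  summary_tbl <- dplyr::bind_rows(reports)
  readr::write_tsv(summary_tbl, file.path(cfg$out_dir, "summary.tsv"),
                   progress = FALSE)
  noise_tbl <- dplyr::bind_rows(noise)
  if (nrow(noise_tbl)) {
    readr::write_tsv(noise_tbl, file.path(cfg$out_dir, "noise.tsv"),
                     progress = FALSE)
  }

  modules <- list()
  ct_scopes <- dplyr::distinct(annotation, .data$organ, .data$cell_type)
  for (organ in unique(ct_scopes$organ)) {
    cts <- sort(ct_scopes$cell_type[ct_scopes$organ == organ])
    if (length(cts) < 2) next
    tables <- setNames(
      lapply(cts, function(ct) degs[[paste(organ, ct, sep = "/")]]$SEA), cts
    )
    modules[[organ]] <- assign_modules(tables)
    readr::write_tsv(modules[[organ]],
                     file.path(cfg$out_dir, sprintf("modules_%s.tsv", slug(organ))),
                     progress = FALSE)
  }

  scores <- NULL
  if (length(cfg$identity_sets)) {
    scores <- purrr::imap(cfg$identity_sets, function(set, nm) {
      dplyr::mutate(
        identity_score(norm, intersect(set, rownames(norm)), seed = cfg$seed),
        set = nm, .before = 1
      )
    })
    scores <- dplyr::bind_rows(scores)
    readr::write_tsv(scores, file.path(cfg$out_dir, "scores.tsv"),
                     progress = FALSE)
  }

  manifest <- cfg[c("min_pct", "min_cells_feature", "lfc_threshold", "alpha",
                    "reverse_lfc", "rescue_lfc", "require_rej_significance",
                    "n_hvg", "scale_factor", "organ_level", "seed")]
  manifest$qc <- unclass(cfg$qc)
  if (!is.null(cfg$sim)) manifest$sim <- unclass(cfg$sim)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(
    list(qc_report = qc$report, degs = degs, statuses = statuses,
         summary = summary_tbl, noise = noise_tbl, similarity = similarity,
         modules = modules, scores = scores, out_dir = cfg$out_dir),
    class = "rejuv_run"
  ))
}

#' Check the published reversal ratios against their printed counts
#'
#' Applies the reversal-ratio display rounding ([pct_display()]) to the
#' bundled table of printed organ-level (total, reversed) count pairs, and
#' sums the per-direction DEG counts against the printed organ totals.
#'
#' @param path Fixture TSV; defaults to the copy shipped with the package.
#' @return A tibble with columns `check`, `expected`, `computed`, `pass` —
#'   six percentage checks and three organ-total checks.
#' @export
#' @examples
#' verify_printed_ratios()
verify_printed_ratios <- function(path = NULL) {
  path <- path %||% system.file("extdata", "printed_reversal_counts.tsv",
                                package = "rejuvr", mustWork = TRUE)
  printed <- readr::read_tsv(path, col_types = "ccdddd", progress = FALSE)
  pct <- tibble::tibble(
    check = sprintf("%s_%s_pct_reversed", printed$organ, printed$direction),
    expected = printed$pct_printed,
    computed = pct_display(printed$n_reversed, printed$n_deg)
  )
  totals <- dplyr::summarise(
    dplyr::group_by(printed, .data$organ),
    check = sprintf("%s_total_degs", .data$organ[[1]]),
    expected = .data$organ_total[[1]],
    computed = sum(.data$n_deg),
    .groups = "drop"
  )
  out <- dplyr::bind_rows(pct, totals[, c("check", "expected", "computed")])
  out$pass <- out$expected == out$computed
  out
}
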