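#' Volcano plot of a DEG table
#'
#' @param object A `deg_table` from [find_degs()].
#' @param ... Unused.
#' @return A ggplot object: avg_log2FC against -log10 adjusted p, coloured
#'   by DEG direction.
#' @export
autoplot.deg_table <- function(object, ...) {
  contrast <- attr(object, "contrast")
  df <- tibble::as_tibble(unclass_deg(object))
  df$neglog_p <- -log10(pmax(df$p_adj, .Machine$double.xmin))
  ggplot2::ggplot(df, ggplot2::aes(.data$avg_log2FC, .data$neglog_p,
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", none = "grey70")
    ) +
    ggplot2::labs(
      title = contrast$name %||% "differential expression",
      x = "avg_log2FC", y = expression(-log[10] ~ adjusted ~ italic(P)),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of reversal ratios
#'
#' @param report A `reversal_report` tibble (one or more scopes, e.g.
#'   the `summary` element of a [run_pipeline()] result).
#' @return A ggplot object showing Rev-Up and Rev-Down percentages per
#'   scope.
#' @export
plot_reversal_ratio <- function(report) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(unclass_deg(report))[, c("scope", "pct_up_reversed_exact",
                                               "pct_down_reversed_exact")],
    -"scope", names_to = "direction", values_to = "pct"
  )
  df$direction <- ifelse(df$direction == "pct_up_reversed_exact",
                         "Rev-Up", "Rev-Down")
  ggplot2::ggplot(df, ggplot2::aes(.data$scope, .data$pct,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(`Rev-Up` = "#b2182b",
                                          `Rev-Down` = "#2166ac")) +
    ggplot2::labs(x = NULL, y = "SEA DEGs reversed in REJ (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Heatmap of group similarity
#'
#' @param object A `group_similarity` matrix from [group_similarity()].
#' @param ... Unused.
#' @return A ggplot tile plot of the pairwise Pearson correlations.
#' @export
autoplot.group_similarity <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("group_a", "group_b", "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$group_a, .data$group_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}
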