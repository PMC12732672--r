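#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a DEG table
#'
#' @param x A `deg_table` from [find_degs()].
#' @param ... Unused.
#' @return A plain tibble of the per-gene test results.
#' @export
tidy.deg_table <- function(x, ...) {
  tibble::as_tibble(unclass_deg(x))
}

#' One-row summary of a DEG table
#'
#' @param x A `deg_table` from [find_degs()].
#' @param ... Unused.
#' @return A one-row tibble: contrast, scope, genes tested, DEG counts by
#'   direction.
#' @export
glance.deg_table <- function(x, ...) {
  cs <- attr(x, "contrast")
  tibble::tibble(
    contrast = cs$name %||% NA_character_,
    organ = cs$organ %||% NA_character_,
    cell_type = cs$cell_type %||% NA_character_,
    n_tested = nrow(x),
    n_deg = sum(x$is_deg),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down")
  )
}

#' Tidy a simulation's ground truth
#'
#' @param x A `parabiosim` from [simulate_parabiosis()].
#' @param ... Unused.
#' @return The truth ledger as a tibble.
#' @export
tidy.parabiosim <- function(x, ...) {
  x$truth
}

#' One-row summary of a simulation
#'
#' @param x A `parabiosim` from [simulate_parabiosis()].
#' @param ... Unused.
#' @return A one-row tibble of dimensions and planted-effect counts.
#' @export
glance.parabiosim <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$counts),
    n_cells = ncol(x$counts),
    n_cell_types = length(x$config$cell_types),
    n_planted = sum(x$truth$planted),
    n_reversed = sum(x$truth$reversed),
    reversal_fraction = x$config$reversal_fraction,
    seed = x$config$seed
  )
}

unclass_deg <- function(x) {
  class(x) <- setdiff(class(x), c("deg_table", "reversal_status",
                                  "reversal_report"))
  x
}
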