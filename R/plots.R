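#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an occupancy series
#'
#' Mean quantal content and Fano factor against stimulus number, faceted.
#'
#' @param object An `occupancy_series` from [occupancy_recursion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot occupancy_series
#' @export
autoplot.occupancy_series <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("stimulus", "mean_qc", "fano")],
    cols = c("mean_qc", "fano"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stimulus, y = .data$value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(
                          c(mean_qc = "mean QC", fano = "Fano factor"))) +
    ggplot2::labs(x = "stimulus number", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a quantal-content trace
#'
#' @param object A `qc_trace`.
#' @param ... Unused.
#' @return A ggplot object: QC (and amplitude when present) per stimulus.
#' @method autoplot qc_trace
#' @export
autoplot.qc_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stimulus, y = .data$qc)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = "stimulus number", y = "quantal content") +
    ggplot2::theme_minimal()
  p
}

#' Plot a feasible parameter region
#'
#' Shades the cells of the (release, refilling) probability grid
#' consistent with all supplied fluctuation-statistic bounds.
#'
#' @param object A `feasible_region` from [feasible_region()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot feasible_region
#' @export
autoplot.feasible_region <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pd, y = .data$pr,
                                   fill = .data$feasible)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey92",
                                          `TRUE` = "#2c7fb8"),
                               name = "feasible") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "refilling probability pd",
                  y = "release probability pr") +
    ggplot2::theme_minimal()
}
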