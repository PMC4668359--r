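bin_palette <- c(GAP = "#8B0000", C0_2 = "#F4A6B8", C2_5 = "#00308F",
                 C5_10 = "#7EC8E3", C10_PLUS = "#2E8B57")

bin_labels <- c(GAP = "Gap (0%)", C0_2 = "0-2%", C2_5 = "2-5%",
                C5_10 = "5-10%", C10_PLUS = ">10%")

#' Stacked representation-bin chart per group
#'
#' The conventional presentation of a gap analysis: one horizontal bar per
#' taxonomic group (or subset, or threshold), stacked by the share of species
#' in each representation bin, dark red for gap species through green for
#' species with at least 10% of their range represented.
#'
#' @param summaries A tibble with a grouping column and the five percentage
#'   columns \code{pct_gap}, \code{pct_0_2}, \code{pct_2_5}, \code{pct_5_10},
#'   \code{pct_10_plus} — e.g. a [group_summaries()] or [run_subset_table()]
#'   result.
#' @param group Name of the column labelling the bars (default the first
#'   non-percentage column).
#' @return A ggplot object.
#' @export
plot_bin_summary <- function(summaries, group = NULL) {
  pct_cols <- c(pct_gap = "GAP", pct_0_2 = "C0_2", pct_2_5 = "C2_5",
                pct_5_10 = "C5_10", pct_10_plus = "C10_PLUS")
  if (is.null(group)) {
    group <- setdiff(names(summaries), names(pct_cols))[1]
  }
  long <- tidyr::pivot_longer(summaries, cols = dplyr::all_of(names(pct_cols)),
                              names_to = "bin", values_to = "pct")
  long$bin <- factor(pct_cols[long$bin], levels = rev(names(bin_palette)))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$pct, y = factor(.data[[group]]), fill = .data$bin)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::scale_fill_manual(values = bin_palette, labels = bin_labels,
                               name = "Range represented",
                               breaks = names(bin_palette)) +
    ggplot2::labs(x = "Species (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Map a density of poorly represented species
#'
#' @param x A [density_map()].
#' @param ... Unused.
#' @return A ggplot object (cells with zero species are blank).
#' @export
plot_density_map <- function(x, ...) {
  tb <- generics::tidy(x)
  tb <- tb[tb$count > 0, ]
  ggplot2::ggplot(tb, ggplot2::aes(.data$center_lon, .data$center_lat,
                                   fill = .data$count)) +
    ggplot2::geom_tile(width = x$grid$resolution_deg,
                       height = x$grid$resolution_deg) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "Species") +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-90, 90), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s species per cell",
                                  ifelse(x$selector == "GAP", "Gap",
                                         "Very-low coverage"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.density_map <- function(object, ...) plot_density_map(object, ...)

#' Map per-cell protected fractions
#'
#' @param x A [rasterize_protection()] raster.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_protection_raster <- function(x, ...) {
  tb <- generics::tidy(x)
  tb <- tb[tb$fraction > 0, ]
  ggplot2::ggplot(tb, ggplot2::aes(.data$center_lon, .data$center_lat,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile(width = x$grid$resolution_deg,
                       height = x$grid$resolution_deg) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "Protected\nfraction") +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-90, 90), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.protection_raster <- function(object, ...) {
  plot_protection_raster(object, ...)
}

#' Coverage against range size
#'
#' Scatter of per-species coverage fraction against range area (log scale) —
#' the standard view of how representation varies with range size when the
#' protected estate is small.
#'
#' @param results A [species_coverage()] table.
#' @return A ggplot object.
#' @export
plot_coverage_by_range <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(
    .data$range_area_km2, 100 * .data$coverage_fraction,
    colour = .data$is_gap)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "#8B0000"),
                                 labels = c("covered", "gap"), name = NULL) +
    ggplot2::labs(x = "Range size (km²)", y = "Range represented (%)") +
    ggplot2::theme_minimal()
}
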