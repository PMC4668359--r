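#' Sweep the occurrence-probability threshold
#'
#' Recomputes the gap analysis at each probability threshold against a single
#' protection raster (rasterization is threshold-independent, so the raster
#' is reused across rows). Because ranges are nested in the threshold, the
#' gap percentage is non-decreasing and the median range size non-increasing
#' down the rows — the qualitative signature a sensitivity table must show.
#'
#' @param maps A [read_probability_maps()] table.
#' @param raster A [rasterize_protection()] result.
#' @param areas A [cell_area_field()] on the same grid.
#' @param thresholds Ascending, duplicate-free probabilities in \[0, 1\]
#'   (default the standard sweep 0, 0.2, 0.4, 0.5, 0.6, 0.8, 1).
#' @return Tibble, one row per threshold: \code{threshold}, \code{n_species},
#'   \code{median_range_km2}, and the five bin percentage columns of
#'   [summarize_bins()].
#' @export
run_threshold_sweep <- function(maps, raster, areas,
                                thresholds = c(0, 0.2, 0.4, 0.5, 0.6, 0.8, 1)) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending")
  }
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must lie in [0, 1]")
  rows <- purrr::map(thresholds, function(t) {
    rng <- threshold_ranges(maps, t, areas)
    if (nrow(rng) == 0) {
      return(tibble::tibble(
        threshold = t, n_species = 0L, median_range_km2 = NA_real_,
        pct_gap = NA_real_, pct_0_2 = NA_real_, pct_2_5 = NA_real_,
        pct_5_10 = NA_real_, pct_10_plus = NA_real_))
    }
    cov <- species_coverage(rng, raster, areas)
    sm <- summarize_bins(cov)
    tibble::tibble(
      threshold = t, n_species = sm$n_species,
      median_range_km2 = median_range_size(rng),
      pct_gap = sm$pct_gap, pct_0_2 = sm$pct_0_2, pct_2_5 = sm$pct_2_5,
      pct_5_10 = sm$pct_5_10, pct_10_plus = sm$pct_10_plus)
  })
  dplyr::bind_rows(rows)
}

#' Compare the four protected-area subsets at one threshold
#'
#' Builds each subset's dissolved geometry and protection raster, then runs
#' the gap analysis once per subset at a fixed probability threshold. Because
#' subset 3 is nested in 2 and subset 4 in 1, total areas and per-species
#' coverage are ordered accordingly across rows.
#'
#' @param maps A [read_probability_maps()] table.
#' @param records An [mpa_records()] table.
#' @param ocean An [ocean_mask()] (used by subsets 1 and 4).
#' @param areas A [cell_area_field()].
#' @param threshold Probability threshold (focal value 0.5).
#' @param subsets Which subsets to evaluate (default all four).
#' @return Tibble, one row per subset: \code{subset}, \code{n_mpas},
#'   \code{total_mpa_area_km2} and the bin percentage columns.
#' @export
run_subset_table <- function(maps, records, ocean, areas, threshold = 0.5,
                             subsets = 1:4) {
  grid <- areas$grid
  rng <- threshold_ranges(maps, threshold, areas)
  if (nrow(rng) == 0) stop("no species present at threshold ", threshold)
  rows <- purrr::map(subsets, function(s) {
    sel <- select_subset(records, s, ocean)
    geom <- dissolve(sel)
    ras <- rasterize_protection(geom, grid, subset = s)
    cov <- species_coverage(rng, ras, areas)
    sm <- summarize_bins(cov, total_protected_area(ras, areas))
    tibble::tibble(
      subset = s, n_mpas = nrow(sel),
      total_mpa_area_km2 = sm$total_mpa_area_km2,
      pct_gap = sm$pct_gap, pct_0_2 = sm$pct_0_2, pct_2_5 = sm$pct_2_5,
      pct_5_10 = sm$pct_5_10, pct_10_plus = sm$pct_10_plus)
  })
  dplyr::bind_rows(rows)
}
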