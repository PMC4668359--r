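COVERAGE_BINS <- c("GAP", "C0_2", "C2_5", "C5_10", "C10_PLUS")

#' Classify coverage fractions into representation bins
#'
#' The representation bins used throughout the reporting: \code{GAP} (exactly
#' zero overlap with any protected cell), \code{C0_2} (0 < c < 2%),
#' \code{C2_5} (2% <= c < 5%), \code{C5_10} (5% <= c < 10%) and
#' \code{C10_PLUS} (c >= 10%). Interior boundaries are closed on the left,
#' and 10% belongs to the top bin, so "species with 10% of their range
#' covered" count as adequately represented. Gap status takes precedence at
#' zero and is decided topologically (no overlapping cell at all), never by
#' comparing a floating-point ratio to zero.
#'
#' @param coverage_fraction Numeric vector of coverage fractions in \[0, 1\].
#' @param is_gap Logical vector: TRUE when the species' range shares no cell
#'   with positive protection.
#' @return Factor with levels \code{GAP, C0_2, C2_5, C5_10, C10_PLUS}.
#' @export
classify_bin <- function(coverage_fraction, is_gap) {
  stopifnot(length(coverage_fraction) == length(is_gap))
  bin <- cut(coverage_fraction, breaks = c(-Inf, 0.02, 0.05, 0.10, Inf),
             labels = c("C0_2", "C2_5", "C5_10", "C10_PLUS"), right = FALSE)
  bin <- as.character(bin)
  bin[is_gap] <- "GAP"
  factor(bin, levels = COVERAGE_BINS)
}

#' Per-species protected-area coverage
#'
#' The core representation statistic. With the species data on a coarse grid
#' and protected-area boundaries far finer, the area of a species' range
#' represented in protected areas is taken to be the protected area of every
#' cell the species is present in:
#' \deqn{covered = \sum_{i \in range} f_i a_i, \quad
#'       coverage = covered / \sum_{i \in range} a_i}
#' where \eqn{f_i} is the cell's protected fraction and \eqn{a_i} its
#' spherical area. This overestimates representation when a species occupies
#' only the unprotected part of a cell — the documented consequence of the
#' resolution mismatch. A species is a gap species when no cell of its range
#' has positive protection.
#'
#' @param ranges A [threshold_ranges()] table (non-empty).
#' @param raster A [rasterize_protection()] result on the same grid.
#' @param areas A [cell_area_field()] on the same grid.
#' @return A tibble of class \code{coverage_results}: one row per species
#'   with \code{species_id}, \code{subset}, \code{threshold},
#'   \code{covered_area_km2}, \code{range_area_km2}, \code{coverage_fraction},
#'   \code{is_gap}, \code{bin}.
#' @export
species_coverage <- function(ranges, raster, areas) {
  grid <- attr(ranges, "grid")
  if (!same_grid(grid, raster$grid) || !same_grid(grid, areas$grid)) {
    stop("grid mismatch between ranges, raster and areas")
  }
  if (nrow(ranges) == 0) stop("empty species ranges")
  f <- raster$fraction[cbind(ranges$row, ranges$col)]
  a <- areas$band_km2[ranges$row]
  per <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(species_id = ranges$species_id,
                                   covered = f * a, area = a, hit = f > 0),
                    .data$species_id),
    covered_area_km2 = sum(.data$covered),
    range_area_km2 = sum(.data$area),
    is_gap = !any(.data$hit),
    .groups = "drop")
  # a gap species' covered area is exactly zero by construction
  per$covered_area_km2[per$is_gap] <- 0
  out <- tibble::tibble(
    species_id = per$species_id,
    subset = raster$subset,
    threshold = attr(ranges, "threshold"),
    covered_area_km2 = per$covered_area_km2,
    range_area_km2 = per$range_area_km2,
    coverage_fraction = per$covered_area_km2 / per$range_area_km2,
    is_gap = per$is_gap)
  out$bin <- classify_bin(out$coverage_fraction, out$is_gap)
  class(out) <- c("coverage_results", class(out))
  out
}

#' Summarise coverage into bin proportions
#'
#' One row in a Table-1 / Table-2 style summary: the percentage of species in
#' each representation bin, plus the species count and (optionally) the total
#' protected area of the subset.
#'
#' @param results A [species_coverage()] table; all rows must share one
#'   subset and threshold.
#' @param total_mpa_area_km2 Optional total protected area to carry along.
#' @return One-row tibble: \code{subset}, \code{threshold}, \code{n_species},
#'   \code{total_mpa_area_km2}, \code{pct_gap}, \code{pct_0_2},
#'   \code{pct_2_5}, \code{pct_5_10}, \code{pct_10_plus} (percentages summing
#'   to 100).
#' @export
summarize_bins <- function(results, total_mpa_area_km2 = NA_real_) {
  if (nrow(results) == 0) stop("no coverage results to summarise")
  if (dplyr::n_distinct(results$subset) > 1 ||
      dplyr::n_distinct(results$threshold) > 1) {
    stop("results mix subsets or thresholds; summarise one slice at a time")
  }
  n <- nrow(results)
  pct <- 100 * as.numeric(table(results$bin)[COVERAGE_BINS]) / n
  tibble::tibble(
    subset = results$subset[1], threshold = results$threshold[1],
    n_species = n, total_mpa_area_km2 = total_mpa_area_km2,
    pct_gap = pct[1], pct_0_2 = pct[2], pct_2_5 = pct[3],
    pct_5_10 = pct[4], pct_10_plus = pct[5])
}

#' Per-taxon bin summaries with median range sizes
#'
#' Groups species by phylum — optionally splitting the largest phylum into
#' its classes, the conventional presentation when one phylum (Chordata)
#' dominates the species list — and reports each group's bin percentages and
#' median range size. Species without a taxonomy label are grouped as
#' \code{"UNKNOWN"}, never dropped.
#'
#' @param results A [species_coverage()] table.
#' @param taxonomy Tibble with \code{species_id}, \code{phylum}, \code{class}
#'   (e.g. \code{dplyr::distinct} rows of a \code{species_maps} table).
#' @param ranges The [threshold_ranges()] used for \code{results} (provides
#'   range areas for the medians).
#' @param split_largest_phylum Split the most speciose phylum into classes?
#' @return Tibble: one row per group with \code{group}, \code{level}
#'   (\code{"phylum"} or \code{"class"}), \code{n_species}, bin percentage
#'   columns and \code{median_range_km2}.
#' @export
group_summaries <- function(results, taxonomy, ranges,
                            split_largest_phylum = TRUE) {
  tax <- dplyr::distinct(taxonomy[, c("species_id", "phylum", "class")])
  df <- dplyr::left_join(results, tax, by = "species_id")
  df$phylum[is.na(df$phylum)] <- "UNKNOWN"
  df$class[is.na(df$class)] <- "UNKNOWN"
  df$range_area_km2 <- NULL # recomputed from the ranges argument
  df <- dplyr::left_join(df, range_sizes(ranges), by = "species_id")
  df$group <- df$phylum
  df$level <- "phylum"
  if (split_largest_phylum && nrow(df) > 0) {
    counts <- sort(table(df$phylum), decreasing = TRUE)
    largest <- names(counts)[1]
    in_largest <- df$phylum == largest
    df$group[in_largest] <- paste0(largest, ": ", df$class[in_largest])
    df$level[in_largest] <- "class"
  }
  dplyr::summarise(
    dplyr::group_by(df, .data$group, .data$level),
    n_species = dplyr::n(),
    pct_gap = 100 * mean(.data$bin == "GAP"),
    pct_0_2 = 100 * mean(.data$bin == "C0_2"),
    pct_2_5 = 100 * mean(.data$bin == "C2_5"),
    pct_5_10 = 100 * mean(.data$bin == "C5_10"),
    pct_10_plus = 100 * mean(.data$bin == "C10_PLUS"),
    median_range_km2 = stats::median(.data$range_area_km2),
    .groups = "drop")
}

#' Density map of poorly represented species
#'
#' Overlays the ranges of a selected species set — gap species, or very-low
#' coverage species (< 2% of range represented, which includes the gap
#' species) — and counts, per cell, how many selected species occur there.
#'
#' @param results A [species_coverage()] table.
#' @param ranges The matching [threshold_ranges()] table.
#' @param selector \code{"GAP"} (zero overlap only) or \code{"VERY_LOW"}
#'   (coverage below 2%, gap species included).
#' @return Object of class \code{density_map}: list with \code{grid},
#'   \code{selector}, \code{count} (integer matrix) and \code{n_species}.
#' @export
density_map <- function(results, ranges, selector = c("GAP", "VERY_LOW")) {
  selector <- match.arg(selector)
  grid <- attr(ranges, "grid")
  chosen <- if (selector == "GAP") results$species_id[results$is_gap] else
    results$species_id[results$is_gap | results$coverage_fraction < 0.02]
  cnt <- matrix(0L, grid$n_rows, grid$n_cols)
  sel <- ranges[ranges$species_id %in% chosen, ]
  if (nrow(sel) > 0) {
    tab <- dplyr::count(sel, .data$row, .data$col)
    cnt[cbind(tab$row, tab$col)] <- as.integer(tab$n)
  }
  structure(list(grid = grid, selector = selector, count = cnt,
                 n_species = length(unique(chosen))),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s: %d species, max %d per cell\n",
              x$selector, x$n_species, max(x$count)))
  invisible(x)
}

#' @export
tidy.density_map <- function(x, ...) {
  tb <- tidy.cell_area_field(cell_area_field(x$grid))
  tb$area_km2 <- NULL
  tb$count <- as.vector(t(x$count))
  tb
}

# region id (or NA) for each range cell center, given eez polygons
range_cell_regions <- function(ranges, eez) {
  grid <- attr(ranges, "grid")
  cells <- dplyr::distinct(ranges[, c("row", "col")])
  ctr <- cell_center(cells$row, cells$col, grid)
  cells$region <- NA_character_
  for (i in seq_len(nrow(eez))) {
    rings <- eez$geometry[[i]]
    bb <- rings_bbox(rings)
    cand <- which(is.na(cells$region) &
                    ctr$center_lon >= bb[1] & ctr$center_lon <= bb[2] &
                    ctr$center_lat >= bb[3] & ctr$center_lat <= bb[4])
    if (length(cand) == 0) next
    hit <- point_in_rings(ctr$center_lon[cand], ctr$center_lat[cand], rings)
    cells$region[cand[hit]] <- eez$region[i]
  }
  dplyr::left_join(ranges[, c("species_id", "row", "col")], cells,
                   by = c("row", "col"))
}

#' Attribute gap species to exclusive economic zones
#'
#' A species is "found inside" an EEZ when at least one of its range cells'
#' centers falls inside any EEZ polygon — a cheap, unambiguous rule at
#' half-degree resolution. A species straddling several EEZs counts in each
#' region's tally but once in the overall proportion.
#'
#' @param results A [species_coverage()] table.
#' @param ranges The matching [threshold_ranges()] table.
#' @param eez Tibble with \code{region} (identifier) and \code{geometry}
#'   (list of ring lists).
#' @return List with \code{species} (tibble: \code{species_id},
#'   \code{in_eez}), \code{regions} (tibble: \code{region},
#'   \code{n_gap_species}), and \code{pct_in_eez} (percentage of gap species
#'   found inside at least one EEZ; \code{NaN} when there are none).
#' @export
eez_attribution <- function(results, ranges, eez) {
  if (!all(c("region", "geometry") %in% names(eez))) {
    stop("eez must have columns 'region' and 'geometry'")
  }
  if (any(is.na(eez$region) | eez$region == "")) {
    stop("every EEZ polygon needs a region identifier")
  }
  gap_ids <- results$species_id[results$is_gap]
  gr <- ranges[ranges$species_id %in% gap_ids, ]
  attr(gr, "grid") <- attr(ranges, "grid")
  reg <- range_cell_regions(gr, eez)
  sp <- dplyr::summarise(dplyr::group_by(reg, .data$species_id),
                         in_eez = any(!is.na(.data$region)),
                         .groups = "drop")
  per_region <- dplyr::count(dplyr::distinct(
    reg[!is.na(reg$region), c("species_id", "region")]),
    .data$region, name = "n_gap_species")
  per_region <- dplyr::left_join(
    tibble::tibble(region = sort(unique(eez$region))), per_region,
    by = "region")
  per_region$n_gap_species[is.na(per_region$n_gap_species)] <- 0L
  list(species = sp, regions = per_region,
       pct_in_eez = 100 * mean(sp$in_eez))
}

#' Gap species recoverable by protecting chosen regions
#'
#' Counts the gap species that have at least one range cell (by cell center)
#' inside the named regions — the species that would cease to be gap species
#' if those regions were fully protected. Monotone non-decreasing as regions
#' are added.
#'
#' @param results A [species_coverage()] table.
#' @param ranges The matching [threshold_ranges()] table.
#' @param regions Character vector of region identifiers (subset of
#'   \code{eez$region}); may be empty. The pseudo-region \code{"HIGH_SEAS"}
#'   names all cells outside every EEZ, so all regions plus the high seas
#'   reach every gap species.
#' @param eez EEZ polygon tibble as in [eez_attribution()].
#' @return Integer count of gap species reachable from the region set.
#' @export
region_cover_potential <- function(results, ranges, regions, eez) {
  unknown <- setdiff(regions, c(eez$region, "HIGH_SEAS"))
  if (length(unknown) > 0) {
    stop("unknown region(s): ", paste(unknown, collapse = ", "))
  }
  if (length(regions) == 0) return(0L)
  gap_ids <- results$species_id[results$is_gap]
  gr <- ranges[ranges$species_id %in% gap_ids, ]
  attr(gr, "grid") <- attr(ranges, "grid")
  reg <- range_cell_regions(gr, eez)
  in_named <- !is.na(reg$region) & reg$region %in% regions
  if ("HIGH_SEAS" %in% regions) in_named <- in_named | is.na(reg$region)
  length(unique(reg$species_id[in_named]))
}

#' @rdname species_coverage
#' @param x A \code{coverage_results} tibble.
#' @param ... Unused.
#' @return \code{glance()} returns a one-row overview: species and gap
#'   counts, gap percentage, percentage under 10% coverage, and the median
#'   coverage fraction.
#' @export
glance.coverage_results <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x),
    n_gap = sum(x$is_gap),
    pct_gap = 100 * mean(x$is_gap),
    pct_under_10 = 100 * mean(x$bin != "C10_PLUS"),
    median_coverage = stats::median(x$coverage_fraction))
}
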