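#' Read species occurrence-probability maps
#'
#' Ingests a long table of modelled occurrence probabilities — one row per
#' species per grid cell, probabilities in \[0, 1\] at cell centers — into the
#' sparse per-species representation used downstream. This matches the
#' structure of gridded species-distribution-model output where each species
#' has a preferred core at probability 1 and suitability decays to 0 at the
#' range limits.
#'
#' Zero-probability rows are dropped (the maps are sparse by convention);
#' duplicate (species, cell) rows and coordinates that are not cell centers
#' of the supplied grid (within 1e-6 degrees) are rejected with the offending
#' row numbers.
#'
#' @param source A data frame with columns \code{species_id}, \code{kingdom},
#'   \code{phylum}, \code{class}, \code{center_lon}, \code{center_lat},
#'   \code{probability}, or a path to a CSV file with that header (a
#'   \code{.parquet} path is read with the arrow package when installed).
#' @param grid A [grid_spec()].
#' @return A tibble of class \code{species_maps} with columns
#'   \code{species_id}, \code{kingdom}, \code{phylum}, \code{class},
#'   \code{row}, \code{col}, \code{probability}; the grid is carried in
#'   attribute \code{grid}.
#' @export
read_probability_maps <- function(source, grid) {
  if (is.character(source) && length(source) == 1) {
    source <- if (grepl("\\.parquet$", source)) {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("reading parquet requires the arrow package")
      }
      arrow::read_parquet(source)
    } else {
      utils::read.csv(source, stringsAsFactors = FALSE)
    }
  }
  need <- c("species_id", "kingdom", "phylum", "class",
            "center_lon", "center_lat", "probability")
  miss <- setdiff(need, names(source))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  p <- as.numeric(source$probability)
  if (any(is.na(p))) stop("non-numeric probability at row(s) ",
                          paste(utils::head(which(is.na(p)), 5), collapse = ", "))
  if (any(p < 0 | p > 1)) {
    stop("probability outside [0,1] at row(s) ",
         paste(utils::head(which(p < 0 | p > 1), 5), collapse = ", "))
  }
  res <- grid$resolution_deg
  exp_lat <- grid$lat_origin - res / 2 -
    round((grid$lat_origin - res / 2 - source$center_lat) / res) * res
  exp_lon <- grid$lon_origin + res / 2 +
    round((source$center_lon - grid$lon_origin - res / 2) / res) * res
  off <- abs(exp_lat - source$center_lat) > 1e-6 |
    abs(exp_lon - source$center_lon) > 1e-6
  if (any(off)) {
    stop("coordinates are not cell centers at row(s) ",
         paste(utils::head(which(off), 5), collapse = ", "))
  }
  idx <- point_to_cell(source$center_lat, source$center_lon, grid)
  out <- tibble::tibble(
    species_id = as.character(source$species_id),
    kingdom = as.character(source$kingdom),
    phylum = as.character(source$phylum),
    class = as.character(source$class),
    row = idx$row, col = idx$col, probability = p)
  dup <- duplicated(out[, c("species_id", "row", "col")])
  if (any(dup)) {
    stop("duplicate (species, cell) rows at row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  }
  out <- dplyr::filter(out, .data$probability > 0)
  if (nrow(out) == 0) stop("no positive-probability cells in input")
  attr(out, "grid") <- grid
  class(out) <- c("species_maps", class(out))
  out
}

#' Write species maps to the long-CSV dialect
#'
#' @param maps A \code{species_maps} tibble.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_probability_maps <- function(maps, path) {
  grid <- attr(maps, "grid")
  ctr <- cell_center(maps$row, maps$col, grid)
  out <- tibble::tibble(
    species_id = maps$species_id, kingdom = maps$kingdom,
    phylum = maps$phylum, class = maps$class,
    center_lon = ctr$center_lon, center_lat = ctr$center_lat,
    probability = maps$probability)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Threshold probability maps into binary ranges
#'
#' A species is treated as present in a cell when its occurrence probability
#' meets the threshold: \code{probability >= t} for \code{t > 0}. At
#' \code{t = 0} presence means \code{probability > 0} — the least conservative
#' range, every cell with any predicted suitability — since otherwise every
#' species would occupy the whole ocean. Ranges are therefore nested: raising
#' the threshold never adds cells.
#'
#' Species with no cells at the threshold have no defined coverage; they are
#' excluded here and their ids recorded in attribute \code{excluded_species}.
#'
#' @param maps A [read_probability_maps()] table.
#' @param threshold Probability threshold in \[0, 1\] (the focal analysis
#'   value is 0.5).
#' @param areas A [cell_area_field()] on the same grid.
#' @return A tibble of class \code{species_ranges} with columns
#'   \code{species_id}, \code{row}, \code{col}, \code{area_km2}; attributes
#'   \code{grid}, \code{threshold}, \code{excluded_species}.
#' @export
threshold_ranges <- function(maps, threshold, areas) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single probability in [0, 1]")
  }
  grid <- attr(maps, "grid")
  if (!same_grid(grid, areas$grid)) stop("grid mismatch")
  keep <- if (threshold > 0) maps$probability >= threshold else
    maps$probability > 0
  out <- tibble::tibble(species_id = maps$species_id[keep],
                        row = maps$row[keep], col = maps$col[keep])
  out$area_km2 <- areas$band_km2[out$row]
  attr(out, "grid") <- grid
  attr(out, "threshold") <- threshold
  attr(out, "excluded_species") <-
    setdiff(unique(maps$species_id), unique(out$species_id))
  class(out) <- c("species_ranges", class(out))
  out
}

#' Range sizes in km^2
#'
#' @param ranges A [threshold_ranges()] table.
#' @return Tibble with \code{species_id}, \code{n_cells},
#'   \code{range_area_km2} (sum of spherical cell areas over member cells).
#' @export
range_sizes <- function(ranges) {
  dplyr::summarise(dplyr::group_by(ranges, .data$species_id),
                   n_cells = dplyr::n(),
                   range_area_km2 = sum(.data$area_km2), .groups = "drop")
}

#' Median range size
#'
#' The statistical median of per-species range areas (mean of the two central
#' values for even counts) — the summary tracked across threshold sweeps.
#'
#' @param range_area_km2 Numeric vector of per-species range areas, or a
#'   \code{species_ranges} table.
#' @return Median range size in km^2.
#' @export
median_range_size <- function(range_area_km2) {
  if (inherits(range_area_km2, "species_ranges")) {
    range_area_km2 <- range_sizes(range_area_km2)$range_area_km2
  }
  if (length(range_area_km2) == 0) stop("no species ranges supplied")
  stats::median(range_area_km2)
}
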