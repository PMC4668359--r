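ring_to_coords <- function(ring) {
  closed <- rbind(ring, ring[1, , drop = FALSE])
  purrr::map(seq_len(nrow(closed)), ~c(closed[.x, 1], closed[.x, 2]))
}

coords_to_ring <- function(coords) {
  m <- do.call(rbind, purrr::map(coords, ~as.numeric(unlist(.x))))
  clean_ring(m)
}

feature_multipolygon <- function(rings, properties) {
  list(type = "Feature", properties = properties,
       geometry = list(type = "MultiPolygon",
                       coordinates = purrr::map(rings, ~list(ring_to_coords(.x)))))
}

#' Write and read protected-area records as GeoJSON
#'
#' A plain FeatureCollection of MultiPolygons with properties \code{pa_id},
#' \code{name}, \code{marine_flag}, \code{iucn_category}. Geometry is
#' lon-lat (WGS84) degrees, matching the package's straight-edge convention.
#'
#' @param records An [mpa_records()] table.
#' @param path File path.
#' @return \code{path} (write) / an \code{mpa_records} tibble (read).
#' @export
write_mpa_geojson <- function(records, path) {
  feats <- purrr::map(seq_len(nrow(records)), function(i) {
    feature_multipolygon(records$geometry[[i]], list(
      pa_id = records$pa_id[i], name = records$name[i],
      marine_flag = records$marine_flag[i],
      iucn_category = records$iucn_category[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_mpa_geojson
#' @export
read_mpa_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- purrr::map(fc$features, function(f) {
    p <- f$properties
    rings <- purrr::map(f$geometry$coordinates, ~coords_to_ring(.x[[1]]))
    tibble::tibble(
      pa_id = as.character(p$pa_id),
      name = as.character(p$name %||% p$pa_id),
      marine_flag = if (is.null(p$marine_flag)) NA else as.logical(p$marine_flag),
      iucn_category = if (is.null(p$iucn_category)) NA_character_ else
        as.character(p$iucn_category),
      geometry = list(purrr::compact(rings)))
  })
  mpa_records(dplyr::bind_rows(rows))
}

#' Write and read EEZ polygons as GeoJSON
#'
#' FeatureCollection of MultiPolygons with a \code{region} property.
#'
#' @param eez Tibble with \code{region} and \code{geometry} (list of ring
#'   lists).
#' @param path File path.
#' @return \code{path} (write) / the tibble (read).
#' @export
write_eez_geojson <- function(eez, path) {
  feats <- purrr::map(seq_len(nrow(eez)), function(i) {
    feature_multipolygon(eez$geometry[[i]], list(region = eez$region[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_eez_geojson
#' @export
read_eez_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- purrr::map(fc$features, function(f) {
    rings <- purrr::map(f$geometry$coordinates, ~coords_to_ring(.x[[1]]))
    tibble::tibble(region = as.character(f$properties$region),
                   geometry = list(purrr::compact(rings)))
  })
  dplyr::bind_rows(rows)
}

#' Write and read an ocean mask as long CSV
#'
#' Schema \code{row,col,ocean} covering every cell of the grid.
#'
#' @param ocean An [ocean_mask()].
#' @param path File path.
#' @param grid A [grid_spec()] (read side).
#' @return \code{path} (write) / an \code{ocean_mask} (read).
#' @export
write_ocean_csv <- function(ocean, path) {
  tb <- tidy.ocean_mask(ocean)
  utils::write.csv(tb[, c("row", "col", "ocean")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ocean_csv
#' @export
read_ocean_csv <- function(path, grid) {
  tb <- utils::read.csv(path)
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  m[cbind(tb$row, tb$col)] <- as.logical(tb$ocean)
  ocean_mask(grid, m)
}

#' Write a raster-like object to long CSV
#'
#' Works for [rasterize_protection()] rasters, [density_map()]s,
#' [cell_area_field()]s and [ocean_mask()]s via their \code{tidy()} methods.
#'
#' @param x A tidied-able raster object.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_raster_csv <- function(x, path) {
  utils::write.csv(generics::tidy(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
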