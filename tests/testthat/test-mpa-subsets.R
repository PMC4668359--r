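# a tiny hand-built seascape: 10-degree grid, ocean everywhere except a
# land block, three protected areas with contrasting attributes
tiny_seascape <- function() {
  g <- grid_spec(10)
  m <- matrix(TRUE, g$n_rows, g$n_cols)
  m[1:6, 1:6] <- FALSE # a land block in the north-west
  list(
    grid = g, ocean = ocean_mask(g, m),
    records = mpa_records(tibble::tibble(
      pa_id = c("A", "B", "C", "D"),
      # A: ocean rectangle; B: ocean; C: ocean; D: inside the land block
      geometry = list(
        list(rect_ring(0, 20, 0, 10)),
        list(rect_ring(40, 60, -20, -10)),
        list(rect_ring(100, 120, 10, 30)),
        list(rect_ring(-150, -140, 50, 60))),
      marine_flag = c(TRUE, FALSE, TRUE, TRUE),
      iucn_category = c("V", "II", "UNASSIGNED", "II"),
      name = c("a", "b", "c", "d"))))
}

test_that("subset predicates combine the marine flag, IUCN class and ocean overlap", {
  s <- tiny_seascape()
  kept <- function(sub) select_subset(s$records, sub, s$ocean)$pa_id
  # A: marine-flagged, IUCN V, ocean-overlapping -> subsets 1 and 2 only
  expect_true("A" %in% kept(1) && "A" %in% kept(2))
  expect_false("A" %in% kept(3) || "A" %in% kept(4))
  # B: unflagged, IUCN II, ocean-overlapping -> subsets 1 and 4 only
  expect_true("B" %in% kept(1) && "B" %in% kept(4))
  expect_false("B" %in% kept(2) || "B" %in% kept(3))
  # C: UNASSIGNED never passes the I-IV filter, whatever else holds
  expect_false("C" %in% kept(3) || "C" %in% kept(4))
  expect_true("C" %in% kept(1) && "C" %in% kept(2))
  # D: land-locked, flagged (wrongly), IUCN II -> attribute subsets only
  expect_false("D" %in% kept(1) || "D" %in% kept(4))
  expect_true("D" %in% kept(2) && "D" %in% kept(3))
  expect_error(select_subset(s$records, 5, s$ocean), "subset")
  expect_error(select_subset(s$records, 1), "ocean")
})

test_that("missing attributes take the conservative reading", {
  recs <- mpa_records(tibble::tibble(
    pa_id = c("X", "Y"),
    geometry = list(list(rect_ring(0, 10, 0, 10)),
                    list(rect_ring(20, 30, 0, 10))),
    marine_flag = c(NA, TRUE),
    iucn_category = c("II", NA)))
  expect_equal(recs$iucn_category[2], "UNASSIGNED")
  g <- grid_spec(10)
  all_ocean <- ocean_mask(g, matrix(TRUE, g$n_rows, g$n_cols))
  expect_false("X" %in% select_subset(recs, 2, all_ocean)$pa_id) # NA flag fails
  expect_false("Y" %in% select_subset(recs, 3, all_ocean)$pa_id) # NA class fails
})

test_that("subset selections nest and so do their rasters", {
  for (seed in c(101, 102)) {
    w <- rand_world(seed)
    ids <- lapply(1:4, function(s) select_subset(w$mpas, s, w$ocean)$pa_id)
    expect_true(all(ids[[3]] %in% ids[[2]]))
    expect_true(all(ids[[4]] %in% ids[[1]]))
    areas <- cell_area_field(w$grid)
    ras <- lapply(1:4, function(s) {
      rasterize_protection(dissolve(select_subset(w$mpas, s, w$ocean)),
                           w$grid, s)
    })
    # nested geometry => per-cell fractions and totals ordered the same way
    expect_true(all(ras[[3]]$fraction <= ras[[2]]$fraction + 1e-12))
    expect_true(all(ras[[4]]$fraction <= ras[[1]]$fraction + 1e-12))
    expect_lte(total_protected_area(ras[[3]], areas),
               total_protected_area(ras[[2]], areas) + 1e-6)
  }
})

test_that("dissolve counts overlapping designations once", {
  r <- rect_ring(10, 20, 0, 10)
  one <- ring_area_km2(r)
  recs <- mpa_records(tibble::tibble(
    pa_id = c("p", "q"), geometry = list(list(r), list(r)),
    marine_flag = TRUE, iucn_category = "II"))
  expect_equal(dissolved_area_km2(dissolve(recs)), one, tolerance = 1e-12)
  # half-overlapping pair -> 1.5 rectangles
  recs2 <- mpa_records(tibble::tibble(
    pa_id = c("p", "q"),
    geometry = list(list(r), list(rect_ring(15, 25, 0, 10))),
    marine_flag = TRUE, iucn_category = "II"))
  expect_equal(dissolved_area_km2(dissolve(recs2)), 1.5 * one,
               tolerance = 1e-12)
})

test_that("rasterization yields exact partial fractions", {
  g <- grid_spec(10)
  b <- cell_bounds(9, 19, g) # an equator-adjacent cell
  # polygon exactly coincident with the cell
  geom <- dissolve(mpa_records(tibble::tibble(
    pa_id = "full",
    geometry = list(list(rect_ring(b$lon_min, b$lon_max, b$lat_min, b$lat_max))),
    marine_flag = TRUE, iucn_category = "II")))
  ras <- rasterize_protection(geom, g)
  expect_equal(ras$fraction[9, 19], 1, tolerance = 1e-12)
  expect_equal(sum(ras$fraction > 1e-12), 1)
  # rectangle over the western half (in longitude): fraction exactly 0.5
  half <- dissolve(mpa_records(tibble::tibble(
    pa_id = "half",
    geometry = list(list(rect_ring(b$lon_min, (b$lon_min + b$lon_max) / 2,
                                   b$lat_min, b$lat_max))),
    marine_flag = TRUE, iucn_category = "II")))
  expect_equal(rasterize_protection(half, g)$fraction[9, 19], 0.5,
               tolerance = 1e-12)
  # empty set -> the all-zero raster is a valid "no MPAs" model
  empty <- rasterize_protection(dissolve(mpa_records(tibble::tibble(
    pa_id = character(), geometry = list(),
    marine_flag = logical(), iucn_category = character()))), g)
  expect_true(all(empty$fraction == 0))
  expect_equal(total_protected_area(empty, cell_area_field(g)), 0)
})

test_that("total protected area recovers dissolved geometry area", {
  withr::with_seed(21, {
    g <- grid_spec(5)
    areas <- cell_area_field(g)
    for (i in 1:5) {
      lon0 <- runif(1, -170, 130)
      lat0 <- runif(1, -70, 50)
      rings <- list(rect_ring(lon0, lon0 + runif(1, 3, 20),
                              lat0, lat0 + runif(1, 3, 15)))
      geom <- structure(list(rings = rings, n_records = 1),
                        class = "mpa_geometry")
      ras <- rasterize_protection(geom, g)
      expect_equal(total_protected_area(ras, areas),
                   rings_union_area_km2(rings), tolerance = 1e-9)
    }
  })
})

test_that("naive per-polygon sums can exceed 1 where the dissolved fraction cannot", {
  g <- grid_spec(10)
  b <- cell_bounds(9, 19, g)
  r1 <- rect_ring(b$lon_min, b$lon_min + 7, b$lat_min, b$lat_max)
  r2 <- rect_ring(b$lon_min + 3, b$lon_max, b$lat_min, b$lat_max)
  naive <- ring_area_km2(clip_ring_rect(r1, b$lon_min, b$lon_max, b$lat_min, b$lat_max)) +
    ring_area_km2(clip_ring_rect(r2, b$lon_min, b$lon_max, b$lat_min, b$lat_max))
  cell <- cell_area(9, 19, g)
  expect_gt(naive / cell, 1)
  geom <- structure(list(rings = list(r1, r2), n_records = 2),
                    class = "mpa_geometry")
  expect_equal(rasterize_protection(geom, g)$fraction[9, 19], 1,
               tolerance = 1e-12)
})

test_that("adding polygons never decreases any cell fraction", {
  withr::with_seed(22, {
    g <- grid_spec(10)
    rings <- lapply(1:6, function(i) {
      lon0 <- runif(1, -150, 120); lat0 <- runif(1, -60, 40)
      rect_ring(lon0, lon0 + runif(1, 5, 30), lat0, lat0 + runif(1, 5, 25))
    })
    prev <- matrix(0, g$n_rows, g$n_cols)
    for (k in seq_along(rings)) {
      geom <- structure(list(rings = rings[seq_len(k)], n_records = k),
                        class = "mpa_geometry")
      cur <- rasterize_protection(geom, g)$fraction
      expect_true(all(cur >= prev - 1e-12))
      prev <- cur
    }
  })
})

test_that("degenerate and point-like geometry is handled as specified", {
  expect_warning(
    recs <- mpa_records(tibble::tibble(
      pa_id = c("ok", "empty"),
      geometry = list(list(rect_ring(0, 10, 0, 10)),
                      list(cbind(c(1, 1, 1), c(2, 2, 2))[0, ])),
      marine_flag = TRUE, iucn_category = "II")),
    "dropped")
  expect_equal(nrow(recs), 1)
  expect_equal(attr(recs, "n_dropped"), 1)
  # a point-only record (degenerate single-vertex ring) is rejected outright
  expect_error(
    mpa_records(tibble::tibble(
      pa_id = "pt", geometry = list(list(cbind(c(5, 5, 5), c(5, 5, 5)))),
      marine_flag = TRUE, iucn_category = "II")),
    "point-only")
  expect_error(
    mpa_records(tibble::tibble(
      pa_id = "x", geometry = list(list(rect_ring(0, 1, 0, 1))),
      marine_flag = TRUE, iucn_category = "VII")),
    "IUCN")
})
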