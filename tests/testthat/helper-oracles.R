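# Independent brute-force oracles. These deliberately re-derive results with
# plain loops and their own geometry predicates so they share no code path
# with the implementation they check.

# per-species coverage by explicit per-cell accumulation
oracle_coverage <- function(ranges_df, fraction, band_km2) {
  ids <- unique(ranges_df$species_id)
  rows <- lapply(ids, function(id) {
    sub <- ranges_df[ranges_df$species_id == id, , drop = FALSE]
    covered <- 0
    total <- 0
    gap <- TRUE
    for (k in seq_len(nrow(sub))) {
      f <- fraction[sub$row[k], sub$col[k]]
      a <- band_km2[sub$row[k]]
      covered <- covered + f * a
      total <- total + a
      if (f > 0) gap <- FALSE
    }
    if (gap) covered <- 0
    data.frame(species_id = id, covered_area_km2 = covered,
               range_area_km2 = total,
               coverage_fraction = covered / total, is_gap = gap,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# bin tally by explicit if-chains
oracle_bin_percentages <- function(coverage_fraction, is_gap) {
  counts <- c(GAP = 0, C0_2 = 0, C2_5 = 0, C5_10 = 0, C10_PLUS = 0)
  for (i in seq_along(coverage_fraction)) {
    c_i <- coverage_fraction[i]
    lab <- if (is_gap[i]) "GAP"
    else if (c_i < 0.02) "C0_2"
    else if (c_i < 0.05) "C2_5"
    else if (c_i < 0.10) "C5_10"
    else "C10_PLUS"
    counts[lab] <- counts[lab] + 1
  }
  100 * counts / length(coverage_fraction)
}

# independent even-odd test: count leftward horizontal-ray crossings
oracle_point_in_rings <- function(lon, lat, rings) {
  inside <- FALSE
  for (ring in rings) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      yi <- ring[i, 2]; yj <- ring[j, 2]
      if ((yi > lat) != (yj > lat)) {
        xcross <- ring[i, 1] + (lat - yi) / (yj - yi) * (ring[j, 1] - ring[i, 1])
        if (xcross < lon) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

# cosine-weighted midpoint sampling of the covered fraction of one cell
oracle_cell_fraction <- function(rings, lon_min, lon_max, lat_min, lat_max,
                                 n = 50) {
  step_lon <- (lon_max - lon_min) / n
  step_lat <- (lat_max - lat_min) / n
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    lat <- lat_min + (i - 0.5) * step_lat
    w <- cos(lat * pi / 180)
    for (j in seq_len(n)) {
      lon <- lon_min + (j - 0.5) * step_lon
      den <- den + w
      if (oracle_point_in_rings(lon, lat, rings)) num <- num + w
    }
  }
  num / den
}

# fine midpoint quadrature of the spherical band-slice area (independent of
# the closed form it checks)
oracle_band_area <- function(lat_min, lat_max, lon_width_deg,
                             radius_km = 6371, n = 20000) {
  d2r <- pi / 180
  step <- (lat_max - lat_min) / n
  lat_mid <- lat_min + (seq_len(n) - 0.5) * step
  radius_km^2 * (lon_width_deg * d2r) * sum(cos(lat_mid * d2r)) * (step * d2r)
}

# a small randomized synthetic world for property and oracle tests
rand_world <- function(seed) {
  withr::with_seed(seed, {
    res <- sample(c(5, 6, 10), 1)
    cfg <- synthetic_world_config(
      seed = sample.int(1e6, 1),
      grid = grid_spec(res),
      ocean_fraction = runif(1, 0.55, 0.85),
      n_regions = sample(3:8, 1),
      n_species = sample(20L:60L, 1),
      range_size_cells = c(3, 40),
      core_fraction = runif(1, 0.2, 0.6),
      n_mpas = sample(10L:50L, 1),
      mpa_size_deg = c(res / 2, 2.5 * res),
      coastal_bias = runif(1, 0, 6),
      species_coastal_bias = runif(1, 0, 6))
    generate_world(cfg)
  })
}

# shared pipeline steps for a world at one subset/threshold
world_pipeline <- function(world, subset = 4, threshold = 0.5) {
  areas <- cell_area_field(world$grid)
  sel <- select_subset(world$mpas, subset, world$ocean)
  ras <- rasterize_protection(dissolve(sel), world$grid, subset = subset)
  rng <- threshold_ranges(world$maps, threshold, areas)
  list(areas = areas, selected = sel, raster = ras, ranges = rng,
       coverage = if (nrow(rng) > 0) species_coverage(rng, ras, areas))
}
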