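mk_ranges <- function(species_id, row, col, grid, threshold = 0.5) {
  areas <- cell_area_field(grid)
  out <- tibble::tibble(species_id = species_id, row = as.integer(row),
                        col = as.integer(col),
                        area_km2 = areas$band_km2[row])
  attr(out, "grid") <- grid
  attr(out, "threshold") <- threshold
  class(out) <- c("species_ranges", class(out))
  out
}

mk_raster <- function(grid, cells = NULL, subset = 4L) {
  f <- matrix(0, grid$n_rows, grid$n_cols)
  if (!is.null(cells)) f[cbind(cells$row, cells$col)] <- cells$fraction
  structure(list(grid = grid, subset = subset, fraction = f),
            class = "protection_raster")
}

test_that("coverage is the protected-fraction-weighted share of the range", {
  g <- grid_spec(10)
  areas <- cell_area_field(g)
  # two equal-area cells (same latitude band), fractions 0.5 and 0
  rng <- mk_ranges("sp", c(9, 9), c(1, 2), g)
  ras <- mk_raster(g, tibble::tibble(row = 9, col = 1, fraction = 0.5))
  cov <- species_coverage(rng, ras, areas)
  expect_equal(cov$coverage_fraction, 0.25, tolerance = 1e-14)
  expect_false(cov$is_gap)
  # no overlap anywhere: a gap species with exactly zero coverage
  gap <- species_coverage(mk_ranges("sp", 3, 5, g), ras, areas)
  expect_true(gap$is_gap)
  expect_identical(gap$covered_area_km2, 0)
  expect_equal(as.character(gap$bin), "GAP")
  expect_error(species_coverage(rng[0, ], ras, areas), "empty")
})

test_that("coverage matches the brute-force oracle on mixed latitude bands", {
  g <- grid_spec(10)
  areas <- cell_area_field(g)
  rng <- mk_ranges(rep("sp", 4), c(4, 4, 5, 5), c(7, 8, 7, 8), g)
  ras <- mk_raster(g, tibble::tibble(row = c(4, 5), col = c(7, 8),
                                     fraction = c(0.3, 0.8)))
  cov <- species_coverage(rng, ras, areas)
  ora <- oracle_coverage(rng, ras$fraction, areas$band_km2)
  expect_equal(cov$coverage_fraction, ora$coverage_fraction, tolerance = 1e-14)
  expect_equal(cov$covered_area_km2, ora$covered_area_km2, tolerance = 1e-14)
  # coverage is a weighted mean of cell fractions, bounded by their extremes
  expect_gte(cov$coverage_fraction, min(c(0.3, 0, 0, 0.8)))
  expect_lte(cov$coverage_fraction, max(c(0.3, 0, 0, 0.8)))
})

test_that("bin boundaries are closed on the left with 10% in the top bin", {
  frac <- c(0, 0.001, 0.02, 0.0199, 0.05, 0.0999, 0.10, 0.5)
  gap <- c(TRUE, rep(FALSE, 7))
  expect_equal(as.character(classify_bin(frac, gap)),
               c("GAP", "C0_2", "C2_5", "C0_2", "C5_10", "C5_10",
                 "C10_PLUS", "C10_PLUS"))
  # gap precedence over a zero ratio
  expect_equal(as.character(classify_bin(0, TRUE)), "GAP")
})

test_that("bin summaries count species, not area, and always total 100%", {
  g <- grid_spec(10)
  areas <- cell_area_field(g)
  # five species engineered one per bin via fractional protection in one cell
  rows <- rep(9L, 5)
  cols <- 1:5
  rng <- mk_ranges(paste0("s", 1:5), rows, cols, g)
  ras <- mk_raster(g, tibble::tibble(row = rows, col = cols,
                                     fraction = c(0, 0.01, 0.03, 0.07, 0.5)))
  cov <- species_coverage(rng, ras, areas)
  sm <- summarize_bins(cov)
  expect_equal(unlist(sm[, c("pct_gap", "pct_0_2", "pct_2_5", "pct_5_10",
                             "pct_10_plus")], use.names = FALSE),
               rep(20, 5))
  # all-gap world
  allgap <- species_coverage(rng, mk_raster(g), areas)
  expect_equal(summarize_bins(allgap)$pct_gap, 100)
  expect_error(summarize_bins(allgap[0, ]), "no coverage")
  mixed <- dplyr::mutate(cov, threshold = c(0.5, 0.5, 0.5, 0.4, 0.5))
  expect_error(summarize_bins(mixed), "mix")
})

test_that("taxon summaries split the largest phylum and keep unknowns", {
  g <- grid_spec(10)
  areas <- cell_area_field(g)
  rng <- mk_ranges(paste0("s", 1:6), rep(9, 6), 1:6, g)
  ras <- mk_raster(g, tibble::tibble(row = 9, col = 1:3, fraction = 0.5))
  cov <- species_coverage(rng, ras, areas)
  tax <- tibble::tibble(
    species_id = paste0("s", 1:5), # s6 lacks taxonomy on purpose
    phylum = c("Chordata", "Chordata", "Chordata", "Mollusca", "Mollusca"),
    class = c("Mammalia", "Mammalia", "Actinopterygii", "Gastropoda",
              "Gastropoda"))
  grp <- group_summaries(cov, tax, rng)
  expect_equal(sum(grp$n_species), 6)
  expect_true("UNKNOWN" %in% grp$group)
  # the largest phylum (Chordata) appears as its classes, not as a phylum bar
  expect_true(all(c("Chordata: Mammalia", "Chordata: Actinopterygii") %in%
                    grp$group))
  expect_false("Chordata" %in% grp$group)
  one <- grp[grp$group == "Chordata: Actinopterygii", ]
  expect_equal(one$pct_10_plus, 100) # its single species is fully in one bin
  # each group's percentages sum to 100
  expect_equal(rowSums(grp[, c("pct_gap", "pct_0_2", "pct_2_5", "pct_5_10",
                               "pct_10_plus")]),
               rep(100, nrow(grp)), ignore_attr = TRUE)
})

test_that("density maps add one per selected species per occupied cell", {
  g <- grid_spec(10)
  areas <- cell_area_field(g)
  rng <- mk_ranges(c("a", "a", "a", "b", "b"), c(9, 9, 10, 9, 9),
                   c(1, 2, 1, 2, 3), g)
  ras <- mk_raster(g) # nothing protected: both species are gap species
  cov <- species_coverage(rng, ras, areas)
  dm <- density_map(cov, rng, "GAP")
  expect_equal(dm$count[9, 1], 1)
  expect_equal(dm$count[9, 2], 2) # a and b overlap here
  expect_equal(dm$count[10, 1], 1)
  expect_equal(sum(dm$count), nrow(rng)) # mass = sum of range sizes in cells
  # protect everything: no gap species, all-zero map
  full <- mk_raster(g, tibble::tibble(row = c(9, 9, 9, 10),
                                      col = c(1, 2, 3, 1), fraction = 1))
  cov2 <- species_coverage(rng, full, areas)
  expect_true(all(density_map(cov2, rng, "GAP")$count == 0))
  # very-low includes gaps plus <2% coverage
  tiny <- mk_raster(g, tibble::tibble(row = 9, col = 2, fraction = 0.02))
  cov3 <- species_coverage(rng, tiny, areas)
  expect_false(any(cov3$is_gap))
  dm3 <- density_map(cov3, rng, "VERY_LOW")
  expect_equal(dm3$n_species, sum(cov3$coverage_fraction < 0.02))
})

test_that("EEZ attribution uses cell-center membership with set semantics", {
  g <- grid_spec(10)
  areas <- cell_area_field(g)
  eez <- tibble::tibble(
    region = c("R1", "R2"),
    geometry = list(list(rect_ring(-180, -90, -90, 0)), # SW quadrant
                    list(rect_ring(-90, 0, -90, 0)))) # south-central
  # sp_in: inside R1; sp_out: high seas; sp_both: straddles R1 and R2
  rng <- mk_ranges(c("in", "out", "both", "both"),
                   c(12, 3, 12, 12), c(3, 30, 8, 12), g)
  cov <- species_coverage(rng, mk_raster(g), areas) # all gap
  ez <- eez_attribution(cov, rng, eez)
  expect_equal(ez$species$in_eez[match(c("in", "out", "both"),
                                       ez$species$species_id)],
               c(TRUE, FALSE, TRUE))
  expect_equal(ez$regions$n_gap_species[ez$regions$region == "R1"], 2)
  expect_equal(ez$regions$n_gap_species[ez$regions$region == "R2"], 1)
  expect_equal(ez$pct_in_eez, 100 * 2 / 3)
  expect_error(eez_attribution(cov, rng, tibble::tibble(
    region = NA_character_, geometry = list(list(rect_ring(0, 1, 0, 1))))),
    "region identifier")
})

test_that("region cover potential counts reachable gap species monotonically", {
  g <- grid_spec(10)
  areas <- cell_area_field(g)
  eez <- tibble::tibble(
    region = c("R1", "R2"),
    geometry = list(list(rect_ring(-180, -90, -90, 0)),
                    list(rect_ring(-90, 0, -90, 0))))
  rng <- mk_ranges(c("in", "out", "both", "both"),
                   c(12, 3, 12, 12), c(3, 30, 8, 12), g)
  cov <- species_coverage(rng, mk_raster(g), areas)
  expect_equal(region_cover_potential(cov, rng, character(0), eez), 0L)
  expect_equal(region_cover_potential(cov, rng, "R1", eez), 2L)
  expect_equal(region_cover_potential(cov, rng, c("R1", "R2"), eez), 2L)
  expect_equal(region_cover_potential(cov, rng, c("R1", "R2", "HIGH_SEAS"),
                                      eez), 3L)
  expect_error(region_cover_potential(cov, rng, "Atlantis", eez), "unknown")
})

test_that("reachable gap species match generator truth on a constructed world", {
  cfg <- synthetic_world_config(seed = 41, grid = grid_spec(6),
                                n_species = 24, range_size_cells = c(3, 12),
                                n_regions = 8)
  targets <- rep(c(0, 0.5), each = 12)
  w <- generate_with_known_coverage(cfg, targets)
  pipe <- world_pipeline(w)
  gap_ids <- pipe$coverage$species_id[pipe$coverage$is_gap]
  expect_setequal(gap_ids, w$truth$species_id[w$truth$is_gap])
  # pick half the regions; expected count from the generator's own records
  chosen <- c("R01", "R02", "R03", "R04")
  expected <- sum(vapply(seq_len(nrow(w$truth)), function(i) {
    w$truth$is_gap[i] && any(w$truth$regions[[i]] %in% chosen)
  }, logical(1)))
  got <- region_cover_potential(pipe$coverage, pipe$ranges, chosen, w$eez)
  expect_equal(got, expected)
  all_regions <- c(w$eez$region, "HIGH_SEAS")
  expect_equal(region_cover_potential(pipe$coverage, pipe$ranges,
                                      all_regions, w$eez),
               sum(w$truth$is_gap))
})
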