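test_that("the same config and seed reproduce the world exactly", {
  cfg <- synthetic_world_config(seed = 61, grid = grid_spec(6),
                                n_species = 30, n_mpas = 20)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$maps, w2$maps)
  expect_identical(w1$mpas, w2$mpas)
  expect_identical(w1$ocean$mask, w2$ocean$mask)
  expect_identical(w1$eez, w2$eez)
  # a different seed gives a different world
  w3 <- generate_world(synthetic_world_config(seed = 62, grid = grid_spec(6),
                                              n_species = 30, n_mpas = 20))
  expect_false(identical(w1$maps, w3$maps))
})

test_that("component sub-streams are independent of each other's settings", {
  base <- synthetic_world_config(seed = 63, grid = grid_spec(6),
                                 n_species = 25, n_mpas = 10)
  more_mpas <- synthetic_world_config(seed = 63, grid = grid_spec(6),
                                      n_species = 25, n_mpas = 40)
  expect_identical(generate_world(base)$maps, generate_world(more_mpas)$maps)
})

test_that("species maps have a core at 1 and linear decay to the range edge", {
  w <- generate_world(synthetic_world_config(
    seed = 64, grid = grid_spec(5), n_species = 40,
    range_size_cells = c(20, 120), core_fraction = 0.3))
  expect_true(all(w$maps$probability > 0 & w$maps$probability <= 1))
  # ranges confined to ocean
  expect_true(all(w$ocean$mask[cbind(w$maps$row, w$maps$col)]))
  per_sp <- split(w$maps$probability, w$maps$species_id)
  for (p in per_sp) {
    # at least the configured share of cells sits in the probability-1 core
    expect_gte(mean(p == 1), 0.3 - 1e-12)
    # one value per accretion layer, equally spaced: linear decay
    vals <- sort(unique(p[p < 1]), decreasing = TRUE)
    if (length(vals) >= 3) {
      expect_lt(max(abs(diff(diff(vals)))), 1e-9)
    }
    expect_gt(min(p), 0) # probability hits 0 only outside the range
  }
})

test_that("core_fraction = 1 makes ranges threshold-invariant on (0, 1]", {
  w <- generate_world(synthetic_world_config(
    seed = 65, grid = grid_spec(6), n_species = 20, core_fraction = 1,
    range_size_cells = c(5, 40)))
  expect_true(all(w$maps$probability == 1))
  areas <- cell_area_field(w$grid)
  r_low <- threshold_ranges(w$maps, 0.01, areas)
  r_high <- threshold_ranges(w$maps, 1, areas)
  expect_equal(nrow(r_low), nrow(r_high))
  expect_equal(range_sizes(r_low), range_sizes(r_high))
})

test_that("range sizes follow the configured taxon-scaled log-uniform law", {
  cfg <- synthetic_world_config(seed = 66, grid = grid_spec(4),
                                n_species = 600, range_size_cells = c(5, 60),
                                species_coastal_bias = 0)
  w <- generate_world(cfg)
  got <- as.integer(table(w$maps$species_id))
  # independent reference draw of the same mixture law
  taxa_w <- c(0.45, 0.06, 0.02, 0.01, 0.16, 0.15, 0.08, 0.05, 0.02)
  mult <- c(1, 2, 8, 3, 0.7, 0.7, 0.5, 0.6, 0.4)
  ref <- withr::with_seed(1234, {
    tx <- sample.int(9, 5000, replace = TRUE, prob = taxa_w)
    pmax(1, round(exp(stats::runif(5000, log(5), log(60))) * mult[tx]))
  })
  d <- suppressWarnings(stats::ks.test(got, ref)$statistic)
  expect_lt(unname(d), 0.1)
})

test_that("protected areas concentrate near the coast under the bias", {
  cfg <- synthetic_world_config(seed = 67, grid = grid_spec(4), n_species = 5,
                                n_mpas = 300, coastal_bias = 8)
  w <- generate_world(cfg)
  coastal <- mpagap:::coastal_cells(w$ocean)
  base_rate <- sum(coastal) / sum(w$ocean$mask)
  centers <- purrr::map_dfr(w$mpas$geometry, function(g) {
    bb <- mpagap:::rings_bbox(g)
    tibble::tibble(lon = mean(bb[1:2]), lat = mean(bb[3:4]))
  })
  idx <- point_to_cell(pmax(-90, pmin(90, centers$lat)),
                       pmax(-180, pmin(180, centers$lon)), w$grid)
  hit_rate <- mean(coastal[cbind(idx$row, idx$col)])
  expect_gt(hit_rate, 1.5 * base_rate)
})

test_that("infeasible range configurations are rejected", {
  cfg <- synthetic_world_config(seed = 68, grid = grid_spec(30),
                                n_species = 3,
                                range_size_cells = c(5000, 6000))
  expect_error(generate_world(cfg), "infeasible")
})

test_that("cell-aligned known-coverage worlds are recovered exactly", {
  targets <- c(0, 0.25, 0.5, 0.75, 1, 0, 0.1, 0.9)
  cfg <- synthetic_world_config(seed = 69, grid = grid_spec(6),
                                n_species = length(targets),
                                range_size_cells = c(8, 30), n_regions = 4)
  w <- generate_with_known_coverage(cfg, targets, alignment = "cell")
  pipe <- world_pipeline(w, subset = 4, threshold = 0.5)
  cov <- pipe$coverage[match(w$truth$species_id, pipe$coverage$species_id), ]
  expect_equal(cov$coverage_fraction, w$truth$achieved, tolerance = 1e-12)
  expect_equal(cov$is_gap, w$truth$is_gap)
  # targets 0 and 1 are exactly achievable
  expect_identical(cov$coverage_fraction[w$truth$target == 0],
                   rep(0, sum(w$truth$target == 0)))
  expect_equal(cov$coverage_fraction[w$truth$target == 1],
               rep(1, sum(w$truth$target == 1)), tolerance = 1e-12)
  # quantisation: every achieved value is the nearest reachable one
  expect_true(all(abs(w$truth$achieved - w$truth$target) <= 0.5 + 1e-12))
})

test_that("free-polygon known-coverage worlds hit targets to rasterization accuracy", {
  targets <- c(0.2, 0.37, 0.6, 0.85)
  cfg <- synthetic_world_config(seed = 70, grid = grid_spec(6),
                                n_species = length(targets),
                                range_size_cells = c(8, 30))
  w <- generate_with_known_coverage(cfg, targets, alignment = "free")
  pipe <- world_pipeline(w, subset = 4, threshold = 0.5)
  cov <- pipe$coverage[match(w$truth$species_id, pipe$coverage$species_id), ]
  expect_equal(w$truth$achieved, targets, tolerance = 1e-12)
  expect_equal(cov$coverage_fraction, targets,
               tolerance = rasterization_tolerance())
})
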