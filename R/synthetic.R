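#' Configuration for a synthetic world
#'
#' Bundles every knob of the seeded generator. The defaults describe a
#' scaled-down but structurally faithful world: a mostly oceanic planet with
#' a few continental blocks, a few hundred species whose range-size
#' distribution is heavy-tailed and taxon-dependent (mammals ranging widest,
#' sessile invertebrates narrowest), occurrence probabilities with a
#' preferred core at 1 and linear decay to the range edge, protected areas
#' biased towards the coast with an incomplete IUCN category field, and
#' longitude-banded coastal EEZ strips.
#'
#' @param seed Integer root seed. One root seed drives independent
#'   sub-streams per component (mask, EEZ, species, MPAs), so changing
#'   \code{n_mpas} does not perturb the species draws.
#' @param grid A [grid_spec()]; the default 2-degree grid keeps simulated
#'   worlds fast while preserving the latitude-dependent cell areas that the
#'   arithmetic must respect.
#' @param ocean_fraction Target fraction of cells that are ocean (Earth-like
#'   0.7).
#' @param n_regions Number of EEZ regions (longitude-banded coastal strips).
#' @param n_species Number of species.
#' @param range_size_cells Length-2 log-uniform bounds on range size in
#'   cells, before the per-taxon multiplier.
#' @param core_fraction Fraction of each range at probability 1 (the
#'   preferred core).
#' @param n_mpas Number of protected-area polygons.
#' @param mpa_size_deg Length-2 uniform bounds on MPA edge length, degrees.
#' @param coastal_bias Placement weight multiplier for coastal cells (0 =
#'   uniform over the ocean).
#' @param species_coastal_bias Weight multiplier for seeding species ranges
#'   in coastal cells, emulating the shelf concentration of marine
#'   biodiversity; offshore seeds still occur, producing the open-ocean
#'   species that dominate the poorly-covered tail.
#' @param iucn_mix Named probability vector over categories Ia, Ib, II, III,
#'   IV, V, VI, UNASSIGNED; the default leaves a substantial share
#'   unassigned, as in real registries.
#' @param marine_flag_error_rate Probability that a truly marine protected
#'   area is not flagged 'marine' (and, at half this rate, that the flag is
#'   missing entirely or a land polygon is wrongly flagged).
#' @return A list of class \code{synthetic_world_config}.
#' @export
synthetic_world_config <- function(
    seed = 1,
    grid = grid_spec(2),
    ocean_fraction = 0.7,
    n_regions = 8,
    n_species = 400,
    range_size_cells = c(15, 600),
    core_fraction = 0.3,
    n_mpas = 700,
    mpa_size_deg = c(0.5, 2.5),
    coastal_bias = 4,
    species_coastal_bias = 6,
    iucn_mix = c(Ia = 0.03, Ib = 0.02, II = 0.12, III = 0.05, IV = 0.18,
                 V = 0.15, VI = 0.20, UNASSIGNED = 0.25),
    marine_flag_error_rate = 0.08) {
  stopifnot(ocean_fraction > 0, ocean_fraction <= 1,
            n_regions >= 1, n_species >= 1, n_mpas >= 0,
            core_fraction >= 0, core_fraction <= 1,
            length(range_size_cells) == 2, all(range_size_cells >= 1),
            range_size_cells[1] <= range_size_cells[2],
            length(mpa_size_deg) == 2, mpa_size_deg[1] > 0,
            mpa_size_deg[1] <= mpa_size_deg[2],
            abs(sum(iucn_mix) - 1) < 1e-9, all(iucn_mix >= 0),
            marine_flag_error_rate >= 0, marine_flag_error_rate <= 1)
  structure(as.list(environment()), class = "synthetic_world_config")
}

# taxon pool: sampling weight and range-size multiplier per group
synthetic_taxa <- function() {
  tibble::tibble(
    kingdom = "Animalia",
    phylum = c("Chordata", "Chordata", "Chordata", "Chordata",
               "Mollusca", "Arthropoda", "Cnidaria", "Echinodermata",
               "Porifera"),
    class = c("Actinopterygii", "Chondrichthyes", "Mammalia", "Reptilia",
              "Gastropoda", "Malacostraca", "Anthozoa", "Asteroidea",
              "Demospongiae"),
    weight = c(0.45, 0.06, 0.02, 0.01, 0.16, 0.15, 0.08, 0.05, 0.02),
    range_multiplier = c(1, 2, 8, 3, 0.7, 0.7, 0.5, 0.6, 0.4))
}

# land laid down as random rectangles until the ocean target is reached
gen_ocean_mask <- function(grid, ocean_fraction) {
  mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  target_land <- round((1 - ocean_fraction) * length(mask))
  guard <- 0
  while (sum(!mask) < target_land && guard < 1000) {
    guard <- guard + 1
    h <- sample(seq(3, max(4, grid$n_rows %/% 4)), 1)
    w <- sample(seq(3, max(4, grid$n_cols %/% 5)), 1)
    r0 <- sample(grid$n_rows - h + 1, 1)
    c0 <- sample(grid$n_cols - w + 1, 1)
    mask[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- FALSE
  }
  ocean_mask(grid, mask)
}

# ocean cells within Chebyshev distance `radius` of land
coastal_cells <- function(ocean, radius = 2) {
  land <- !ocean$mask
  near <- matrix(FALSE, nrow(land), ncol(land))
  for (dr in -radius:radius) for (dc in -radius:radius) {
    rs <- seq_len(nrow(land)) + dr
    cs <- seq_len(ncol(land)) + dc
    ok_r <- rs >= 1 & rs <= nrow(land)
    ok_c <- cs >= 1 & cs <= ncol(land)
    near[ok_r, ok_c] <- near[ok_r, ok_c] | land[rs[ok_r], cs[ok_c]]
  }
  near & ocean$mask
}

# EEZ strips: coastal cells partitioned into longitude bands, one region
# each; horizontally adjacent cells are merged into single rectangles
gen_eez <- function(grid, coastal, n_regions) {
  res <- grid$resolution_deg
  cells <- which(coastal, arr.ind = TRUE)
  regions <- sprintf("R%02d", seq_len(n_regions))
  geoms <- vector("list", n_regions)
  map <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  if (nrow(cells) > 0) {
    band_width <- grid$n_cols / n_regions
    reg_idx <- pmin(n_regions, floor((cells[, 2] - 1) / band_width) + 1)
    map[cells] <- regions[reg_idx]
    for (g in seq_len(n_regions)) {
      sub <- cells[reg_idx == g, , drop = FALSE]
      rings <- list()
      for (r in unique(sub[, 1])) {
        cols <- sort(sub[sub[, 1] == r, 2])
        runs <- split(cols, cumsum(c(1, diff(cols) != 1)))
        for (run in runs) {
          b1 <- cell_bounds(r, run[1], grid)
          b2 <- cell_bounds(r, run[length(run)], grid)
          rings[[length(rings) + 1]] <-
            rect_ring(b1$lon_min, b2$lon_max, b1$lat_min, b1$lat_max)
        }
      }
      geoms[[g]] <- rings
    }
  } else {
    geoms <- purrr::map(geoms, ~list())
  }
  list(eez = tibble::tibble(region = regions, geometry = geoms),
       region_map = map)
}

# breadth-first accretion of a contiguous range over ocean cells;
# returns a matrix (row, col, layer) or NULL if the seed pool is empty
grow_range <- function(ocean_ok, n_target, grid, seed_weight = NULL) {
  open <- which(ocean_ok)
  if (length(open) == 0) return(NULL)
  start <- if (is.null(seed_weight)) open[sample.int(length(open), 1)] else
    open[sample.int(length(open), 1, prob = seed_weight[open])]
  nr <- grid$n_rows
  visited <- rep(FALSE, length(ocean_ok))
  cells <- integer(n_target)
  layer <- integer(n_target)
  visited[start] <- TRUE
  cells[1] <- start
  layer[1] <- 0L
  n <- 1L
  frontier <- start
  lev <- 0L
  while (n < n_target && length(frontier) > 0) {
    lev <- lev + 1L
    r <- (frontier - 1L) %% nr + 1L
    cl <- (frontier - 1L) %/% nr + 1L
    nbr <- c(ifelse(r > 1, frontier - 1L, NA),
             ifelse(r < nr, frontier + 1L, NA),
             ifelse(cl > 1, frontier - nr, NA),
             # wrap east-west so ranges can cross the antimeridian column seam
             ifelse(cl < grid$n_cols, frontier + nr, frontier + nr - length(ocean_ok)),
             ifelse(cl > 1, NA, frontier - nr + length(ocean_ok)))
    nbr <- unique(nbr[!is.na(nbr)])
    nbr <- nbr[ocean_ok[nbr] & !visited[nbr]]
    if (length(nbr) == 0) break
    nbr <- nbr[sample.int(length(nbr))]
    take <- min(length(nbr), n_target - n)
    nbr <- nbr[seq_len(take)]
    visited[nbr] <- TRUE
    cells[(n + 1):(n + take)] <- nbr
    layer[(n + 1):(n + take)] <- lev
    n <- n + take
    frontier <- nbr
  }
  cells <- cells[seq_len(n)]
  layer <- layer[seq_len(n)]
  cbind(row = (cells - 1L) %% nr + 1L,
        col = (cells - 1L) %/% nr + 1L,
        layer = layer)
}

# core at probability 1 over ~core_fraction of cells, then linear decay
# with BFS-layer distance, reaching 0 just beyond the outermost layer
layer_probabilities <- function(layer, core_fraction) {
  d_max <- max(layer)
  counts <- cumsum(tabulate(layer + 1L, nbins = d_max + 1L))
  d_core <- which(counts >= core_fraction * length(layer))[1] - 1L
  p <- rep(1, length(layer))
  tail <- layer > d_core
  p[tail] <- 1 - (layer[tail] - d_core) / (d_max - d_core + 1)
  p
}

gen_species <- function(config, ocean, exclude_used = FALSE,
                        core_fraction = config$core_fraction) {
  grid <- config$grid
  seed_weight <- rep(1, length(ocean$mask))
  seed_weight[as.vector(coastal_cells(ocean))] <-
    1 + (config$species_coastal_bias %||% 0)
  taxa <- synthetic_taxa()
  draws <- sample.int(nrow(taxa), config$n_species, replace = TRUE,
                      prob = taxa$weight)
  lo <- log(config$range_size_cells[1])
  hi <- log(config$range_size_cells[2])
  sizes <- round(exp(stats::runif(config$n_species, lo, hi)) *
                   taxa$range_multiplier[draws])
  n_ocean <- sum(ocean$mask)
  if (config$range_size_cells[1] > n_ocean) {
    stop("infeasible config: minimum range size exceeds the ocean (",
         n_ocean, " cells)")
  }
  # taxon scaling can push a draw past the ocean; cap at what fits
  sizes <- pmax(1, pmin(sizes, n_ocean))
  ocean_ok <- as.vector(ocean$mask)
  rows <- vector("list", config$n_species)
  for (i in seq_len(config$n_species)) {
    rng <- grow_range(ocean_ok, sizes[i], grid, seed_weight)
    if (is.null(rng)) break
    if (exclude_used) ocean_ok[(rng[, "col"] - 1L) * grid$n_rows + rng[, "row"]] <- FALSE
    rows[[i]] <- tibble::tibble(
      species_id = sprintf("SP%04d", i),
      kingdom = taxa$kingdom[draws[i]],
      phylum = taxa$phylum[draws[i]],
      class = taxa$class[draws[i]],
      row = as.integer(rng[, "row"]), col = as.integer(rng[, "col"]),
      probability = layer_probabilities(rng[, "layer"], core_fraction))
  }
  maps <- dplyr::bind_rows(rows)
  attr(maps, "grid") <- grid
  class(maps) <- c("species_maps", class(maps))
  maps
}

gen_mpas <- function(config, ocean, coastal) {
  grid <- config$grid
  res <- grid$resolution_deg
  if (config$n_mpas == 0) {
    return(mpa_records(tibble::tibble(
      pa_id = character(), geometry = list(),
      marine_flag = logical(), iucn_category = character(),
      name = character())))
  }
  weight <- matrix(0, grid$n_rows, grid$n_cols)
  weight[ocean$mask] <- 1
  weight[coastal] <- 1 + config$coastal_bias
  # a slice of terrestrial polygons exercises the marine-vs-not predicates
  if (any(!ocean$mask)) weight[!ocean$mask] <- 0.2
  cells <- sample.int(length(weight), config$n_mpas, replace = TRUE,
                      prob = as.vector(weight))
  r <- (cells - 1L) %% grid$n_rows + 1L
  cl <- (cells - 1L) %/% grid$n_rows + 1L
  ctr <- cell_center(r, cl, grid)
  jitter_lon <- stats::runif(config$n_mpas, -res / 2, res / 2)
  jitter_lat <- stats::runif(config$n_mpas, -res / 2, res / 2)
  w <- stats::runif(config$n_mpas, config$mpa_size_deg[1], config$mpa_size_deg[2])
  h <- stats::runif(config$n_mpas, config$mpa_size_deg[1], config$mpa_size_deg[2])
  lon0 <- pmax(-180, pmin(180 - 1e-6, ctr$center_lon + jitter_lon - w / 2))
  lon1 <- pmin(180, lon0 + w)
  lat0 <- pmax(-90, pmin(90 - 1e-6, ctr$center_lat + jitter_lat - h / 2))
  lat1 <- pmin(90, lat0 + h)
  geoms <- purrr::map(seq_len(config$n_mpas),
                      ~list(rect_ring(lon0[.x], lon1[.x], lat0[.x], lat1[.x])))
  iucn <- sample(names(config$iucn_mix), config$n_mpas, replace = TRUE,
                 prob = config$iucn_mix)
  truly_marine <- purrr::map_lgl(geoms, geometry_overlaps_ocean, ocean = ocean)
  u <- stats::runif(config$n_mpas)
  err <- config$marine_flag_error_rate
  flag <- truly_marine
  flag[truly_marine & u < err] <- FALSE
  flag[!truly_marine & u < err / 2] <- TRUE
  flag[u >= err & u < err + err / 2] <- NA
  mpa_records(tibble::tibble(
    pa_id = sprintf("PA%04d", seq_len(config$n_mpas)),
    name = sprintf("Synthetic MPA %d", seq_len(config$n_mpas)),
    marine_flag = flag,
    iucn_category = iucn,
    geometry = geoms))
}

#' Generate a seeded synthetic world
#'
#' Produces a complete, internally consistent input set for the gap-analysis
#' pipeline: an ocean mask with continental blocks, species probability maps
#' grown by seeded breadth-first accretion (a contiguous preferred core at
#' probability 1, probability decaying linearly with accretion-layer distance
#' to 0 at the range edge, confined to ocean cells), rectangular MPA polygons
#' placed with a coastal bias and carrying WDPA-style imperfect attributes
#' (an IUCN mix with a large unassigned share; a sometimes-wrong or missing
#' marine flag), and longitude-banded coastal EEZ polygons.
#'
#' Identical \code{config} (including seed) yields an identical world; each
#' component draws from its own RNG sub-stream.
#'
#' @param config A [synthetic_world_config()].
#' @return A list of class \code{synthetic_world}: \code{grid}, \code{ocean},
#'   \code{maps}, \code{mpas}, \code{eez}, \code{region_map} (per-cell EEZ
#'   region or NA), \code{truth} (NULL; see
#'   [generate_with_known_coverage()]), \code{config}.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synthetic_world_config"))
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1, 4))
  ocean <- withr::with_seed(seeds[1], gen_ocean_mask(config$grid, config$ocean_fraction))
  coastal <- coastal_cells(ocean)
  ez <- withr::with_seed(seeds[2], gen_eez(config$grid, coastal, config$n_regions))
  maps <- withr::with_seed(seeds[3], gen_species(config, ocean))
  mpas <- withr::with_seed(seeds[4], gen_mpas(config, ocean, coastal))
  structure(list(grid = config$grid, ocean = ocean, maps = maps, mpas = mpas,
                 eez = ez$eez, region_map = ez$region_map, truth = NULL,
                 config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> seed %s: %d species, %d MPAs, %d EEZ regions, %.0f%% ocean\n",
    format(x$config$seed), length(unique(x$maps$species_id)), nrow(x$mpas),
    nrow(x$eez), 100 * mean(x$ocean$mask)))
  invisible(x)
}

#' Generate a world with analytically known coverage
#'
#' A recovery harness: species ranges are grown disjointly (no two species
#' share a cell) with every in-range probability equal to 1, and each
#' species' protected area is assembled inside its own range so that the
#' true area-weighted coverage is known by construction:
#' \itemize{
#'   \item \code{alignment = "cell"}: the MPA is a union of whole grid
#'     cells; the achievable coverages are quantised by cell areas, and the
#'     nearest achievable value to each target is used and recorded;
#'   \item \code{alignment = "free"}: whole cells plus one partial cell
#'     whose longitudinal width is solved so the truth equals the target
#'     exactly (spherical area is linear in longitude width), exercising
#'     genuine partial-cell rasterization.
#' }
#' All constructed MPAs are marine-flagged and IUCN category II, so every
#' subset retains them and the full pipeline (any subset, any threshold in
#' (0, 1\]) must recover \code{truth$achieved}.
#'
#' @param config A [synthetic_world_config()]; \code{n_species} is overridden
#'   by \code{length(target_coverages)} and \code{core_fraction} by 1.
#' @param target_coverages Numeric vector of per-species target coverage
#'   fractions in \[0, 1\].
#' @param alignment \code{"cell"} or \code{"free"}.
#' @return A \code{synthetic_world} whose \code{truth} is a tibble with
#'   \code{species_id}, \code{target}, \code{achieved}, \code{is_gap}, and
#'   \code{regions} (list column: EEZ regions touched by gap species'
#'   ranges, from the generator's own cell-region map).
#' @export
generate_with_known_coverage <- function(config, target_coverages,
                                         alignment = c("cell", "free")) {
  stopifnot(inherits(config, "synthetic_world_config"),
            all(target_coverages >= 0), all(target_coverages <= 1))
  alignment <- match.arg(alignment)
  config$n_species <- length(target_coverages)
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1, 4))
  ocean <- withr::with_seed(seeds[1], gen_ocean_mask(config$grid, config$ocean_fraction))
  coastal <- coastal_cells(ocean)
  ez <- withr::with_seed(seeds[2], gen_eez(config$grid, coastal, config$n_regions))
  maps <- withr::with_seed(seeds[3],
                           gen_species(config, ocean, exclude_used = TRUE,
                                       core_fraction = 1))
  grid <- config$grid
  band <- cell_area_field(grid)$band_km2
  ids <- unique(maps$species_id)
  stopifnot(length(ids) == length(target_coverages))

  build_one <- function(i) {
    sp <- maps[maps$species_id == ids[i], ]
    a <- band[sp$row]
    total <- sum(a)
    want <- target_coverages[i] * total
    cum <- cumsum(a)
    rings <- list()
    if (alignment == "cell") {
      k <- which.min(abs(c(0, cum) - want)) - 1L
      achieved <- if (k == 0) 0 else cum[k] / total
    } else {
      k <- sum(cum <= want + 1e-9)
      achieved <- target_coverages[i]
      rem <- want - (if (k == 0) 0 else cum[k])
      if (rem > 1e-9 && k < nrow(sp)) {
        b <- cell_bounds(sp$row[k + 1], sp$col[k + 1], grid)
        fwidth <- rem / band[sp$row[k + 1]] * grid$resolution_deg
        rings[[1]] <- rect_ring(b$lon_min, b$lon_min + fwidth,
                                b$lat_min, b$lat_max)
      }
    }
    if (k > 0) {
      for (j in seq_len(k)) {
        b <- cell_bounds(sp$row[j], sp$col[j], grid)
        rings[[length(rings) + 1]] <-
          rect_ring(b$lon_min, b$lon_max, b$lat_min, b$lat_max)
      }
    }
    list(rings = rings, achieved = achieved)
  }
  built <- purrr::map(seq_along(ids), build_one)
  has_geom <- lengths(purrr::map(built, "rings")) > 0
  mpas <- mpa_records(tibble::tibble(
    pa_id = sprintf("KC%04d", seq_along(ids))[has_geom],
    name = paste0("Known-coverage MPA for ", ids)[has_geom],
    marine_flag = TRUE,
    iucn_category = "II",
    geometry = purrr::map(built, "rings")[has_geom]))
  achieved <- purrr::map_dbl(built, "achieved")
  gap <- achieved == 0
  regions <- purrr::map(seq_along(ids), function(i) {
    if (!gap[i]) return(character(0))
    sp <- maps[maps$species_id == ids[i], ]
    sort(unique(stats::na.omit(ez$region_map[cbind(sp$row, sp$col)])))
  })
  truth <- tibble::tibble(species_id = ids, target = target_coverages,
                          achieved = achieved, is_gap = gap,
                          regions = regions)
  structure(list(grid = grid, ocean = ocean, maps = maps, mpas = mpas,
                 eez = ez$eez, region_map = ez$region_map, truth = truth,
                 config = config),
            class = "synthetic_world")
}
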