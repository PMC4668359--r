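#' @name polygon-geometry
#' @title Polygon primitives on the sphere
#'
#' @description
#' Polygons are plain numeric matrices with two columns (\code{lon},
#' \code{lat}, degrees, WGS84) holding one ring; the closing vertex may be
#' omitted. A multipolygon is a list of rings. Edges are straight lines in
#' longitude-latitude space (the convention of gridded conservation datasets,
#' where polygons are stored and overlaid in geographic coordinates).
#'
#' Under that convention the spherical area of a region is
#' \code{R^2 * integral of cos(lat) dlat dlon}, which Green's theorem turns
#' into a sum of exact closed-form terms over edges: for an edge with latitude
#' linear in longitude, \code{integral of sin(lat(lon)) dlon} has the
#' antiderivative \code{(cos(lat1) - cos(lat2)) / slope}. No quadrature is
#' involved; areas are exact to floating point.
#'
#' Overlapping rings are handled by a vertical-slab scanline: slab boundaries
#' are placed at every vertex longitude and every pairwise edge crossing, so
#' that within a slab the covered latitude intervals have a fixed structure
#' and the union integrates edge-by-edge. The even-odd rule makes the result
#' well-defined even for self-intersecting ("bowtie") rings, which is how
#' invalid real-world protected-area geometries are tolerated without a
#' repair engine.
NULL

DEG2RAD <- pi / 180

#' Build a rectangular ring
#'
#' @param lon_min,lon_max,lat_min,lat_max Bounds in degrees.
#' @return A 4x2 matrix ring (counter-clockwise).
#' @export
rect_ring <- function(lon_min, lon_max, lat_min, lat_max) {
  stopifnot(lon_max > lon_min, lat_max > lat_min)
  cbind(lon = c(lon_min, lon_max, lon_max, lon_min),
        lat = c(lat_min, lat_min, lat_max, lat_max))
}

# drop consecutive duplicate vertices and an explicit closing vertex;
# returns NULL when fewer than 3 distinct vertices remain
clean_ring <- function(ring) {
  if (is.null(ring) || nrow(ring) < 3) return(NULL)
  n <- nrow(ring)
  if (n > 1 && all(abs(ring[1, ] - ring[n, ]) < 1e-12)) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) return(NULL)
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 1e-12)
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) < 3) return(NULL)
  ring
}

#' Spherical area of a single ring (signed by orientation, returned absolute)
#'
#' Exact closed-form area of a lon-lat straight-edged ring on the sphere via
#' the Green's-theorem edge sum. Self-intersecting rings get the net signed
#' area of their winding; use [rings_union_area_km2()] for even-odd semantics.
#'
#' @param ring Two-column (lon, lat) matrix, degrees.
#' @param radius_km Sphere radius, km.
#' @return Area in km^2.
#' @export
ring_area_km2 <- function(ring, radius_km = 6371) {
  ring <- clean_ring(ring)
  if (is.null(ring)) return(0)
  lam <- ring[, 1] * DEG2RAD
  phi <- ring[, 2] * DEG2RAD
  lam2 <- c(lam[-1], lam[1])
  phi2 <- c(phi[-1], phi[1])
  dphi <- phi2 - phi
  # integral of sin(phi) dlam along each edge, phi linear in lam
  flat <- abs(dphi) < 1e-12
  term <- numeric(length(lam))
  term[flat] <- (lam2[flat] - lam[flat]) * sin((phi[flat] + phi2[flat]) / 2)
  nf <- !flat
  term[nf] <- (lam2[nf] - lam[nf]) * (cos(phi[nf]) - cos(phi2[nf])) / dphi[nf]
  abs(radius_km^2 * sum(term))
}

#' Clip a ring to a longitude-latitude rectangle
#'
#' Sutherland-Hodgman clipping against the four half-planes of the rectangle.
#' Works in lon-lat coordinates, matching the straight-edge convention.
#'
#' @param ring Two-column (lon, lat) matrix.
#' @param lon_min,lon_max,lat_min,lat_max Clip rectangle, degrees.
#' @return Clipped ring matrix, or \code{NULL} if the intersection is empty.
#' @export
clip_ring_rect <- function(ring, lon_min, lon_max, lat_min, lat_max) {
  ring <- clean_ring(ring)
  if (is.null(ring)) return(NULL)
  clip_half <- function(pts, coord, bound, keep_ge) {
    if (is.null(pts) || nrow(pts) == 0) return(NULL)
    n <- nrow(pts)
    vals <- pts[, coord]
    inside <- if (keep_ge) vals >= bound else vals <= bound
    out <- vector("list", 2L * n)
    k <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      pi_ <- pts[i, ]; pj <- pts[j, ]
      if (inside[i]) { k <- k + 1L; out[[k]] <- pi_ }
      if (inside[i] != inside[j]) {
        t <- (bound - vals[i]) / (vals[j] - vals[i])
        k <- k + 1L
        out[[k]] <- pi_ + t * (pj - pi_)
      }
    }
    if (k < 3L) return(NULL)
    do.call(rbind, out[seq_len(k)])
  }
  ring <- clip_half(ring, 1L, lon_min, TRUE)
  ring <- clip_half(ring, 1L, lon_max, FALSE)
  ring <- clip_half(ring, 2L, lat_min, TRUE)
  ring <- clip_half(ring, 2L, lat_max, FALSE)
  clean_ring(ring)
}

# longitudes where two segments cross strictly in their interiors
segment_crossings_x <- function(edges) {
  n <- nrow(edges)
  if (n < 2) return(numeric(0))
  xs <- numeric(0)
  for (i in seq_len(n - 1)) {
    x1 <- edges[i, 1]; y1 <- edges[i, 2]; x2 <- edges[i, 3]; y2 <- edges[i, 4]
    for (j in seq((i + 1), n)) {
      x3 <- edges[j, 1]; y3 <- edges[j, 2]; x4 <- edges[j, 3]; y4 <- edges[j, 4]
      den <- (x2 - x1) * (y4 - y3) - (y2 - y1) * (x4 - x3)
      if (abs(den) < 1e-300) next
      t <- ((x3 - x1) * (y4 - y3) - (y3 - y1) * (x4 - x3)) / den
      u <- ((x3 - x1) * (y2 - y1) - (y3 - y1) * (x2 - x1)) / den
      if (t > 0 && t < 1 && u > 0 && u < 1) xs <- c(xs, x1 + t * (x2 - x1))
    }
  }
  xs
}

# integral of sin(lat(lon)) dlon (radians) for one edge restricted to [xa, xb]
edge_sin_integral <- function(edge, xa, xb) {
  x1 <- edge[1]; y1 <- edge[2]; x2 <- edge[3]; y2 <- edge[4]
  ya <- y1 + (y2 - y1) * (xa - x1) / (x2 - x1)
  yb <- y1 + (y2 - y1) * (xb - x1) / (x2 - x1)
  la <- xa * DEG2RAD; lb <- xb * DEG2RAD
  pa <- ya * DEG2RAD; pb <- yb * DEG2RAD
  if (abs(pb - pa) < 1e-12) {
    (lb - la) * sin((pa + pb) / 2)
  } else {
    (lb - la) * (cos(pa) - cos(pb)) / (pb - pa)
  }
}

#' Spherical area of the union of rings (even-odd rule)
#'
#' Computes the area covered by at least one ring, counting overlaps once —
#' the "dissolve" semantics that prevent double counting where protected-area
#' designations overlap. Exact (closed-form edge integrals); robust to
#' self-intersections via the even-odd rule.
#'
#' @param rings List of two-column (lon, lat) matrices.
#' @param radius_km Sphere radius, km.
#' @return Area in km^2.
#' @export
rings_union_area_km2 <- function(rings, radius_km = 6371) {
  rings <- purrr::compact(purrr::map(rings, clean_ring))
  if (length(rings) == 0) return(0)
  # edge table: x1 y1 x2 y2 ring_id, vertical edges dropped (no x-extent)
  edge_list <- purrr::imap(rings, function(r, id) {
    nxt <- rbind(r[-1, , drop = FALSE], r[1, , drop = FALSE])
    e <- cbind(r[, 1], r[, 2], nxt[, 1], nxt[, 2], id)
    e[abs(e[, 1] - e[, 3]) > 1e-14, , drop = FALSE]
  })
  edges <- do.call(rbind, edge_list)
  if (is.null(edges) || nrow(edges) == 0) return(0)
  brk <- sort(unique(c(edges[, 1], edges[, 3], segment_crossings_x(edges))))
  if (length(brk) < 2) return(0)
  total <- 0
  for (s in seq_len(length(brk) - 1)) {
    xa <- brk[s]; xb <- brk[s + 1]
    if (xb - xa <= 0) next
    xm <- (xa + xb) / 2
    lo1 <- pmin(edges[, 1], edges[, 3])
    hi1 <- pmax(edges[, 1], edges[, 3])
    act <- which(lo1 <= xm & hi1 > xm & !(lo1 == xm & hi1 == xm))
    if (length(act) < 2) next
    # per ring: crossing latitudes at xm, paired even-odd into intervals
    iv <- list()
    for (id in unique(edges[act, 5])) {
      ei <- act[edges[act, 5] == id]
      ym <- edges[ei, 2] +
        (edges[ei, 4] - edges[ei, 2]) * (xm - edges[ei, 1]) / (edges[ei, 3] - edges[ei, 1])
      ord <- order(ym)
      ei <- ei[ord]; ym <- ym[ord]
      np <- (length(ei) %/% 2) * 2
      if (np < 2) next
      for (k in seq(1, np, by = 2)) {
        iv[[length(iv) + 1]] <- c(ym[k], ym[k + 1], ei[k], ei[k + 1])
      }
    }
    if (length(iv) == 0) next
    m <- do.call(rbind, iv)
    m <- m[order(m[, 1]), , drop = FALSE]
    # merge overlapping intervals; integrate each merged piece's boundary edges
    cur_lo <- m[1, 1]; cur_hi <- m[1, 2]
    e_lo <- m[1, 3]; e_hi <- m[1, 4]
    flush <- function() {
      total <<- total +
        radius_km^2 * (edge_sin_integral(edges[e_hi, ], xa, xb) -
                       edge_sin_integral(edges[e_lo, ], xa, xb))
    }
    if (nrow(m) > 1) {
      for (k in seq(2, nrow(m))) {
        if (m[k, 1] <= cur_hi + 1e-12) {
          if (m[k, 2] > cur_hi) { cur_hi <- m[k, 2]; e_hi <- m[k, 4] }
        } else {
          flush()
          cur_lo <- m[k, 1]; cur_hi <- m[k, 2]
          e_lo <- m[k, 3]; e_hi <- m[k, 4]
        }
      }
    }
    flush()
  }
  unname(total)
}

#' Even-odd point-in-polygon test
#'
#' @param lon,lat Point coordinates (vectorised), degrees.
#' @param rings List of rings (a multipolygon); a point inside an odd number
#'   of rings is "inside".
#' @return Logical vector.
#' @export
point_in_rings <- function(lon, lat, rings) {
  rings <- purrr::compact(purrr::map(rings, clean_ring))
  inside <- rep(FALSE, length(lon))
  for (r in rings) {
    x1 <- r[, 1]; y1 <- r[, 2]
    x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
    for (p in seq_along(lon)) {
      crosses <- (y1 > lat[p]) != (y2 > lat[p])
      if (!any(crosses)) next
      xint <- x1[crosses] + (lat[p] - y1[crosses]) /
        (y2[crosses] - y1[crosses]) * (x2[crosses] - x1[crosses])
      if (sum(xint > lon[p]) %% 2 == 1) inside[p] <- !inside[p]
    }
  }
  inside
}

#' Split geometry at the antimeridian
#'
#' Rings supplied with longitudes outside \[-180, 180\] (the usual "unwrapped"
#' encoding of dateline-crossing polygons) are cut into pieces that lie inside
#' the standard range, shifting by 360 degrees as needed. Rings already inside
#' the range pass through untouched.
#'
#' @param rings List of (lon, lat) matrices.
#' @return List of rings, all with longitudes in \[-180, 180\].
#' @export
split_antimeridian <- function(rings) {
  out <- list()
  for (r in rings) {
    r <- clean_ring(r)
    if (is.null(r)) next
    if (all(r[, 1] >= -180 & r[, 1] <= 180)) {
      out[[length(out) + 1]] <- r
      next
    }
    for (shift in c(-360, 0, 360)) {
      shifted <- r
      shifted[, 1] <- shifted[, 1] + shift
      piece <- clip_ring_rect(shifted, -180, 180, -90, 90)
      if (!is.null(piece) && ring_area_km2(piece, 1) > 1e-15) {
        out[[length(out) + 1]] <- piece
      }
    }
  }
  out
}

# bounding box over a list of rings: c(lon_min, lon_max, lat_min, lat_max)
rings_bbox <- function(rings) {
  lon <- unlist(lapply(rings, function(r) r[, 1]))
  lat <- unlist(lapply(rings, function(r) r[, 2]))
  c(min(lon), max(lon), min(lat), max(lat))
}
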