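EARTH_RADIUS_KM <- 6371

#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth of radius 6371 km, the radius used
#' throughout the package for buffers and geodesic discs.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees (vectorised, recycled).
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' haversine_km(0, 0, 1, 0) # ~111.2 km along the equator
haversine_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  # geosphere expects signed longitudes; haversine is convention-invariant
  p1 <- cbind(signed_lon(rep_len(lon1, n)), rep_len(lat1, n))
  p2 <- cbind(signed_lon(rep_len(lon2, n)), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM)
}

#' Cells within a geodesic radius of a point set
#'
#' Marks every grid cell whose center lies within `radius_km` great-circle
#' kilometres of at least one input point. This is the buffering primitive
#' behind the 100 km reef mask dilation, the 500 km fallback ranges of
#' data-poor species, and the 2,500 km range constraint.
#'
#' @param points Data frame with columns `lon`, `lat` (degrees).
#' @param radius_km Buffer radius in km, > 0.
#' @param grid An `env_grid` supplying the lattice.
#' @return Logical matrix on the grid lattice.
#' @export
geodesic_buffer_cells <- function(points, radius_km, grid) {
  if (!is.numeric(radius_km) || length(radius_km) != 1L || radius_km <= 0) {
    abort("`radius_km` must be a single positive number.")
  }
  nr <- length(grid$lat_centers)
  nc <- length(grid$lon_centers)
  out <- matrix(FALSE, nr, nc)
  if (nrow(points) == 0L) return(out)
  lon <- recenter_lon(points$lon)
  lat <- points$lat
  km_per_deg <- pi * EARTH_RADIUS_KM / 180
  dlat <- radius_km / km_per_deg
  cs <- grid$cell_size
  for (p in seq_along(lon)) {
    ii <- which(abs(grid$lat_centers - lat[p]) <= dlat + cs)
    if (length(ii) == 0L) next
    cos_min <- min(cos(grid$lat_centers[ii] * pi / 180))
    dlon <- if (cos_min <= 1e-9) 180 else min(180, radius_km / (km_per_deg * cos_min) + cs)
    dl <- abs(grid$lon_centers - lon[p])
    jj <- which(pmin(dl, 360 - dl) <= dlon)
    if (length(jj) == 0L) next
    cand <- expand.grid(i = ii, j = jj)
    d <- haversine_km(lon[p], lat[p],
                      grid$lon_centers[cand$j], grid$lat_centers[cand$i])
    hit <- cand[d <= radius_km, , drop = FALSE]
    out[cbind(hit$i, hit$j)] <- TRUE
  }
  out
}

#' Minimum convex polygon of occurrence records
#'
#' Planar convex hull of a species' records in recentered (`[0, 360)`)
#' longitude/latitude space, so ranges straddling the antimeridian stay
#' contiguous. The vertex ring is returned counter-clockwise.
#'
#' Species with fewer than three distinct records, or with all records
#' collinear, cannot form a polygon; such inputs raise a condition of class
#' `"richstack_fallback"` that range assembly catches to route the species to
#' the geodesic buffer fallback.
#'
#' @param records Data frame with columns `lon`, `lat`.
#' @param species_id Optional identifier stored on the polygon.
#' @return An object of class `range_polygon`: list with `species_id` and a
#'   `vertices` tibble (`lon`, `lat`, counter-clockwise, no repeated closing
#'   vertex).
#' @export
mcp_hull <- function(records, species_id = NA_character_) {
  pts <- distinct(tibble(lon = recenter_lon(records$lon), lat = records$lat))
  if (nrow(pts) < 3L) {
    abort(sprintf("species '%s': %d distinct record(s); a convex polygon needs 3",
                  species_id, nrow(pts)),
          class = "richstack_fallback")
  }
  h <- grDevices::chull(pts$lon, pts$lat)
  if (length(h) < 3L) {
    abort(sprintf("species '%s': records are collinear; no convex polygon",
                  species_id),
          class = "richstack_fallback")
  }
  v <- pts[h, ]
  if (ring_signed_area(v$lon, v$lat) < 0) v <- v[rev(seq_len(nrow(v))), ]
  structure(list(species_id = species_id, vertices = v),
            class = "range_polygon")
}

ring_signed_area <- function(x, y) {
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("<range_polygon> species '%s', %d vertices, area %.3f deg^2\n",
              x$species_id, nrow(x$vertices),
              ring_signed_area(x$vertices$lon, x$vertices$lat)))
  invisible(x)
}

# Even-odd point-in-polygon with boundary counted as inside. Vectorised over
# points; the edge loop is over the (few) polygon vertices.
points_in_ring <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(px)
  inside <- logical(n)
  boundary <- logical(n)
  k <- length(vx)
  for (e in seq_len(k)) {
    x1 <- vx[e]; y1 <- vy[e]
    x2 <- vx[if (e == k) 1L else e + 1L]
    y2 <- vy[if (e == k) 1L else e + 1L]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    # boundary test: zero cross product and within the edge's bounding box
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    scale <- max(abs(c(x1, y1, x2, y2, 1)))
    onseg <- abs(cr) <= eps * scale &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    boundary <- boundary | onseg
  }
  inside | boundary
}

#' Rasterize a range polygon onto the grid
#'
#' A cell is marked present when its center lies inside or on the polygon
#' (even-odd rule, boundary-inclusive), making richness counts reproducible
#' bit-exactly across runs and platforms.
#'
#' @param poly A `range_polygon`.
#' @param grid An `env_grid`.
#' @return Logical matrix on the grid lattice.
#' @export
rasterize_polygon <- function(poly, grid) {
  v <- poly$vertices
  nr <- length(grid$lat_centers)
  nc <- length(grid$lon_centers)
  out <- matrix(FALSE, nr, nc)
  cs <- grid$cell_size
  ii <- which(grid$lat_centers >= min(v$lat) - cs & grid$lat_centers <= max(v$lat) + cs)
  jj <- which(grid$lon_centers >= min(v$lon) - cs & grid$lon_centers <= max(v$lon) + cs)
  if (length(ii) == 0L || length(jj) == 0L) return(out)
  cand <- expand.grid(i = ii, j = jj)
  hit <- points_in_ring(grid$lon_centers[cand$j], grid$lat_centers[cand$i],
                        v$lon, v$lat)
  out[cbind(cand$i[hit], cand$j[hit])] <- TRUE
  out
}
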