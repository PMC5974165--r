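REEF_LAT_LIMIT <- 40  # reef habitat restricted to warm waters, |lat| <= 40 deg

# Low-frequency random surface: white noise on a coarse knot lattice,
# bilinearly interpolated to the grid and standardised. Consumes the current
# RNG stream (callers control the seed).
smooth_field <- function(lat_centers, lon_centers, knot_deg = 6) {
  pad <- knot_deg
  kx <- seq(min(lon_centers) - pad, max(lon_centers) + pad, by = knot_deg)
  ky <- seq(min(lat_centers) - pad, max(lat_centers) + pad, by = knot_deg)
  Z <- matrix(rnorm(length(ky) * length(kx)), length(ky), length(kx))
  nr <- length(lat_centers)
  nc <- length(lon_centers)
  xp <- rep(lon_centers, each = nr)
  yp <- rep(lat_centers, times = nc)
  v <- pracma::interp2(kx, ky, Z, xp, yp, method = "linear")
  m <- matrix(v, nr, nc)
  (m - mean(m)) / sd(as.vector(m))
}

#' Generate a synthetic environmental raster stack
#'
#' Builds smooth, spatially autocorrelated environmental layers on a regular
#' latitude/longitude grid, mimicking the structure of marine climatology
#' stacks: variables come in correlated families (temperature, productivity,
#' nutrients, radiation, ...) driven by shared latent surfaces, and the
#' temperature-like first layer carries a latitudinal gradient. The family
#' structure makes principal-component reduction of the stack meaningful. A
#' smooth land field carves out invalid (non-marine) cells.
#'
#' @param extent Numeric `c(lon_min, lon_max, lat_min, lat_max)` in degrees;
#'   longitudes in the recentered `[0, 360]` convention.
#' @param cell_size Cell size in degrees; must divide the extent evenly.
#' @param n_layers Number of environmental layers (>= 2).
#' @param correlation Target pairwise correlation within a variable family,
#'   in `[0, 1)`. Families are driven by `n_factors` independent latent
#'   surfaces; correlation across families is near zero.
#' @param n_factors Number of latent family surfaces.
#' @param land_fraction Fraction of cells carved out as land.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param layer_names Optional layer names (defaults mimic marine
#'   climatology variable families).
#' @return An [env_grid].
#' @export
generate_env_grid <- function(extent = c(40, 260, -34, 33), cell_size = 0.5,
                              n_layers = 7, correlation = 0.7, n_factors = 4,
                              land_fraction = 0.15, seed = 1L,
                              layer_names = NULL) {
  if (n_layers < 2L) abort("`n_layers` must be >= 2.")
  if (correlation < 0 || correlation >= 1) abort("`correlation` must lie in [0, 1).")
  lon_span <- extent[2] - extent[1]
  lat_span <- extent[4] - extent[3]
  if (lon_span <= 0 || lat_span <= 0) {
    abort("degenerate extent: zero cells.")
  }
  nx <- lon_span / cell_size
  ny <- lat_span / cell_size
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8) {
    abort("`cell_size` must divide the extent evenly.")
  }
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  if (nx < 1L || ny < 1L) abort("degenerate extent: zero cells.")
  lon_centers <- recenter_lon(extent[1] + (seq_len(nx) - 0.5) * cell_size)
  lat_centers <- extent[3] + (seq_len(ny) - 0.5) * cell_size

  default_names <- c("sst_mean", "sst_range", "chlo_mean", "attenuation",
                     "nitrate", "par_mean", "cloud_mean", "dissox", "salinity",
                     "phosphate", "silicate", "calcite", "ph")
  layer_names <- layer_names %||%
    make.unique(rep_len(default_names, n_layers), sep = "_")
  if (length(layer_names) != n_layers) abort("`layer_names` length must equal `n_layers`.")

  set.seed(as.integer(seed))
  factors <- lapply(seq_len(n_factors), function(k)
    smooth_field(lat_centers, lon_centers))
  trend <- matrix(rep(-abs(lat_centers), nx), ny, nx)
  trend <- (trend - mean(trend)) / sd(as.vector(trend))
  r_shared <- sqrt(correlation)
  r_own <- sqrt(1 - correlation)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    g <- ((l - 1L) %% n_factors) + 1L
    own <- smooth_field(lat_centers, lon_centers)
    lay <- r_shared * factors[[g]] + r_own * own
    if (l == 1L) lay <- lay + trend  # temperature-like layer tracks latitude
    layers[[l]] <- (lay - mean(lay)) / sd(as.vector(lay))
  }
  names(layers) <- layer_names
  land <- smooth_field(lat_centers, lon_centers)
  valid <- land <= quantile(as.vector(land), 1 - land_fraction)
  env_grid(layers, lat_centers, lon_centers, cell_size, valid)
}

#' Generate a clustered synthetic reef mask
#'
#' Marks roughly `coverage` of the marine cells as reef habitat. Reef cells
#' are clustered (top quantile of a smooth random surface, not independent
#' noise) and restricted to warm-water latitudes (`|lat| <= 40` degrees).
#' For a fixed seed the reef set is nested: lowering `coverage` always yields
#' a subset.
#'
#' @param grid An [env_grid].
#' @param coverage Target reef fraction of marine cells, in (0, 1).
#' @param seed Integer seed.
#' @return An object of class `reef_mask`: list with logical `mask`,
#'   `buffered` flag, and the lattice coordinates.
#' @export
generate_reef_mask <- function(grid, coverage = 0.08, seed = 1L) {
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage <= 0 || coverage >= 1) {
    abort("`coverage` must lie strictly within (0, 1).")
  }
  set.seed(as.integer(seed))
  field <- smooth_field(grid$lat_centers, grid$lon_centers)
  lat_ok <- abs(grid$lat_centers) <= REEF_LAT_LIMIT
  eligible <- grid$valid_mask & matrix(rep(lat_ok, length(grid$lon_centers)),
                                       length(grid$lat_centers))
  n_marine <- sum(grid$valid_mask)
  k <- min(round(coverage * n_marine), sum(eligible))
  mask <- matrix(FALSE, nrow(field), ncol(field))
  if (k > 0) {
    idx <- which(eligible)
    top <- idx[order(field[idx], decreasing = TRUE)[seq_len(k)]]
    mask[top] <- TRUE
  }
  structure(list(mask = mask, buffered = FALSE,
                 lat_centers = grid$lat_centers,
                 lon_centers = grid$lon_centers),
            class = "reef_mask")
}

#' @export
print.reef_mask <- function(x, ...) {
  cat(sprintf("<reef_mask> %d reef cell(s)%s\n", sum(x$mask),
              if (x$buffered) ", buffered" else ""))
  invisible(x)
}

#' Dilate a reef mask by a geodesic radius
#'
#' Expands the reef habitat mask by `radius_km` great-circle kilometres
#' (default 100 km) and intersects it with the marine mask; the result is the
#' analysis mask that every range estimate is constrained to.
#'
#' @param reef A `reef_mask`.
#' @param grid The [env_grid] it lives on.
#' @param radius_km Buffer radius in km.
#' @return A `reef_mask` with `buffered = TRUE`.
#' @export
buffer_reef_mask <- function(reef, grid, radius_km = 100) {
  pts <- cell_centers(grid, which(reef$mask))
  m <- geodesic_buffer_cells(pts, radius_km, grid) & grid$valid_mask
  structure(list(mask = m, buffered = TRUE,
                 lat_centers = grid$lat_centers,
                 lon_centers = grid$lon_centers),
            class = "reef_mask")
}

#' Specify a ground-truth Gaussian niche
#'
#' The synthetic truth for one species: suitability at a cell is
#' `max_suitability * exp(-0.5 * sum(((x - optimum) / tolerance)^2))` over the
#' environmental layers, optionally clipped to a geodesic disc for species
#' with limited distribution ranges.
#'
#' @param species_id Identifier.
#' @param optima Named numeric vector, one optimum per environmental layer.
#' @param tolerances Named positive numeric vector (Gaussian niche widths);
#'   `Inf` gives a flat (uninformative) axis.
#' @param max_suitability Peak suitability in (0, 1].
#' @param range_limit_km Optional positive radius restricting the species to
#'   a geodesic disc around `range_center`.
#' @param range_center Named `c(lon, lat)` center of the disc (required when
#'   `range_limit_km` is set).
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(species_id, optima, tolerances, max_suitability = 1,
                       range_limit_km = NULL, range_center = NULL) {
  if (any(tolerances <= 0)) abort("`tolerances` must be positive.")
  if (max_suitability <= 0 || max_suitability > 1) {
    abort("`max_suitability` must lie in (0, 1].")
  }
  if (!is.null(range_limit_km)) {
    if (range_limit_km <= 0) abort("`range_limit_km` must be positive.")
    if (is.null(range_center)) abort("`range_center` is required with `range_limit_km`.")
  }
  structure(list(species_id = species_id, optima = optima,
                 tolerances = tolerances, max_suitability = max_suitability,
                 range_limit_km = range_limit_km, range_center = range_center),
            class = "niche_spec")
}

#' Ground-truth suitability of a niche at grid cells
#'
#' @param niche A [niche_spec].
#' @param grid An [env_grid] whose layers match the niche's `optima` names.
#' @param cells Integer cell ids (default: all cells).
#' @return Numeric vector of suitabilities in `[0, 1]`.
#' @export
niche_suitability <- function(niche, grid, cells = NULL) {
  cells <- cells %||% seq_len(n_grid_cells(grid))
  vars <- names(niche$optima)
  missing <- setdiff(vars, grid_layer_names(grid))
  if (length(missing)) {
    abort(paste0("grid lacks layer(s): ", paste(missing, collapse = ", ")))
  }
  X <- grid_values_at(grid, cells, vars)
  z2 <- sweep(X, 2L, niche$optima[vars], `-`)
  z2 <- sweep(z2, 2L, niche$tolerances[vars], `/`)^2
  z2[!is.finite(z2)] <- 0  # infinite tolerance => flat axis
  s <- niche$max_suitability * exp(-0.5 * rowSums(z2))
  if (!is.null(niche$range_limit_km)) {
    cc <- cell_centers(grid, cells)
    d <- haversine_km(niche$range_center[["lon"]], niche$range_center[["lat"]],
                      cc$lon, cc$lat)
    s[d > niche$range_limit_km] <- 0
  }
  s
}

#' Sample occurrence records from a ground-truth niche
#'
#' Draws `n_records` records from reef cells with probability proportional to
#' the niche's suitability (clipped to the species' geodesic range disc when
#' one is set). Coordinates are jittered uniformly within the source cell; if
#' a table of fixed sample `sites` is supplied, records are drawn from those
#' sites instead, emulating survey revisits.
#'
#' @param niche A [niche_spec].
#' @param grid An [env_grid].
#' @param reef A `reef_mask`.
#' @param n_records Number of records (>= 1); sampling is with replacement.
#' @param seed Integer seed.
#' @param sites Optional tibble of fixed sampling sites with columns `cell`,
#'   `lon`, `lat`.
#' @return A tibble with columns `species_id`, `lon`, `lat`, `source`.
#' @export
sample_occurrences <- function(niche, grid, reef, n_records, seed = 1L,
                               sites = NULL) {
  if (n_records < 1L) abort("`n_records` must be >= 1.")
  if (is.null(sites)) {
    cells <- which(reef$mask)
    cc <- cell_centers(grid, cells)
  } else {
    cc <- sites
    cells <- sites$cell
  }
  w <- niche_suitability(niche, grid, cells)
  if (!any(w > 0) || sum(w) == 0) {
    abort(sprintf("unsamplable niche for species '%s': no reef cell with positive suitability",
                  niche$species_id),
          class = "richstack_unsamplable")
  }
  set.seed(as.integer(seed))
  idx <- sample.int(length(cells), n_records, replace = TRUE, prob = w)
  if (is.null(sites)) {
    half <- grid$cell_size / 2
    lon <- recenter_lon(cc$lon[idx] + runif(n_records, -half, half))
    lat <- cc$lat[idx] + runif(n_records, -half, half)
  } else {
    lon <- cc$lon[idx]
    lat <- cc$lat[idx]
  }
  tibble(species_id = niche$species_id, lon = lon, lat = lat,
         source = "synthetic")
}

#' Generate the default synthetic biodiversity study
#'
#' Builds a complete, reproducible study with known ground truth: a
#' correlated environmental stack, a clustered reef mask, ~500 fixed sampling
#' sites, and 68 species whose Gaussian niches are anchored near a richness
#' hotspot. Record counts are heterogeneous (a few species have fewer than
#' three records, so they can only be ranged by geodesic buffering) and some
#' species are flagged as range-limited with a geodesic distribution cap.
#' Everything regenerates identically from one master seed.
#'
#' @param seed Master seed; all stage- and species-level draws are derived
#'   from it with [child_seed()].
#' @param n_species,n_sites,n_records_total Pool sizes; defaults are 68
#'   species, 507 sites, 2964 records.
#' @param extent,cell_size,n_layers,correlation,reef_coverage Passed to the
#'   grid and reef generators.
#' @param hotspot Named `c(lon, lat)` around which niche anchors concentrate.
#' @param n_rare Number of species forced to < 3 records.
#' @param n_range_limited Number of species flagged range-limited.
#' @return An object of class `synthetic_study`: list with `grid`, `reef`,
#'   `sites`, `species` (tibble with a `niche` list-column), `occurrences`.
#' @export
synthetic_study <- function(seed = 1L, n_species = 68, n_sites = 507,
                            n_records_total = 2964,
                            extent = c(40, 260, -34, 33), cell_size = 0.5,
                            n_layers = 7, correlation = 0.7,
                            reef_coverage = 0.08,
                            hotspot = c(lon = 125, lat = 10),
                            n_rare = 6, n_range_limited = 8) {
  grid <- generate_env_grid(extent, cell_size, n_layers, correlation,
                            seed = child_seed(seed, "env"))
  reef <- generate_reef_mask(grid, reef_coverage,
                             seed = child_seed(seed, "reef"))
  reef_cells <- which(reef$mask)
  if (length(reef_cells) < 10L) abort("reef mask is degenerate (too few cells).")

  set.seed(child_seed(seed, "sites"))
  site_cells <- sort(sample(reef_cells, min(n_sites, length(reef_cells))))
  sc <- cell_centers(grid, site_cells)
  half <- cell_size / 2
  sites <- tibble(
    cell = sc$cell,
    lon = recenter_lon(sc$lon + runif(nrow(sc), -half, half)),
    lat = sc$lat + runif(nrow(sc), -half, half),
    site_id = sprintf("site%03d", seq_len(nrow(sc))))

  ids <- sprintf("sp%02d", seq_len(n_species))
  set.seed(child_seed(seed, "counts"))
  n_rare <- min(n_rare, max(n_species - 2L, 0L))
  raw <- stats::rlnorm(n_species, meanlog = log(30), sdlog = 0.8)
  rare <- sort(sample(n_species, n_rare))
  n_rec <- integer(n_species)
  n_rec[rare] <- sample(1:2, n_rare, replace = TRUE)
  rest <- setdiff(seq_len(n_species), rare)
  target <- n_records_total - sum(n_rec[rare])
  n_rec[rest] <- pmax(3L, as.integer(round(raw[rest] * target / sum(raw[rest]))))
  # nudge the largest species so the total matches exactly
  gap <- target - sum(n_rec[rest])
  n_rec[rest[which.max(n_rec[rest])]] <- n_rec[rest[which.max(n_rec[rest])]] + gap
  n_range_limited <- min(n_range_limited, length(rest))
  limited <- sort(sample(rest, n_range_limited))
  limit_km <- stats::runif(n_range_limited, 1500, 2500)

  layer_sds <- vapply(grid$layers, function(m) sd(as.vector(m)), 0)
  rc <- cell_centers(grid, reef_cells)
  species <- vector("list", n_species)
  occs <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    set.seed(child_seed(seed, "niche", ids[s]))
    a_lon <- recenter_lon(rnorm(1, hotspot[["lon"]], 25))
    a_lat <- rnorm(1, hotspot[["lat"]], 8)
    anchor <- which.min(haversine_km(a_lon, a_lat, rc$lon, rc$lat))
    anchor_cell <- reef_cells[anchor]
    opt <- grid_values_at(grid, anchor_cell)[1, ] +
      rnorm(n_layers, 0, 0.1 * layer_sds)
    tol <- layer_sds * runif(n_layers, 0.6, 1.5)
    names(opt) <- names(tol) <- grid_layer_names(grid)
    lim <- if (s %in% limited) limit_km[match(s, limited)] else NULL
    ctr <- if (s %in% limited) c(lon = rc$lon[anchor], lat = rc$lat[anchor]) else NULL
    niche <- niche_spec(ids[s], opt, tol, max_suitability = 1,
                        range_limit_km = lim, range_center = ctr)
    # records normally come from the fixed survey sites; species whose
    # suitability is positive at no site (e.g. a small range disc missing
    # every site) are surveyed directly on their reef habitat instead
    occs[[s]] <- tryCatch(
      sample_occurrences(niche, grid, reef, n_rec[s],
                         seed = child_seed(seed, "occ", ids[s]),
                         sites = sites),
      richstack_unsamplable = function(cnd) {
        sample_occurrences(niche, grid, reef, n_rec[s],
                           seed = child_seed(seed, "occ", ids[s]))
      })
    species[[s]] <- tibble(species_id = ids[s], n_records = n_rec[s],
                           range_limited = s %in% limited,
                           range_limit_km = if (!is.null(lim)) lim else NA_real_,
                           niche = list(niche))
  }
  structure(
    list(grid = grid, reef = reef, sites = sites,
         species = bind_rows(species),
         occurrences = bind_rows(occs),
         seed = as.integer(seed)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d species, %d records at %d sites; seed %d\n",
    nrow(x$species), nrow(x$occurrences), nrow(x$sites), x$seed))
  invisible(x)
}
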