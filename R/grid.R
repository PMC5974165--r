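#' Longitude recentering helpers
#'
#' The analysis grid is centered at 180 degrees longitude so that
#' Pacific-spanning geometry is contiguous: all longitudes are carried in the
#' `[0, 360)` convention. `recenter_lon()` maps any longitude into that
#' convention; `signed_lon()` maps back to `[-180, 180)`.
#'
#' @param lon Numeric vector of longitudes in degrees, any convention.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' recenter_lon(-170) # 190
#' signed_lon(190)    # -170
recenter_lon <- function(lon) lon %% 360

#' @rdname recenter_lon
#' @export
signed_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Construct an environmental raster stack
#'
#' A lightweight in-memory raster stack on a regular latitude/longitude
#' lattice. Layers are matrices with rows indexing latitude (ascending, row 1
#' is the southernmost band) and columns indexing longitude (ascending, in
#' the `[0, 360)` recentered convention). All layers share one shape and one
#' validity (marine) mask.
#'
#' @param layers Named list of numeric matrices, all of identical dimension.
#' @param lat_centers,lon_centers Cell-center coordinates in degrees;
#'   `lon_centers` must be strictly increasing within `[0, 360)`.
#' @param cell_size Cell edge length in degrees.
#' @param valid_mask Logical matrix marking marine (analysable) cells.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(layers, lat_centers, lon_centers, cell_size, valid_mask) {
  if (!is.list(layers) || length(layers) < 1L || is.null(names(layers)) ||
      any(!nzchar(names(layers)))) {
    abort("`layers` must be a non-empty named list of matrices.")
  }
  dims <- c(length(lat_centers), length(lon_centers))
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), as.integer(dims))) {
      abort(sprintf("layer '%s' does not match the %d x %d lattice", nm,
                    dims[1], dims[2]))
    }
  }
  if (!identical(dim(valid_mask), as.integer(dims))) {
    abort("`valid_mask` does not match the lattice.")
  }
  if (any(lat_centers < -90 | lat_centers > 90)) {
    abort("latitudes must lie within [-90, 90].")
  }
  if (is.unsorted(lon_centers, strictly = TRUE) ||
      any(lon_centers < 0 | lon_centers >= 360)) {
    abort("`lon_centers` must be strictly increasing within [0, 360).")
  }
  if (is.unsorted(lat_centers, strictly = TRUE)) {
    abort("`lat_centers` must be strictly increasing.")
  }
  structure(
    list(layers = layers,
         lat_centers = as.numeric(lat_centers),
         lon_centers = as.numeric(lon_centers),
         cell_size = as.numeric(cell_size),
         valid_mask = valid_mask),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf(
    "<env_grid> %d x %d cells at %.4g deg, %d layer(s): %s\n  lon [%.2f, %.2f] lat [%.2f, %.2f]; %d valid cells\n",
    length(x$lat_centers), length(x$lon_centers), x$cell_size,
    length(x$layers), paste(names(x$layers), collapse = ", "),
    min(x$lon_centers), max(x$lon_centers),
    min(x$lat_centers), max(x$lat_centers), sum(x$valid_mask)))
  invisible(x)
}

#' @export
dim.env_grid <- function(x) c(length(x$lat_centers), length(x$lon_centers))

n_grid_cells <- function(grid) length(grid$lat_centers) * length(grid$lon_centers)

grid_layer_names <- function(grid) names(grid$layers)

#' Cell centers of a grid as a tibble
#'
#' @param grid An `env_grid`.
#' @param cells Optional integer vector of cell ids (column-major matrix
#'   indices); default all cells.
#' @return A tibble with columns `cell`, `lon`, `lat`.
#' @export
cell_centers <- function(grid, cells = NULL) {
  nr <- length(grid$lat_centers)
  nc <- length(grid$lon_centers)
  if (is.null(cells)) cells <- seq_len(nr * nc)
  i <- ((cells - 1L) %% nr) + 1L
  j <- ((cells - 1L) %/% nr) + 1L
  tibble(cell = as.integer(cells),
         lon = grid$lon_centers[j],
         lat = grid$lat_centers[i])
}

#' Snap points to grid cells
#'
#' Maps longitude/latitude points (any longitude convention) to the id of the
#' cell whose footprint contains them. Points outside the grid extent map to
#' `NA`.
#'
#' @param grid An `env_grid`.
#' @param lon,lat Numeric vectors of point coordinates in degrees.
#' @return Integer vector of cell ids (column-major indices into the layer
#'   matrices), `NA` where the point falls off-grid.
#' @export
point_to_cell <- function(grid, lon, lat) {
  lon <- recenter_lon(lon)
  cs <- grid$cell_size
  lon0 <- grid$lon_centers[1] - cs / 2
  lat0 <- grid$lat_centers[1] - cs / 2
  j <- floor((lon - lon0) / cs) + 1
  i <- floor((lat - lat0) / cs) + 1
  nr <- length(grid$lat_centers)
  nc <- length(grid$lon_centers)
  # points exactly on the outer edge belong to the last cell
  j[lon == lon0 + nc * cs] <- nc
  i[lat == lat0 + nr * cs] <- nr
  bad <- i < 1 | i > nr | j < 1 | j > nc | !is.finite(lon) | !is.finite(lat)
  i[bad] <- NA_integer_
  j[bad] <- NA_integer_
  as.integer((j - 1L) * nr + i)
}

#' Extract layer values at cells
#'
#' @param grid An `env_grid`.
#' @param cells Integer cell ids.
#' @param layers Character vector of layer names (default all).
#' @return Numeric matrix, one row per cell, one column per layer.
#' @export
grid_values_at <- function(grid, cells, layers = NULL) {
  layers <- layers %||% grid_layer_names(grid)
  out <- vapply(layers, function(nm) grid$layers[[nm]][cells],
                numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, layers))
  out
}

#' @export
as_tibble.env_grid <- function(x, ...) {
  cc <- cell_centers(x)
  vals <- as_tibble(as.data.frame(grid_values_at(x, cc$cell)))
  dplyr::bind_cols(cc, vals, tibble(valid = as.vector(x$valid_mask)))
}

same_lattice <- function(a_lat, a_lon, b_lat, b_lon, tol = 1e-9) {
  length(a_lat) == length(b_lat) && length(a_lon) == length(b_lon) &&
    max(abs(a_lat - b_lat)) < tol && max(abs(a_lon - b_lon)) < tol
}

# ---- ESRI ASCII grid dialect -------------------------------------------------

#' Read and write single-band ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' cell values from north to south. Values are written with `%.17g` so a
#' write/read round trip is bit-exact for doubles.
#'
#' @param mat Numeric matrix, rows = latitude ascending (southernmost first).
#' @param lat_centers,lon_centers Cell-center coordinates.
#' @param cell_size Cell size in degrees.
#' @param path File path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `read_ascii_grid()` returns a list with `values` (matrix oriented
#'   like `env_grid` layers), `lat_centers`, `lon_centers`, `cell_size`,
#'   `nodata`.
#' @export
write_ascii_grid <- function(mat, lat_centers, lon_centers, cell_size, path,
                             nodata = -9999) {
  stopifnot(nrow(mat) == length(lat_centers), ncol(mat) == length(lon_centers))
  vals <- mat
  vals[is.na(vals)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.17g", lon_centers[1] - cell_size / 2),
    sprintf("yllcorner %.17g", lat_centers[1] - cell_size / 2),
    sprintf("cellsize %.17g", cell_size),
    sprintf("NODATA_value %.17g", nodata)
  )
  # ESRI convention: first data row is the northernmost band
  rows <- apply(vals[rev(seq_len(nrow(vals))), , drop = FALSE], 1L,
                function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]])
  nrows <- as.integer(vals[["nrows"]])
  cs <- vals[["cellsize"]]
  nodata <- vals[["nodata_value"]]
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- do.call(rbind, lapply(body, as.numeric))
  if (!identical(dim(m), c(nrows, ncols))) {
    abort("ASCII grid body does not match the declared nrows/ncols.")
  }
  m <- m[rev(seq_len(nrows)), , drop = FALSE]  # back to south-first rows
  m[m == nodata] <- NA_real_
  list(values = m,
       lat_centers = vals[["yllcorner"]] + (seq_len(nrows) - 0.5) * cs,
       lon_centers = vals[["xllcorner"]] + (seq_len(ncols) - 0.5) * cs,
       cell_size = cs, nodata = nodata)
}

#' Write or read a full raster stack directory
#'
#' One `.asc` file per layer plus `valid_mask.asc` and a JSON sidecar with
#' layer names and lattice metadata.
#'
#' @param grid An `env_grid`.
#' @param dir Directory (created if missing).
#' @return `read_env_grid()` returns an `env_grid`.
#' @export
write_env_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in grid_layer_names(grid)) {
    write_ascii_grid(grid$layers[[nm]], grid$lat_centers, grid$lon_centers,
                     grid$cell_size, file.path(dir, paste0(nm, ".asc")))
  }
  write_ascii_grid(grid$valid_mask * 1, grid$lat_centers, grid$lon_centers,
                   grid$cell_size, file.path(dir, "valid_mask.asc"))
  jsonlite::write_json(
    list(layer_names = grid_layer_names(grid), cell_size = grid$cell_size),
    file.path(dir, "stack.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_env_grid
#' @export
read_env_grid <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  layers <- lapply(meta$layer_names, function(nm) {
    read_ascii_grid(file.path(dir, paste0(nm, ".asc")))$values
  })
  names(layers) <- meta$layer_names
  ref <- read_ascii_grid(file.path(dir, "valid_mask.asc"))
  env_grid(layers, ref$lat_centers, ref$lon_centers, meta$cell_size,
           ref$values == 1)
}
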