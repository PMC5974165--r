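#' Stack binary species ranges into a richness map
#'
#' Cellwise sum of per-species boolean range grids: each cell's value is the
#' number of species whose range covers it.
#'
#' @param ranges List of [binary_range] objects on one lattice.
#' @param method Label for the map (`"MCP"` or `"SDM"`), recorded for
#'   provenance; defaults to the majority provenance of the inputs.
#' @return An object of class `richness_map`: integer `values` matrix,
#'   `n_species`, `method`, lattice coordinates.
#' @export
stack_ranges <- function(ranges, method = NULL) {
  if (length(ranges) == 0L) {
    abort("`stack_ranges` needs a reference lattice; pass at least one range or use `empty_richness_map()`.")
  }
  ref <- ranges[[1]]
  vals <- matrix(0L, length(ref$lat_centers), length(ref$lon_centers))
  for (r in ranges) {
    if (!same_lattice(ref$lat_centers, ref$lon_centers,
                      r$lat_centers, r$lon_centers)) {
      abort(sprintf("range for species '%s' is on a different lattice",
                    r$species_id))
    }
    vals <- vals + r$cells
  }
  method <- method %||%
    names(sort(table(vapply(ranges, `[[`, "", "provenance")), decreasing = TRUE))[1]
  structure(list(values = vals, n_species = length(ranges), method = method,
                 lat_centers = ref$lat_centers, lon_centers = ref$lon_centers),
            class = "richness_map")
}

#' All-zero richness map on a grid lattice
#'
#' @param grid An [env_grid] (or anything carrying `lat_centers`,
#'   `lon_centers`).
#' @param method Label.
#' @return A `richness_map` with zero species.
#' @export
empty_richness_map <- function(grid, method = "MCP") {
  structure(list(values = matrix(0L, length(grid$lat_centers),
                                 length(grid$lon_centers)),
                 n_species = 0L, method = method,
                 lat_centers = grid$lat_centers,
                 lon_centers = grid$lon_centers),
            class = "richness_map")
}

#' @export
print.richness_map <- function(x, ...) {
  cat(sprintf("<richness_map> %s overlay of %d species; max richness %d\n",
              x$method, x$n_species, max(x$values)))
  invisible(x)
}

#' @export
as_tibble.richness_map <- function(x, ...) {
  nr <- length(x$lat_centers)
  nc <- length(x$lon_centers)
  tibble(lon = rep(x$lon_centers, each = nr),
         lat = rep(x$lat_centers, times = nc),
         richness = as.vector(x$values))
}

#' Class a richness map into richness bands for display
#'
#' Groups positive richness values into classes of width `bin_width`
#' (default 5); zero keeps its own class 0. By default class boundaries sit
#' at multiples of `bin_width` (`class = ceiling(value / bin_width)`). With
#' `anchor` set — typically to the map maximum — boundaries are shifted so
#' the top class ends exactly at the anchor (e.g. anchor 56, width 5 gives
#' bands ..., 47-51, 52-56), the legend convention of richness atlases.
#'
#' @param map A `richness_map`.
#' @param bin_width Class width, >= 1.
#' @param anchor Optional value at which the top class closes.
#' @return Integer matrix of class indices (0 = empty).
#' @export
classify_richness <- function(map, bin_width = 5, anchor = NULL) {
  if (bin_width < 1) abort("`bin_width` must be >= 1.")
  v <- map$values
  if (is.null(anchor)) {
    cls <- ceiling(v / bin_width)
  } else {
    cls <- ceiling(anchor / bin_width) - floor((anchor - v) / bin_width)
  }
  cls[v == 0] <- 0
  storage.mode(cls) <- "integer"
  cls
}

#' Binned richness gradient along latitude or longitude
#'
#' Groups analysis-mask cells into `bin_deg`-degree bins (default 3) by
#' their center coordinate and summarises per-bin richness with boxplot
#' statistics: quartiles by linear interpolation, Tukey whiskers (most
#' extreme values within 1.5 IQR of the quartiles) and the bin maximum
#' recorded separately. Only cells inside the analysis mask contribute;
#' bins with no mask cells are kept with `n_cells = 0` and `NA` statistics.
#'
#' @param map A `richness_map`.
#' @param mask The analysis `reef_mask`.
#' @param axis `"latitude"` or `"longitude"`.
#' @param bin_deg Bin width in degrees.
#' @return A tibble of class `gradient_profile` with columns `bin_lower`,
#'   `bin_center`, `n_cells`, `min`, `q1`, `median`, `q3`, `whisker_low`,
#'   `whisker_high`, `max`; the axis and bin width are kept as attributes.
#' @export
richness_gradient <- function(map, mask, axis = c("latitude", "longitude"),
                              bin_deg = 3) {
  axis <- match.arg(axis)
  if (!same_lattice(map$lat_centers, map$lon_centers,
                    mask$lat_centers, mask$lon_centers)) {
    abort("richness map and mask are on different lattices.")
  }
  cells <- which(mask$mask)
  cc <- cell_centers(list(lat_centers = map$lat_centers,
                          lon_centers = map$lon_centers), cells)
  coord <- if (axis == "latitude") cc$lat else cc$lon
  v <- map$values[cells]
  axis_range <- if (axis == "latitude") range(map$lat_centers) else range(map$lon_centers)
  lowers <- seq(floor(axis_range[1] / bin_deg) * bin_deg,
                ceiling((axis_range[2] + 1e-9) / bin_deg) * bin_deg - bin_deg,
                by = bin_deg)
  bin_of <- floor(coord / bin_deg) * bin_deg
  stats_for <- function(lo) {
    x <- v[bin_of == lo]
    if (length(x) == 0L) {
      return(tibble(bin_lower = lo, bin_center = lo + bin_deg / 2,
                    n_cells = 0L, min = NA_real_, q1 = NA_real_,
                    median = NA_real_, q3 = NA_real_, whisker_low = NA_real_,
                    whisker_high = NA_real_, max = NA_real_))
    }
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    tibble(bin_lower = lo, bin_center = lo + bin_deg / 2,
           n_cells = length(x), min = min(x),
           q1 = q[1], median = q[2], q3 = q[3],
           whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
           whisker_high = max(x[x <= q[3] + 1.5 * iqr]),
           max = max(x))
  }
  out <- bind_rows(lapply(lowers, stats_for))
  attr(out, "axis") <- axis
  attr(out, "bin_deg") <- bin_deg
  class(out) <- c("gradient_profile", class(out))
  out
}

#' Coordinate of the peak of a richness gradient
#'
#' The bin center whose median richness is highest (first on ties).
#'
#' @param profile A [richness_gradient] result.
#' @return Bin-center coordinate in degrees.
#' @export
gradient_peak <- function(profile) {
  ok <- profile$n_cells > 0
  profile$bin_center[ok][which.max(profile$median[ok])]
}
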