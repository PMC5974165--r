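#' Per-species binary range on the analysis grid
#'
#' @param species_id Identifier.
#' @param cells Logical matrix on the grid lattice.
#' @param provenance How the range was derived: `"SDM"`, `"MCP"` or
#'   `"buffer500"`.
#' @param grid The [env_grid] lattice.
#' @param masked Whether the range has been intersected with the analysis
#'   mask.
#' @return An object of class `binary_range`.
#' @export
binary_range <- function(species_id, cells, provenance, grid, masked = TRUE) {
  provenance <- match.arg(provenance, c("SDM", "MCP", "buffer500"))
  structure(list(species_id = species_id, cells = cells,
                 provenance = provenance, masked = masked,
                 lat_centers = grid$lat_centers,
                 lon_centers = grid$lon_centers),
            class = "binary_range")
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf("<binary_range> species '%s' via %s: %d cell(s)%s\n",
              x$species_id, x$provenance, sum(x$cells),
              if (x$masked) ", masked" else ""))
  invisible(x)
}

#' Assemble one species' binary range by the hybrid routing rule
#'
#' Routes a species to its range estimator and applies the analysis mask:
#' the `"MCP"` method rasterises the minimum convex polygon of the records;
#' the `"SDM"` method uses the thresholded ensemble prediction. Species
#' ineligible for the requested method — fewer than three records (or
#' collinear ones) for a polygon, too few presence cells for a model — fall
#' back to merging geodesic buffers of `fallback_radius_km` (default 500 km)
#' around each record. Both richness maps are therefore hybrids, and every
#' range carries its provenance.
#'
#' @param occ One species' records (`lon`, `lat`, optionally `species_id`).
#' @param method `"MCP"` or `"SDM"`.
#' @param grid The [env_grid] lattice.
#' @param mask The buffered `reef_mask` (must have `buffered = TRUE`).
#' @param sdm Optional [run_sdm_ensemble] result (required for a non-fallback
#'   `"SDM"` route).
#' @param min_records_mcp Minimum records for a convex polygon (default 3).
#' @param fallback_radius_km Buffer radius for the fallback route.
#' @param species_id Identifier (taken from `occ` if present).
#' @return A [binary_range] with provenance recorded.
#' @export
hybrid_range <- function(occ, method = c("MCP", "SDM"), grid, mask,
                         sdm = NULL, min_records_mcp = 3,
                         fallback_radius_km = 500, species_id = NULL) {
  method <- match.arg(method)
  species_id <- species_id %||%
    (if ("species_id" %in% names(occ)) occ$species_id[1] else NA_character_)
  if (!isTRUE(mask$buffered)) {
    warn("analysis mask is not buffered; expected the 100 km-dilated reef mask.")
  }
  cells <- NULL
  provenance <- "buffer500"
  if (method == "MCP" && nrow(distinct(tibble(lon = occ$lon, lat = occ$lat))) >=
        min_records_mcp) {
    cells <- tryCatch({
      poly <- mcp_hull(occ, species_id = species_id)
      ras <- rasterize_polygon(poly, grid)
      # occupied record cells are direct evidence of presence: keep them even
      # when a boundary record's cell center falls just outside the hull
      rec <- point_to_cell(grid, occ$lon, occ$lat)
      ras[rec[!is.na(rec)]] <- TRUE
      ras
    }, richstack_fallback = function(cnd) NULL)
    if (!is.null(cells)) provenance <- "MCP"
  } else if (method == "SDM" && !is.null(sdm) && isTRUE(sdm$eligible)) {
    cells <- sdm$binary
    provenance <- "SDM"
  }
  if (is.null(cells)) {
    cells <- geodesic_buffer_cells(occ, fallback_radius_km, grid)
  }
  cells <- cells & mask$mask
  if (!any(cells)) {
    warn(sprintf("species '%s': empty range after masking (%s route)",
                 species_id, provenance))
  }
  binary_range(species_id, cells, provenance, grid, masked = TRUE)
}
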