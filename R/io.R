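#' Read an occurrence table from delimited text
#'
#' Expects a header with at least `species_id`, `lon`, `lat` (a `source`
#' column is carried through when present). Longitudes are accepted in
#' either `[-180, 180)` or `[0, 360)` and normalised to the recentered
#' `[0, 360)` convention; rows with unparseable coordinates are rejected
#' with a warning naming their line numbers.
#'
#' @param path Delimited text file.
#' @param delim Field delimiter (default comma).
#' @return A tibble with columns `species_id`, `lon`, `lat`, `source`,
#'   ordered by species.
#' @export
read_occurrences <- function(path, delim = ",") {
  raw <- read.csv(path, sep = delim, colClasses = "character",
                  check.names = TRUE, strip.white = TRUE)
  required <- c("species_id", "lon", "lat")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("occurrence file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    warn(sprintf("'%s' contains no records", path))
    return(tibble(species_id = character(), lon = numeric(),
                  lat = numeric(), source = character()))
  }
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad <- is.na(lon) | is.na(lat) | lat < -90 | lat > 90
  if (any(bad)) {
    warn(sprintf("rejected %d row(s) with unparseable coordinates (line %s)",
                 sum(bad),
                 paste(which(bad) + 1L, collapse = ", ")))  # +1 for the header
  }
  out <- tibble(
    species_id = raw$species_id,
    lon = recenter_lon(lon),
    lat = lat,
    source = if ("source" %in% names(raw)) raw$source else NA_character_)
  arrange(out[!bad, ], .data$species_id)
}

#' @rdname read_occurrences
#' @param occ Occurrence tibble (`species_id`, `lon`, `lat`, optionally
#'   `source`).
#' @export
write_occurrences <- function(occ, path) {
  cols <- intersect(c("species_id", "lon", "lat", "source"), names(occ))
  write.csv(occ[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse records to one per occupied grid cell
#'
#' Duplicate records of a species within one cell collapse to a single
#' modeling record; the raw multiplicity is preserved in `n_raw` for
#' provenance.
#'
#' @param occ Occurrence tibble.
#' @param grid An [env_grid].
#' @return A tibble with `species_id`, `cell`, `lon`, `lat` (cell centers)
#'   and `n_raw`.
#' @export
occurrence_cells <- function(occ, grid) {
  occ |>
    mutate(cell = point_to_cell(grid, .data$lon, .data$lat)) |>
    filter(!is.na(.data$cell)) |>
    count(.data$species_id, .data$cell, name = "n_raw") |>
    mutate(lon = cell_centers(grid, .data$cell)$lon,
           lat = cell_centers(grid, .data$cell)$lat) |>
    select("species_id", "cell", "lon", "lat", "n_raw")
}

#' Export a range polygon as a plain-text ring
#'
#' One `lon lat` pair per line, counter-clockwise, preceded by a comment
#' line carrying the species id.
#'
#' @param poly A `range_polygon`.
#' @param path Output file.
#' @return `read_range_polygon()` returns the polygon.
#' @export
write_range_polygon <- function(poly, path) {
  writeLines(c(sprintf("# species_id %s", poly$species_id),
               sprintf("%.17g %.17g", poly$vertices$lon, poly$vertices$lat)),
             path)
  invisible(path)
}

#' @rdname write_range_polygon
#' @export
read_range_polygon <- function(path) {
  lines <- readLines(path)
  sid <- sub("^# species_id ", "", lines[1])
  xy <- do.call(rbind, lapply(strsplit(lines[-1], " "), as.numeric))
  structure(list(species_id = sid,
                 vertices = tibble(lon = xy[, 1], lat = xy[, 2])),
            class = "range_polygon")
}
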