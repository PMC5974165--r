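#' Pipeline configuration
#'
#' Collects every tunable of the richness-mapping pipeline with its default:
#' the grid specification, the three geodesic radii (100 km reef-mask
#' dilation, 500 km fallback buffers, 2,500 km range constraint), the PCA
#' sampling size (10,000 cells, Kaiser retention), the ensemble settings
#' (10 replicates, 80% training fraction, 10,000 background cells,
#' regularisation scale 1, 8-record eligibility), the 3-degree gradient
#' bins, and the master seed every random draw derives from.
#'
#' @param extent,cell_size Grid specification (degrees).
#' @param synthetic Synthetic-study sizes (see [synthetic_study()]).
#' @param radii_km Named list: `reef_mask`, `fallback`, `constraint`.
#' @param pca Named list: `n_sample`.
#' @param sdm Named list: `n_replicates`, `train_fraction`,
#'   `background_size`, `beta0`, `min_records_sdm`.
#' @param mcp Named list: `min_records`.
#' @param gradient Named list: `bin_deg`.
#' @param seed Master seed.
#' @return A validated list of class `richness_config`.
#' @export
richness_config <- function(extent = c(40, 260, -34, 33), cell_size = 0.5,
                            synthetic = list(), radii_km = list(),
                            pca = list(), sdm = list(), mcp = list(),
                            gradient = list(), seed = 1L) {
  cfg <- list(
    extent = extent, cell_size = cell_size,
    synthetic = utils::modifyList(
      list(n_species = 68, n_sites = 507, n_records_total = 2964,
           n_layers = 7, correlation = 0.7, reef_coverage = 0.08,
           hotspot = c(lon = 125, lat = 10), n_rare = 6,
           n_range_limited = 8), synthetic),
    radii_km = utils::modifyList(
      list(reef_mask = 100, fallback = 500, constraint = 2500), radii_km),
    pca = utils::modifyList(list(n_sample = 10000), pca),
    sdm = utils::modifyList(
      list(n_replicates = 10, train_fraction = 0.8, background_size = 10000,
           beta0 = 1.0, min_records_sdm = 8), sdm),
    mcp = utils::modifyList(list(min_records = 3), mcp),
    gradient = utils::modifyList(list(bin_deg = 3), gradient),
    seed = as.integer(seed))
  if (any(unlist(cfg$radii_km) <= 0)) abort("all radii must be positive.")
  if (cfg$sdm$train_fraction <= 0 || cfg$sdm$train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1).")
  }
  structure(cfg, class = "richness_config")
}

#' Run the full richness-mapping pipeline
#'
#' Executes every stage in order: synthetic study generation (unless a
#' `study` is supplied), PCA reduction of the environmental stack and
#' projection of the retained components, per-species distribution-model
#' ensembles and hybrid range assembly for both the MCP and the SDM
#' overlay, cellwise stacking into two richness maps, and 3-degree
#' latitudinal/longitudinal gradient profiles of the SDM and MCP maps.
#' Fully deterministic for a fixed master seed: per-stage, per-species
#' seeds are hashed from it, so adding a species never reshuffles the
#' draws of the others.
#'
#' @param config A [richness_config].
#' @param study Optional pre-built [synthetic_study] (or compatible list
#'   with `grid`, `reef`, `species`, `occurrences`); when supplied, its
#'   data are used instead of simulating.
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `richness_run`: the study, `mask`, `pca`,
#'   `pc_grid`, per-species `sdm` list, `ranges_mcp`, `ranges_sdm`,
#'   `richness_mcp`, `richness_sdm`, four `gradients`, and a `manifest`
#'   (config, seeds, per-species routing with reasons).
#' @export
run_richness_pipeline <- function(config = richness_config(), study = NULL,
                                  quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) inform(sprintf(fmt, ...))
  seed <- config$seed
  stage <- function(name, sid, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed%s: %s", name,
                    if (is.null(sid)) "" else paste0(" for species ", sid),
                    conditionMessage(e)))
    })
  }

  if (is.null(study)) {
    say("simulate: %d species on a %.2g-degree grid",
        config$synthetic$n_species, config$cell_size)
    syn <- config$synthetic
    study <- stage("simulate", NULL, synthetic_study(
      seed = seed, n_species = syn$n_species, n_sites = syn$n_sites,
      n_records_total = syn$n_records_total, extent = config$extent,
      cell_size = config$cell_size, n_layers = syn$n_layers,
      correlation = syn$correlation, reef_coverage = syn$reef_coverage,
      hotspot = syn$hotspot, n_rare = syn$n_rare,
      n_range_limited = syn$n_range_limited))
  }
  grid <- study$grid

  say("mask: dilating reef habitat by %g km", config$radii_km$reef_mask)
  mask <- stage("mask", NULL,
                buffer_reef_mask(study$reef, grid, config$radii_km$reef_mask))

  say("pca: %d sampled cells", config$pca$n_sample)
  n_pca <- min(config$pca$n_sample, sum(grid$valid_mask))
  samples <- stage("pca", NULL,
                   sample_env_cells(grid, n_pca, seed = child_seed(seed, "pca")))
  pca <- stage("pca", NULL, fit_env_pca(samples))
  pc_grid <- stage("pca", NULL, project_pcs(grid, pca))
  say("pca: %d component(s) retained (%.1f%% of variance)",
      pca$n_retained, 100 * sum(pca$variance_fraction[seq_len(pca$n_retained)]))

  species <- study$species
  occ_by_sp <- split(study$occurrences, study$occurrences$species_id)
  sdms <- vector("list", nrow(species))
  ranges_mcp <- vector("list", nrow(species))
  ranges_sdm <- vector("list", nrow(species))
  names(sdms) <- names(ranges_mcp) <- names(ranges_sdm) <- species$species_id
  routing <- vector("list", nrow(species))

  for (s in seq_len(nrow(species))) {
    sid <- species$species_id[s]
    occ <- occ_by_sp[[sid]]
    ens <- stage("sdm", sid, withCallingHandlers(
      run_sdm_ensemble(
        occ, pc_grid, mask,
        n_replicates = config$sdm$n_replicates,
        train_fraction = config$sdm$train_fraction,
        background_size = config$sdm$background_size,
        beta0 = config$sdm$beta0,
        min_records = config$sdm$min_records_sdm,
        seed = child_seed(seed, "sdm", sid), species_id = sid),
      message = function(m) invokeRestart("muffleMessage")))
    if (isTRUE(ens$eligible) && isTRUE(species$range_limited[s])) {
      ens <- stage("constrain", sid,
                   constrain_range(ens, occ, grid,
                                   radius_km = config$radii_km$constraint))
    }
    sdms[[sid]] <- ens
    ranges_mcp[[sid]] <- stage("mcp", sid, suppressWarnings(hybrid_range(
      occ, "MCP", grid, mask,
      min_records_mcp = config$mcp$min_records,
      fallback_radius_km = config$radii_km$fallback, species_id = sid)))
    ranges_sdm[[sid]] <- stage("hybrid", sid, suppressWarnings(hybrid_range(
      occ, "SDM", grid, mask, sdm = ens,
      fallback_radius_km = config$radii_km$fallback, species_id = sid)))
    routing[[s]] <- tibble(
      species_id = sid,
      n_records = nrow(occ),
      n_presence_cells = ens$n_presence_cells,
      range_limited = isTRUE(species$range_limited[s]),
      mcp_route = ranges_mcp[[sid]]$provenance,
      sdm_route = ranges_sdm[[sid]]$provenance,
      reason = if (isTRUE(ens$eligible)) NA_character_ else ens$reason)
  }
  routing <- bind_rows(routing)
  say("sdm: %d of %d species modelable", sum(routing$sdm_route == "SDM"),
      nrow(routing))

  richness_mcp <- stage("stack", NULL, stack_ranges(ranges_mcp, method = "MCP"))
  richness_sdm <- stage("stack", NULL, stack_ranges(ranges_sdm, method = "SDM"))
  bd <- config$gradient$bin_deg
  gradients <- list(
    sdm_latitude = richness_gradient(richness_sdm, mask, "latitude", bd),
    sdm_longitude = richness_gradient(richness_sdm, mask, "longitude", bd),
    mcp_latitude = richness_gradient(richness_mcp, mask, "latitude", bd),
    mcp_longitude = richness_gradient(richness_mcp, mask, "longitude", bd))
  say("stack: max richness %d (MCP) / %d (SDM)",
      max(richness_mcp$values), max(richness_sdm$values))

  manifest <- list(
    package = "richstack",
    version = as.character(utils::packageVersion("richstack")),
    seed = seed,
    config = unclass(config),
    n_species = nrow(species),
    routing = routing,
    pca = list(n_retained = pca$n_retained,
               eigenvalues = pca$eigenvalues,
               variance_fraction = pca$variance_fraction))

  structure(
    list(study = study, mask = mask, pca = pca, pc_grid = pc_grid,
         sdm = sdms, ranges_mcp = ranges_mcp, ranges_sdm = ranges_sdm,
         richness_mcp = richness_mcp, richness_sdm = richness_sdm,
         gradients = gradients, routing = routing, manifest = manifest,
         config = config),
    class = "richness_run")
}

#' @export
print.richness_run <- function(x, ...) {
  cat(sprintf(
    "<richness_run> %d species; max richness %d (MCP) / %d (SDM); %d SDM-modeled, %d MCP polygons\n",
    nrow(x$routing), max(x$richness_mcp$values), max(x$richness_sdm$values),
    sum(x$routing$sdm_route == "SDM"), sum(x$routing$mcp_route == "MCP")))
  invisible(x)
}

#' @export
glance.richness_run <- function(x, ...) {
  eligible <- purrr::keep(x$sdm, ~ isTRUE(.x$eligible))
  auc <- purrr::map_dbl(eligible, ~ mean(.x$replicates$auc_test))
  tibble(
    n_species = nrow(x$routing),
    n_sdm = sum(x$routing$sdm_route == "SDM"),
    n_mcp = sum(x$routing$mcp_route == "MCP"),
    n_buffer_sdm_map = sum(x$routing$sdm_route == "buffer500"),
    mean_auc_test = mean(auc),
    median_auc_test = stats::median(auc),
    max_richness_mcp = max(x$richness_mcp$values),
    max_richness_sdm = max(x$richness_sdm$values),
    n_pcs_retained = x$pca$n_retained,
    variance_retained = sum(x$pca$variance_fraction[seq_len(x$pca$n_retained)]),
    lat_peak_sdm = gradient_peak(x$gradients$sdm_latitude),
    lat_peak_mcp = gradient_peak(x$gradients$mcp_latitude),
    lon_peak_sdm = gradient_peak(x$gradients$sdm_longitude))
}

#' Write the artifact bundle of a pipeline run
#'
#' Rasters go out in the ESRI ASCII dialect, tables as CSV, the manifest and
#' the PCA sidecar as JSON. The manifest records the config, the master
#' seed and the per-species routing with reasons, and suffices to re-execute
#' the run.
#'
#' @param run A [run_richness_pipeline] result.
#' @param dir Output directory (created if needed).
#' @param per_species Also write each species' binary range raster.
#' @return `dir`, invisibly.
#' @export
write_richness_run <- function(run, dir, per_species = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- run$study$grid
  wg <- function(mat, name) {
    write_ascii_grid(mat, g$lat_centers, g$lon_centers, g$cell_size,
                     file.path(dir, name))
  }
  wg(run$richness_mcp$values, "richness_mcp.asc")
  wg(run$richness_sdm$values, "richness_sdm.asc")
  wg(run$mask$mask * 1, "analysis_mask.asc")
  if (per_species) {
    for (sid in names(run$ranges_sdm)) {
      wg(run$ranges_sdm[[sid]]$cells * 1, sprintf("range_sdm_%s.asc", sid))
      wg(run$ranges_mcp[[sid]]$cells * 1, sprintf("range_mcp_%s.asc", sid))
    }
  }
  for (nm in names(run$gradients)) {
    write.csv(run$gradients[[nm]], file.path(dir, paste0("gradient_", nm, ".csv")),
              row.names = FALSE)
  }
  write_occurrences(run$study$occurrences, file.path(dir, "occurrences.csv"))
  write.csv(run$routing, file.path(dir, "routing.csv"), row.names = FALSE)
  write_env_pca(run$pca, file.path(dir, "pca.json"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
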