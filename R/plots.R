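#' Plot methods
#'
#' `autoplot()` methods render the main result types with ggplot2:
#' richness maps as raster tiles, gradient profiles as the layered area
#' chart used for latitudinal/longitudinal richness gradients (dark grey =
#' maximum, medium grey = quartiles, light grey = whiskers, solid line =
#' median), environmental stacks as faceted layer maps, and ensembles as
#' their mean suitability surface.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name richstack-plots
NULL

#' @rdname richstack-plots
#' @export
autoplot.richness_map <- function(object, ...) {
  df <- as_tibble(object) |> filter(.data$richness > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$richness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "species") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s richness overlay (%d species)",
                                  object$method, object$n_species),
                  x = "longitude (deg, 180-centered)", y = "latitude (deg)") +
    ggplot2::theme_minimal()
}

#' @rdname richstack-plots
#' @export
autoplot.gradient_profile <- function(object, ...) {
  df <- filter(object, .data$n_cells > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 0, ymax = .data$max),
                         fill = "grey30") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$whisker_low,
                                      ymax = .data$whisker_high),
                         fill = "grey80") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         fill = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.8) +
    ggplot2::labs(x = sprintf("%s (deg, %g-deg bins)", attr(object, "axis"),
                              attr(object, "bin_deg")),
                  y = "species richness") +
    ggplot2::theme_minimal()
}

#' @rdname richstack-plots
#' @export
autoplot.env_grid <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(cols = -c("cell", "lon", "lat", "valid"),
                        names_to = "layer", values_to = "value") |>
    filter(.data$valid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @rdname richstack-plots
#' @export
autoplot.sdm_ensemble <- function(object, ...) {
  if (!isTRUE(object$eligible)) abort("ensemble is not modelable; nothing to plot.")
  nr <- length(object$lat_centers)
  nc <- length(object$lon_centers)
  df <- tibble(lon = rep(object$lon_centers, each = nr),
               lat = rep(object$lat_centers, times = nc),
               p = as.vector(object$mean_probability)) |>
    filter(!is.na(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "suitability", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("species '%s' mean suitability (threshold %.3f)",
                                  object$species_id, object$threshold)) +
    ggplot2::theme_minimal()
}

#' @export
plot.richness_map <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.gradient_profile <- function(x, ...) print(autoplot(x, ...))
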