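# ggplot2 views of footprints and risk surfaces.

fortify_component <- function(fps, component) {
  purrr::imap_dfr(fps[[component]], function(g, i) {
    df <- geom_to_df(g)
    if (nrow(df) == 0) return(df)
    df$spill_id <- as.character(fps$spill_id[i])
    df$component <- component
    df$group <- paste(fps$spill_id[i], component, df$ring)
    df
  })
}

#' Plot spill footprints
#'
#' Draws the three footprint components per spill over an optional DEM
#' hillshade-style raster: start accumulation zone (purple), flow corridor
#' (green), end accumulation zone (orange).
#'
#' @param fps An `sfer_footprint_set`.
#' @param dem Optional `elevation_grid` drawn underneath.
#' @return A ggplot object.
#' @export
plot_footprints <- function(fps, dem = NULL) {
  comp <- dplyr::bind_rows(
    fortify_component(fps, "start_zone"),
    fortify_component(fps, "corridor"),
    fortify_component(fps, "end_zone")
  )
  p <- ggplot2::ggplot()
  if (!is.null(dem)) {
    idx <- which(!is.na(dem$values), arr.ind = TRUE)
    ctr <- cell_center(dem, idx[, 1], idx[, 2])
    dem_df <- tibble::tibble(x = ctr$x, y = ctr$y, z = dem$values[idx])
    p <- p + ggplot2::geom_raster(
      data = dem_df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$z)) +
      ggplot2::scale_fill_gradient(low = "grey20", high = "grey95",
                                   name = "elevation (m)")
  }
  p +
    ggplot2::geom_polygon(
      data = comp,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$group,
                   colour = .data$component),
      fill = NA, linewidth = 0.5) +
    ggplot2::scale_colour_manual(
      values = c(start_zone = "#7b3294", corridor = "#008837",
                 end_zone = "#e66101"),
      name = "component") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_footprints
#' @param object An `sfer_footprint_set`.
#' @param ... Passed on (unused).
#' @export
autoplot.sfer_footprint_set <- function(object, ...) plot_footprints(object)

#' Choropleth of zone-level risk
#'
#' Fills each zone by its quantile class (when classified) or raw risk
#' value, the map style used to compare tracts or subwatersheds.
#'
#' @param zones A `zone_table`.
#' @param rows Risk rows for those zones (matched on `zone_id`).
#' @return A ggplot object.
#' @export
plot_risk_map <- function(zones, rows) {
  use_class <- !all(is.na(rows$quantile_class))
  val <- if (use_class) rows$quantile_class else rows$value
  names(val) <- rows$zone_id
  df <- purrr::imap_dfr(zones$geometry, function(g, i) {
    d <- geom_to_df(g)
    d$zone_id <- zones$zone_id[i]
    d$group <- paste(zones$zone_id[i], d$ring)
    d$fill_val <- val[[zones$zone_id[i]]]
    d
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$group,
                                        fill = .data$fill_val)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
  if (use_class) {
    p + ggplot2::scale_fill_viridis_c(name = "quantile class",
                                      breaks = sort(unique(val)))
  } else {
    p + ggplot2::scale_fill_viridis_c(name = unique(rows$metric)[1])
  }
}
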