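# Readers and writers for the pipeline's exchange formats: ESRI ASCII
# grids for rasters, GeoJSON for vector layers, CSV for tables, YAML for
# run configuration. All inputs to one pipeline run must share a single
# projected, metre-unit CRS; geographic coordinates are rejected up front.

crs_of <- function(x) {
  if (inherits(x, "elevation_grid") || inherits(x, "flow_grid")) return(x$crs)
  attr(x, "crs")
}

check_crs_match <- function(...) {
  labels <- unique(unlist(lapply(list(...), crs_of)))
  labels <- labels[!is.null(labels) & !is.na(labels)]
  if (length(labels) > 1L) {
    stop("inputs carry different CRS labels (", paste(labels, collapse = ", "),
         "); reproject everything to one projected CRS first", call. = FALSE)
  }
  invisible(labels)
}

#' Read a DEM from an ESRI ASCII grid
#'
#' Parses the `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header followed by north-to-south rows of elevations. ASCII grids carry
#' no CRS, so the caller asserts one via `crs`; geographic labels are
#' rejected with an instruction to reproject.
#'
#' @param path File path (`.asc` / ESRI ASCII grid).
#' @param crs Label of the projected, metre-unit CRS the grid lives in.
#' @return An `elevation_grid`.
#' @export
read_dem <- function(path, crs = "local-metric") {
  if (grepl("\\.(tif|tiff|gpkg|img)$", tolower(path))) {
    stop("only ESRI ASCII grids (.asc) are supported; export the raster ",
         "to ASCII grid format first", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ESRI ASCII grid header in ", path, call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(paste(lines[-seq_len(i)], collapse = " ")), "\\s+"))))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc || anyNA(vals)) {
    stop("ESRI ASCII grid body does not parse to ", nr, " x ", nc,
         " numbers in ", path, call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  elevation_grid(m, origin_x = hdr$xllcorner,
                 origin_y = hdr$yllcorner + nr * hdr$cellsize,
                 cell_size = hdr$cellsize, crs = crs)
}

#' Write a grid as an ESRI ASCII grid
#'
#' `write_dem_ascii()` writes elevations; `write_flowdir_ascii()` writes a
#' flow-direction grid using the ESRI D8 code convention (E=1, SE=2, S=4,
#' SW=8, W=16, NW=32, N=64, NE=128, pit=0) for interoperability.
#'
#' @param grid An `elevation_grid` or `flow_grid`.
#' @param path Output path.
#' @param nodata Sentinel written for nodata cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_dem_ascii <- function(grid, path, nodata = -9999) {
  write_ascii_grid(grid$values, grid, path, nodata)
}

#' @rdname write_dem_ascii
#' @export
write_flowdir_ascii <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "flow_grid"))
  esri <- grid$codes
  pos <- !is.na(esri) & esri > 0L
  esri[pos] <- D8_ESRI[grid$codes[pos]]
  write_ascii_grid(esri, grid, path, nodata)
}

write_ascii_grid <- function(values, grid, path, nodata) {
  m <- values
  m[is.na(m)] <- nodata
  hdr <- c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$origin_x, digits = 15)),
    paste("yllcorner", format(grid$origin_y - grid$n_rows * grid$cell_size,
                              digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("NODATA_value", nodata)
  )
  body <- apply(m, 1L, function(r) paste(format(r, digits = 15, trim = TRUE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

GALLON_L <- 3.78541

#' Read a spill catalog from CSV
#'
#' Expects a header with columns `id` (or `spill_id`), `x`, `y`, `quantity`
#' and optionally `cause`/`primary_cause` and `valid`. Rows whose quantity
#' or coordinates do not parse are kept as invalid drafts so that
#' [validate_spills()] can count and report them.
#'
#' @param path CSV path (comma-separated, UTF-8, header mandatory).
#' @param gallons Set `TRUE` when volumes are reported in US gallons; they
#'   are converted to litres (x 3.78541). The sizing formula is not
#'   unit-invariant, so quantities must end up in litres.
#' @return A tibble of spill drafts.
#' @export
read_spills <- function(path, gallons = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df) <- tolower(names(df))
  if ("id" %in% names(df) && !"spill_id" %in% names(df)) {
    names(df)[names(df) == "id"] <- "spill_id"
  }
  if ("cause" %in% names(df) && !"primary_cause" %in% names(df)) {
    names(df)[names(df) == "cause"] <- "primary_cause"
  }
  miss <- setdiff(c("spill_id", "x", "y", "quantity"), names(df))
  if (length(miss)) {
    stop("spill CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    spill_id = df$spill_id,
    x = suppressWarnings(as.numeric(df$x)),
    y = suppressWarnings(as.numeric(df$y)),
    quantity = suppressWarnings(as.numeric(df$quantity))
  )
  if (gallons) out$quantity <- out$quantity * GALLON_L
  if ("primary_cause" %in% names(df)) out$primary_cause <- df$primary_cause
  if ("valid" %in% names(df)) {
    out$valid <- as.logical(df$valid)
    out$valid[is.na(out$valid)] <- TRUE
  }
  out
}

#' Write spill records to CSV
#' @param spills A spill tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spills <- function(spills, path) {
  utils::write.csv(spills, path, row.names = FALSE)
  invisible(path)
}

# ---- GeoJSON ------------------------------------------------------------

geom_to_geojson <- function(g) {
  # each ring becomes one polygon of a MultiPolygon; rings follow the
  # even-odd convention, so containment survives a package round-trip
  polys <- lapply(unclass(g), function(r) {
    ring <- cbind(c(r$x, r$x[1]), c(r$y, r$y[1]))
    list(apply(ring, 1, function(p) p, simplify = FALSE))
  })
  list(type = "MultiPolygon",
       coordinates = lapply(polys, function(p) {
         list(lapply(p[[1]], function(v) as.numeric(v)))
       }))
}

geojson_to_geom <- function(geometry) {
  rings <- list()
  push <- function(coords) {
    for (ring in coords) {
      m <- do.call(rbind, lapply(ring, as.numeric))
      n <- nrow(m)
      if (n >= 4L && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
      if (nrow(m) >= 3L) {
        rings[[length(rings) + 1L]] <<- list(x = m[, 1], y = m[, 2])
      }
    }
  }
  if (geometry$type == "Polygon") {
    push(geometry$coordinates)
  } else if (geometry$type == "MultiPolygon") {
    for (poly in geometry$coordinates) push(poly)
  } else {
    stop("unsupported GeoJSON geometry type: ", geometry$type, call. = FALSE)
  }
  new_geom(rings)
}

#' Read zones from a GeoJSON file
#'
#' Reads a FeatureCollection of Polygon/MultiPolygon features. `zone_id` is
#' taken from the `zone_id`, `id` or `name` property (in that order);
#' `population` from the property of the same name when present. Features
#' with degenerate geometry raise an error naming the feature.
#'
#' @param path GeoJSON path.
#' @param kind `"tract"` or `"subwatershed"`.
#' @param crs CRS label the coordinates live in (GeoJSON files produced by
#'   this package store it in the top-level `crs_label` member).
#' @return A [zone_table()].
#' @export
read_zones <- function(path, kind = c("tract", "subwatershed"), crs = NULL) {
  kind <- match.arg(kind)
  gj <- jsonlite::read_json(path)
  crs <- crs %||% gj$crs_label %||% "local-metric"
  feats <- gj$features
  ids <- character(0); geoms <- list(); pops <- numeric(0)
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    props <- f$properties %||% list()
    id <- props$zone_id %||% props$id %||% props$name %||% as.character(i)
    g <- geojson_to_geom(f$geometry)
    if (geom_is_empty(g) || geom_area(g) <= 0) {
      stop("feature '", id, "' in ", path, " has invalid or empty geometry",
           call. = FALSE)
    }
    ids <- c(ids, as.character(id))
    geoms <- c(geoms, list(g))
    pops <- c(pops, as.numeric(props$population %||% NA_real_))
  }
  zone_table(ids, kind, geoms, pops, crs = crs)
}

#' Write zones or footprints to GeoJSON
#'
#' `write_zones()` writes a `zone_table`; `write_footprints()` writes one
#' feature per spill from an `sfer_footprint_set` for a chosen component
#' layer, carrying `spill_id`, `quantity`, `buffer_size_m` and
#' `termination_reason` properties. A `values` data frame (e.g. classified
#' risk rows) can be joined onto zones by `zone_id` for choropleth export.
#'
#' @param zones A `zone_table`.
#' @param path Output path.
#' @param values Optional data frame with a `zone_id` column to join.
#' @return `path`, invisibly.
#' @export
write_zones <- function(zones, path, values = NULL) {
  props <- zones[setdiff(names(zones), "geometry")]
  if (!is.null(values)) {
    props <- dplyr::left_join(props, values, by = "zone_id")
  }
  feats <- lapply(seq_len(nrow(zones)), function(i) {
    list(type = "Feature",
         properties = as.list(props[i, , drop = FALSE]),
         geometry = geom_to_geojson(zones$geometry[[i]]))
  })
  out <- list(type = "FeatureCollection",
              crs_label = crs_of(zones) %||% "local-metric",
              features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_zones
#' @param footprints An `sfer_footprint_set`.
#' @param layer Which component polygon to write.
#' @export
write_footprints <- function(footprints, path,
                             layer = c("footprint", "start_zone", "corridor",
                                       "end_zone")) {
  layer <- match.arg(layer)
  feats <- lapply(seq_len(nrow(footprints)), function(i) {
    list(type = "Feature",
         properties = list(
           spill_id = footprints$spill_id[i],
           quantity = footprints$quantity[i],
           buffer_size_m = footprints$buffer_size_m[i],
           termination_reason = footprints$termination_reason[i]),
         geometry = geom_to_geojson(footprints[[layer]][[i]]))
  })
  out <- list(type = "FeatureCollection",
              crs_label = crs_of(footprints) %||% "local-metric",
              layer = layer, features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read footprint polygons from a GeoJSON layer written by [write_footprints()]
#' @param path GeoJSON path.
#' @return A tibble with `spill_id`, scalar properties and a `footprint`
#'   list column of geometries.
#' @export
read_footprints <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  out <- tibble::tibble(
    spill_id = vapply(feats, function(f) as.character(f$properties$spill_id),
                      character(1)),
    quantity = vapply(feats, function(f) as.numeric(f$properties$quantity),
                      numeric(1)),
    buffer_size_m = vapply(feats, function(f)
      as.numeric(f$properties$buffer_size_m), numeric(1)),
    termination_reason = vapply(feats, function(f)
      as.character(f$properties$termination_reason), character(1)),
    footprint = lapply(feats, function(f) geojson_to_geom(f$geometry))
  )
  attr(out, "crs") <- gj$crs_label %||% "local-metric"
  class(out) <- c("sfer_footprint_set", class(out))
  out
}

#' Read a population raster from an ESRI ASCII grid
#'
#' Converts a person-count grid (LandScan-style) into buffered points: one
#' disc per non-nodata cell, carrying the cell's count.
#'
#' @param path ESRI ASCII grid of per-cell person counts.
#' @param pop_buffer Disc radius in metres (default 35).
#' @param crs CRS label.
#' @return A [population_cells()] tibble.
#' @export
read_population <- function(path, pop_buffer = 35, crs = "local-metric") {
  g <- read_dem(path, crs = crs)
  pts <- grid_points(g, point_buffer = pop_buffer)
  population_cells(pts$x, pts$y, pts$elevation, pop_buffer = pop_buffer,
                   crs = crs)
}

#' Write risk rows to CSV
#' @param rows A tibble of risk rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read and write run configuration
#'
#' YAML configuration mirroring [sizing_config()] plus `edge_policy`,
#' `mode`, `k` and `seed`. Missing entries take the package defaults.
#'
#' @param path YAML path.
#' @return `read_run_config()`: a list with elements `sizing`
#'   (a [sizing_config()]), `edge_policy`, `mode`, `k`, `seed`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  sz <- sizing_config(
    max_buffer_m = raw$max_buffer_m %||% 50,
    min_buffer_m = raw$min_buffer_m,
    traceline_buffer_m = raw$traceline_buffer_m %||% 15,
    point_buffer_m = raw$point_buffer_m %||% 4.5,
    concavity = raw$concavity %||% 0.8
  )
  list(sizing = sz,
       edge_policy = raw$edge_policy %||% "stop_at_edge",
       mode = raw$mode %||% "union",
       k = raw$k %||% 5L,
       seed = raw$seed %||% 1L)
}

#' @rdname read_run_config
#' @param config A configuration list as returned by [read_run_config()].
#' @export
write_run_config <- function(config, path) {
  flat <- c(unclass(config$sizing),
            config[setdiff(names(config), "sizing")])
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}
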