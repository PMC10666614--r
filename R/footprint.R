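# Spill footprints: a volume-scaled accumulation zone around the spill
# origin, the D8-traced flowpath buffered into a worst-case corridor, and a
# second accumulation zone around the first pooling point.

#' Footprint sizing configuration
#'
#' Tunable lengths controlling footprint construction. All lengths are in
#' metres; quantities are in litres.
#'
#' @param max_buffer_m Cap on the accumulation-zone buffer radius (default
#'   50 m): the radius assigned to the largest spill in the catalog.
#' @param min_buffer_m Floor on the buffer radius. `NULL` (default) resolves
#'   to one DEM cell size at build time, so a zone always spans at least one
#'   cell; the raw log-proportional formula can return zero or less for
#'   quantities of one litre or under.
#' @param traceline_buffer_m Corridor half-width around the traced flowpath
#'   (default 15 m, a worst-case path width).
#' @param point_buffer_m Radius of the disc drawn around each elevation
#'   point (default 4.5 m), standing in for the area of its source cell.
#' @param concavity Concave-hull tightness in (0, 1]; 1 gives the convex
#'   hull (default 0.8).
#' @return A `sizing_config` list.
#' @export
sizing_config <- function(max_buffer_m = 50, min_buffer_m = NULL,
                          traceline_buffer_m = 15, point_buffer_m = 4.5,
                          concavity = 0.8) {
  stopifnot(max_buffer_m > 0, traceline_buffer_m > 0, point_buffer_m > 0,
            concavity > 0, concavity <= 1)
  if (!is.null(min_buffer_m)) {
    stopifnot(min_buffer_m > 0, min_buffer_m <= max_buffer_m)
  }
  structure(
    list(max_buffer_m = max_buffer_m, min_buffer_m = min_buffer_m,
         traceline_buffer_m = traceline_buffer_m,
         point_buffer_m = point_buffer_m, concavity = concavity),
    class = "sizing_config"
  )
}

resolve_min_buffer <- function(cfg, cell_size = NULL) {
  if (!is.null(cfg$min_buffer_m)) return(cfg$min_buffer_m)
  if (!is.null(cell_size)) return(min(cell_size, cfg$max_buffer_m))
  0
}

#' Volume-proportional buffer size
#'
#' The accumulation-zone radius for a spill of `q` litres scales with the
#' log of the volume relative to the largest volume in the catalog:
#' `s = log(q) / (log(q_max) / max_buffer_m)`, clamped to
#' `[min_buffer_m, max_buffer_m]`. Taking logs damps the effect of
#' outlier volumes; the ratio of logs makes the result base-invariant but
#' not unit-invariant, so volumes must be supplied in litres.
#'
#' @param q Spill volume(s) in litres, `0 < q <= q_max` (vectorised).
#' @param q_max Largest volume in the catalog, litres, greater than 1.
#' @param cfg A [sizing_config()].
#' @param cell_size Optional DEM cell size used to resolve a `NULL`
#'   `min_buffer_m`.
#' @return Buffer radius/radii in metres.
#' @examples
#' buffer_size(10000, 10000)  # the cap: 50 m
#' buffer_size(100, 10000)    # half the cap on the log scale: 25 m
#' @export
buffer_size <- function(q, q_max, cfg = sizing_config(), cell_size = NULL) {
  if (!is.numeric(q_max) || length(q_max) != 1L || q_max <= 1) {
    stop("q_max must exceed 1 litre (log(q_max) must be positive); ",
         "a catalog whose largest spill is <= 1 litre cannot be scaled",
         call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("spill quantities must be positive and finite", call. = FALSE)
  }
  if (any(q > q_max)) {
    stop("q exceeds q_max: q_max must be the catalog maximum", call. = FALSE)
  }
  s <- log(q) / (log(q_max) / cfg$max_buffer_m)
  lo <- resolve_min_buffer(cfg, cell_size)
  pmin(cfg$max_buffer_m, pmax(lo, s))
}

#' Validate a table of spill records
#'
#' Splits draft spill records into usable and dropped sets. A record is
#' dropped when its coordinates are missing or non-finite (location/geocode
#' failure), when its quantity is missing, non-finite or not positive, or
#' when it arrives explicitly flagged unusable via a `valid` column.
#'
#' @param drafts A data frame with columns `spill_id`, `x`, `y`, `quantity`,
#'   optionally `primary_cause` and `valid`.
#' @return A list with `kept` (tibble), `dropped` (tibble with a
#'   `drop_reason` column) and `report` (tibble of reason counts; the kept
#'   and dropped counts always sum to the input size).
#' @export
validate_spills <- function(drafts) {
  drafts <- tibble::as_tibble(drafts)
  n <- nrow(drafts)
  if (!"spill_id" %in% names(drafts)) {
    drafts$spill_id <- if (n) seq_len(n) else integer(0)
  }
  for (col in c("x", "y", "quantity")) {
    if (!col %in% names(drafts)) drafts[[col]] <- rep(NA_real_, n)
  }
  reason <- rep(NA_character_, n)
  flagged <- if ("valid" %in% names(drafts)) !is.na(drafts$valid) & !drafts$valid
             else rep(FALSE, n)
  bad_xy <- !is.finite(drafts$x) | !is.finite(drafts$y)
  bad_q <- !is.finite(drafts$quantity) | drafts$quantity <= 0
  reason[bad_q] <- "quantity"
  reason[bad_xy] <- "coordinates"           # location problems take priority
  reason[flagged & is.na(reason)] <- "flagged"
  dropped <- drafts[!is.na(reason), , drop = FALSE]
  dropped$drop_reason <- reason[!is.na(reason)]
  kept <- drafts[is.na(reason), , drop = FALSE]
  report <- tibble::tibble(
    reason = c("kept", sort(unique(dropped$drop_reason))),
    count = c(nrow(kept),
              as.integer(table(dropped$drop_reason)[sort(unique(dropped$drop_reason))]))
  )
  list(kept = kept, dropped = dropped, report = report)
}

#' Accumulation zone around a start or end point
#'
#' Builds the pooling polygon around a spill start or flowpath end point:
#' a potential zone (disc of the volume-scaled radius) is drawn around the
#' centre, the buffered elevation points strictly below the centre's
#' elevation whose discs reach into the potential zone are collected
#' together with the centre's own disc, and their concave hull, clipped to
#' the potential zone, is returned. The centre disc guarantees the zone is
#' never empty and always contains the centre point.
#'
#' @param center_x,center_y Zone centre coordinates (m).
#' @param center_elev Elevation of the centre (m).
#' @param points Buffered elevation points from [grid_points()].
#' @param radius Potential-zone radius in metres, positive.
#' @param cfg A [sizing_config()].
#' @return A polygon geometry.
#' @export
accumulation_zone <- function(center_x, center_y, center_elev, points,
                              radius, cfg = sizing_config()) {
  if (!is.numeric(radius) || radius <= 0) {
    stop("radius must be a positive length in metres", call. = FALSE)
  }
  stopifnot(nrow(points) > 0, is.finite(center_elev))
  pb <- attr(points, "point_buffer") %||% cfg$point_buffer_m
  potential <- geom_circle(center_x, center_y, radius)

  d <- sqrt((points$x - center_x)^2 + (points$y - center_y)^2)
  sel <- points$elevation < center_elev & d <= radius + pb
  # the centre always contributes its own disc
  th <- seq(0, 2 * pi, length.out = 25L)[-25L]
  cloud_x <- center_x + pb * cos(th)
  cloud_y <- center_y + pb * sin(th)
  if (any(sel)) {
    px <- points$x[sel]; py <- points$y[sel]
    cloud_x <- c(cloud_x, rep(px, each = 24L) + pb * cos(th))
    cloud_y <- c(cloud_y, rep(py, each = 24L) + pb * sin(th))
  }
  hull <- concave_hull(cloud_x, cloud_y, cfg$concavity)
  zone <- geom_intersection(hull, potential)
  center_disc <- geom_intersection(geom_circle(center_x, center_y, pb),
                                   potential)
  zone <- geom_union(zone, center_disc)
  if (geom_is_empty(zone)) zone <- center_disc
  zone
}

#' Build the footprint of one spill
#'
#' Chains the model's three components: the flowpath is traced downslope
#' from the spill origin to its first pooling cell, accumulation zones of
#' the volume-scaled radius are built at the origin and at the trace end,
#' and the traced line is buffered into the corridor. The footprint is the
#' union of the three. A spill starting on a pit has an empty corridor and
#' coincident start/end zones. Footprints are a function of location,
#' volume and terrain only, so re-running identical inputs reproduces the
#' identical footprint.
#'
#' @param spill One spill record: a list or one-row data frame with
#'   `spill_id`, `x`, `y`, `quantity`.
#' @param dem An `elevation_grid`.
#' @param fdir The matching `flow_grid`.
#' @param q_max Largest quantity in the catalog (litres).
#' @param cfg A [sizing_config()].
#' @param points Optional precomputed [grid_points()] for `dem` (computed on
#'   the fly when omitted).
#' @return An `sfer_footprint`: list with the three component polygons, the
#'   dissolved `footprint`, the trace, `buffer_size_m`, `end_x`, `end_y` and
#'   `termination_reason`.
#' @export
build_footprint <- function(spill, dem, fdir, q_max, cfg = sizing_config(),
                            points = NULL) {
  spill <- as.list(spill)
  if (!is.finite(spill$x) || !is.finite(spill$y) ||
      !is.finite(spill$quantity) || spill$quantity <= 0) {
    stop("invalid spill record; run validate_spills() first", call. = FALSE)
  }
  if (is.null(points)) points <- grid_points(dem, cfg$point_buffer_m)
  s <- buffer_size(spill$quantity, q_max, cfg, cell_size = dem$cell_size)

  trace <- trace_flowpath(fdir, dem, spill$x, spill$y)
  start_elev <- elevation_at(dem, spill$x, spill$y)

  start_zone <- accumulation_zone(spill$x, spill$y, start_elev, points, s, cfg)
  end_zone <- accumulation_zone(trace$end_x, trace$end_y, trace$end_elevation,
                                points, s, cfg)
  corridor <- if (nrow(trace$path) >= 2L) {
    geom_buffer_path(trace$path$x, trace$path$y, cfg$traceline_buffer_m)
  } else {
    geom_empty()
  }
  footprint <- geom_union_all(list(start_zone, corridor, end_zone))

  structure(
    list(spill_id = spill$spill_id, x = spill$x, y = spill$y,
         quantity = spill$quantity, buffer_size_m = s,
         start_zone = start_zone, corridor = corridor, end_zone = end_zone,
         footprint = footprint, trace = trace,
         end_x = trace$end_x, end_y = trace$end_y,
         termination_reason = trace$reason),
    class = "sfer_footprint"
  )
}

#' @export
print.sfer_footprint <- function(x, ...) {
  cat(sprintf(
    "<sfer_footprint %s: %.0f L, buffer %.1f m, path %.1f m (%s), area %.0f m^2>\n",
    format(x$spill_id), x$quantity, x$buffer_size_m, x$trace$length_m,
    x$termination_reason, geom_area(x$footprint)))
  invisible(x)
}

#' Build footprints for a spill catalog
#'
#' Validates the catalog, derives the flow-direction grid once, and builds
#' one footprint per usable spill. The catalog maximum quantity anchors the
#' volume-proportional sizing for every spill.
#'
#' @param spills Data frame of spill records (`spill_id`, `x`, `y`,
#'   `quantity`, optionally `primary_cause`, `valid`).
#' @param dem An `elevation_grid`.
#' @param cfg A [sizing_config()].
#' @param edge_policy Passed to [flow_direction()].
#' @param q_max Catalog maximum quantity; defaults to the maximum over the
#'   kept records.
#' @return An `sfer_footprint_set`: a tibble with one row per kept spill,
#'   scalar columns (`spill_id`, `x`, `y`, `quantity`, `buffer_size_m`,
#'   `end_x`, `end_y`, `termination_reason`, `path_length_m`, `area_m2`)
#'   and list columns (`start_zone`, `corridor`, `end_zone`, `footprint`,
#'   `trace`). The validation report is attached as attribute
#'   `validation`.
#' @export
build_footprints <- function(spills, dem, cfg = sizing_config(),
                             edge_policy = c("stop_at_edge", "flow_outward"),
                             q_max = NULL) {
  edge_policy <- match.arg(edge_policy)
  val <- validate_spills(spills)
  kept <- val$kept
  fdir <- flow_direction(dem, edge_policy)
  points <- grid_points(dem, cfg$point_buffer_m)
  if (is.null(q_max)) {
    q_max <- if (nrow(kept)) max(kept$quantity) else NA_real_
  }
  fps <- purrr::pmap(list(kept$spill_id, kept$x, kept$y, kept$quantity),
                     function(id, x, y, q) {
                       build_footprint(list(spill_id = id, x = x, y = y,
                                            quantity = q),
                                       dem, fdir, q_max, cfg, points)
                     })
  out <- tibble::tibble(
    spill_id = kept$spill_id, x = kept$x, y = kept$y,
    quantity = kept$quantity,
    buffer_size_m = vapply(fps, `[[`, numeric(1), "buffer_size_m"),
    end_x = vapply(fps, `[[`, numeric(1), "end_x"),
    end_y = vapply(fps, `[[`, numeric(1), "end_y"),
    termination_reason = vapply(fps, `[[`, character(1), "termination_reason"),
    path_length_m = vapply(fps, function(f) f$trace$length_m, numeric(1)),
    area_m2 = vapply(fps, function(f) geom_area(f$footprint), numeric(1)),
    start_zone = lapply(fps, `[[`, "start_zone"),
    corridor = lapply(fps, `[[`, "corridor"),
    end_zone = lapply(fps, `[[`, "end_zone"),
    footprint = lapply(fps, `[[`, "footprint"),
    trace = lapply(fps, `[[`, "trace")
  )
  class(out) <- c("sfer_footprint_set", class(out))
  attr(out, "validation") <- val$report
  attr(out, "crs") <- dem$crs
  attr(out, "q_max") <- q_max
  out
}
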