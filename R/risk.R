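# Zone-level exposure risk from spill footprints.
#
# pRisk: estimated persons inside a census tract's unioned footprints over
# the tract's resident population. lRisk: fraction of a subwatershed's area
# covered by unioned footprints. Union semantics stop repeated spills at
# one location from being counted more than once; the chronic_sum mode
# keeps the multiplicity instead, for users focused on repeat offenders.

#' Construct a zone table
#'
#' Zones are administrative or hydrologic polygons: census-tract-like zones
#' carry a resident population; subwatershed-like zones do not.
#'
#' @param zone_id Identifiers.
#' @param kind `"tract"` or `"subwatershed"` (recycled).
#' @param geometry List of polygon geometries (`sfer_geom`).
#' @param population Person counts (required for tracts; `NA` otherwise).
#' @param ... Further attribute columns (e.g. under-5 counts, mean
#'   imperviousness), recycled to the number of zones.
#' @param crs CRS label the geometries live in.
#' @return A `zone_table` tibble.
#' @export
zone_table <- function(zone_id, kind, geometry, population = NA_real_, ...,
                       crs = "local-metric") {
  kind <- match.arg(kind, c("tract", "subwatershed"), several.ok = FALSE)
  stopifnot(is.list(geometry),
            all(vapply(geometry, inherits, logical(1), "sfer_geom")))
  if (any(vapply(geometry, geom_is_empty, logical(1)))) {
    stop("zone geometries must be non-empty", call. = FALSE)
  }
  if (any(!is.na(population) & population < 0)) {
    stop("population must be non-negative", call. = FALSE)
  }
  check_projected_crs(crs)
  out <- tibble::tibble(zone_id = zone_id, kind = kind,
                        geometry = geometry, population = population, ...)
  attr(out, "crs") <- crs
  class(out) <- c("zone_table", class(out))
  out
}

#' Construct a population cell set
#'
#' LandScan-style population cells converted to buffered points: each cell
#' centre carries its person count and a disc whose radius (default 35 m)
#' approximates the cell's reach. A cell's count is attributed in full to
#' any footprint its disc touches; no areal weighting is applied.
#'
#' @param x,y Cell-centre coordinates (m).
#' @param count Persons per cell, non-negative.
#' @param pop_buffer Disc radius in metres (default 35).
#' @param crs CRS label.
#' @return A `population_cells` tibble with columns `x`, `y`, `count`.
#' @export
population_cells <- function(x, y, count, pop_buffer = 35,
                             crs = "local-metric") {
  stopifnot(length(x) == length(y), length(x) == length(count),
            all(count >= 0), pop_buffer > 0)
  check_projected_crs(crs)
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        count = as.numeric(count))
  attr(out, "pop_buffer") <- pop_buffer
  attr(out, "crs") <- crs
  class(out) <- c("population_cells", class(out))
  out
}

#' Union or enumerate footprint geometries
#'
#' `mode = "union"` dissolves all footprints into one geometry so that
#' overlapping or repeated spills are counted once in the risk metrics.
#' `mode = "chronic_sum"` returns the undissolved list, retaining overlap
#' multiplicity for chronic-spill accounting.
#'
#' @param footprints An `sfer_footprint_set`, a single footprint, or a list
#'   of footprint geometries.
#' @param mode `"union"` (default) or `"chronic_sum"`.
#' @return A geometry (`union`) or a list of geometries (`chronic_sum`);
#'   empty input gives an empty geometry / empty list.
#' @export
union_footprints <- function(footprints, mode = c("union", "chronic_sum")) {
  mode <- match.arg(mode)
  gs <- footprint_geoms(footprints)
  if (mode == "union") geom_union_all(gs) else gs
}

new_risk_rows <- function(zone_id, metric, value, exposed_population = NA_real_,
                          exposed_area = NA_real_, n_spills, flag = NA_character_) {
  tibble::tibble(zone_id = zone_id, metric = metric, value = value,
                 exposed_population = exposed_population,
                 exposed_area = exposed_area, n_spills = n_spills,
                 quantile_class = NA_integer_, flag = flag)
}

#' Population exposure risk per census tract
#'
#' For each tract, the footprints are combined (see [union_footprints()]),
#' intersected with the tract polygon, and every population cell whose disc
#' touches the resulting geometry contributes its full person count to the
#' exposed population. The metric is exposed persons over tract population.
#' Because the numerator comes from gridded ambient-population counts and
#' the denominator from the census, values above 1 can occur; they are
#' reported with a warning, not clamped. A zero-population tract with a
#' positive exposure is flagged `"undefined"`.
#'
#' @param footprints Footprints (see [union_footprints()]).
#' @param tracts A `zone_table` of kind `"tract"` with populations.
#' @param pop A [population_cells()] set.
#' @param mode `"union"` or `"chronic_sum"`.
#' @return A tibble of risk rows: `zone_id`, `metric = "pRisk"`, `value`,
#'   `exposed_population`, `n_spills`, `quantile_class` (unset), `flag`.
#' @export
population_risk <- function(footprints, tracts, pop,
                            mode = c("union", "chronic_sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pop, "population_cells"))
  if (!all(tracts$kind == "tract")) {
    stop("population_risk() expects zones of kind 'tract'", call. = FALSE)
  }
  if (any(is.na(tracts$population))) {
    stop("every tract needs a population attribute", call. = FALSE)
  }
  check_crs_match(footprints, tracts, pop)
  r <- attr(pop, "pop_buffer")
  gs <- footprint_geoms(footprints)
  dissolved <- if (mode == "union") list(geom_union_all(gs)) else gs

  rows <- purrr::pmap_dfr(
    list(tracts$zone_id, tracts$geometry, tracts$population),
    function(id, zgeom, zpop) {
      exposed <- 0
      for (g in dissolved) {
        clipped <- geom_intersection(g, zgeom)
        if (geom_is_empty(clipped)) next
        hit <- geom_distance_points(clipped, pop$x, pop$y) <= r
        exposed <- exposed + sum(pop$count[hit])
      }
      n_spills <- sum(vapply(gs, function(g) {
        !geom_is_empty(geom_intersection(g, zgeom))
      }, logical(1)))
      if (zpop > 0) {
        value <- exposed / zpop
        flag <- NA_character_
      } else if (exposed == 0) {
        value <- 0
        flag <- NA_character_
      } else {
        value <- NA_real_
        flag <- "undefined"
      }
      new_risk_rows(id, "pRisk", value, exposed_population = exposed,
                    n_spills = n_spills, flag = flag)
    })
  if (any(!is.na(rows$value) & rows$value > 1)) {
    warning("pRisk above 1 in ", sum(!is.na(rows$value) & rows$value > 1),
            " tract(s): ambient-population counts exceed the census ",
            "population there", call. = FALSE)
  }
  rows
}

#' Land exposure risk per subwatershed
#'
#' The fraction of each subwatershed's area covered by the (unioned)
#' footprints: `area(footprints intersect zone) / area(zone)`, in `[0, 1]`
#' under union semantics. In `chronic_sum` mode overlapping footprints are
#' counted with multiplicity, so the ratio can exceed 1.
#'
#' @param footprints Footprints (see [union_footprints()]).
#' @param subwatersheds A `zone_table` of kind `"subwatershed"`.
#' @param mode `"union"` or `"chronic_sum"`.
#' @return A tibble of risk rows: `zone_id`, `metric = "lRisk"`, `value`,
#'   `exposed_area`, `n_spills`, `quantile_class` (unset), `flag`.
#' @export
land_risk <- function(footprints, subwatersheds,
                      mode = c("union", "chronic_sum")) {
  mode <- match.arg(mode)
  if (!all(subwatersheds$kind == "subwatershed")) {
    stop("land_risk() expects zones of kind 'subwatershed'", call. = FALSE)
  }
  check_crs_match(footprints, subwatersheds)
  gs <- footprint_geoms(footprints)
  dissolved <- if (mode == "union") list(geom_union_all(gs)) else gs

  purrr::pmap_dfr(
    list(subwatersheds$zone_id, subwatersheds$geometry),
    function(id, zgeom) {
      zarea <- geom_area(zgeom)
      if (zarea <= 0) stop("subwatershed ", id, " has zero area", call. = FALSE)
      exposed <- sum(vapply(dissolved, function(g) {
        geom_area(geom_intersection(g, zgeom))
      }, numeric(1)))
      n_spills <- sum(vapply(gs, function(g) {
        !geom_is_empty(geom_intersection(g, zgeom))
      }, logical(1)))
      new_risk_rows(id, "lRisk", exposed / zarea, exposed_area = exposed,
                    n_spills = n_spills)
    })
}

#' Quantile map classification
#'
#' Assigns each risk row a class 1..k with (as near as ties permit) equal
#' numbers of zones per class, the classification used for choropleth risk
#' maps. Classes are rank-based: tied values share the lower class. When
#' fewer than `k` distinct classes survive (heavy ties), the collapse is
#' reported via the `"collapsed"` attribute and a message, not an error.
#'
#' @param rows A tibble of risk rows with a `value` column.
#' @param k Number of classes, at least 2 (default 5 — quintiles).
#' @return `rows` with `quantile_class` filled in; attributes `breaks`
#'   (the j/k sample quantiles) and `collapsed` (logical).
#' @export
classify_quantiles <- function(rows, k = 5L) {
  stopifnot(k >= 2L, nrow(rows) > 0)
  v <- rows$value
  if (any(is.na(v))) {
    stop("cannot classify undefined risk values; resolve flags first",
         call. = FALSE)
  }
  n <- length(v)
  cls <- as.integer(ceiling(k * rank(v, ties.method = "min") / n))
  rows$quantile_class <- cls
  collapsed <- length(unique(cls)) < k
  if (collapsed) {
    message("quantile classes collapsed: ", length(unique(cls)),
            " distinct class(es) for k = ", k)
  }
  attr(rows, "breaks") <- stats::quantile(v, probs = seq_len(k - 1L) / k,
                                          names = FALSE)
  attr(rows, "k") <- as.integer(k)
  attr(rows, "collapsed") <- collapsed
  rows
}

#' Priority sites from the top risk quintiles
#'
#' Intersects the tracts in the top population-risk class with the
#' subwatersheds in the top land-risk class. Each overlap becomes a
#' priority site with a representative point, the dual-metric shortlist a
#' planner would pin on a map.
#'
#' @param p_rows Classified pRisk rows (from [classify_quantiles()]).
#' @param l_rows Classified lRisk rows, same `k`.
#' @param tracts,subwatersheds The zone tables the rows refer to.
#' @return A tibble with `tract_id`, `subwatershed_id`, `geometry` (list of
#'   intersection polygons), `point_x`, `point_y`; zero rows when the top
#'   classes do not overlap.
#' @export
prioritize <- function(p_rows, l_rows, tracts, subwatersheds) {
  kp <- attr(p_rows, "k"); kl <- attr(l_rows, "k")
  if (is.null(kp) || is.null(kl) || kp != kl) {
    stop("both row sets must be classified with the same k", call. = FALSE)
  }
  # with heavy ties the classes collapse below k; the top occupied class
  # is then the top quantile
  top_t <- p_rows$zone_id[p_rows$quantile_class == max(p_rows$quantile_class)]
  top_s <- l_rows$zone_id[l_rows$quantile_class == max(l_rows$quantile_class)]
  tt <- tracts[tracts$zone_id %in% top_t, , drop = FALSE]
  ss <- subwatersheds[subwatersheds$zone_id %in% top_s, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tt))) {
    for (j in seq_len(nrow(ss))) {
      inter <- geom_intersection(tt$geometry[[i]], ss$geometry[[j]])
      if (geom_is_empty(inter) || geom_area(inter) <= 0) next
      ctr <- geom_centroid(inter)
      out[[length(out) + 1L]] <- tibble::tibble(
        tract_id = tt$zone_id[i], subwatershed_id = ss$zone_id[j],
        geometry = list(inter), point_x = ctr[1], point_y = ctr[2])
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(tract_id = character(), subwatershed_id = character(),
                          geometry = list(), point_x = numeric(),
                          point_y = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Zonal mean of a raster over a polygon
#'
#' Mean of the grid values whose cell centres fall inside the zone
#' geometry; nodata cells are excluded. Used e.g. to overlay mean
#' imperviousness on the top land-risk subwatersheds.
#'
#' @param zone A polygon geometry or a one-row `zone_table`.
#' @param grid An `elevation_grid`-shaped value raster.
#' @return The mean, or `NA` (with a warning) when no cell centre falls
#'   inside the zone.
#' @export
zonal_mean <- function(zone, grid) {
  g <- if (inherits(zone, "sfer_geom")) zone else zone$geometry[[1]]
  stopifnot(inherits(grid, "elevation_grid"))
  idx <- which(!is.na(grid$values), arr.ind = TRUE)
  ctr <- cell_center(grid, idx[, 1], idx[, 2])
  inside <- geom_contains_points(g, ctr$x, ctr$y)
  if (!any(inside)) {
    warning("no raster cell centre falls inside the zone", call. = FALSE)
    return(NA_real_)
  }
  mean(grid$values[idx][inside])
}

#' Tabulate spill records by primary cause
#'
#' Counts records per primary cause and reports each cause's share of the
#' tabulated records, rounded half-up to two decimals, sorted by count
#' descending. Records without a cause label are grouped as
#' `"Unspecified"`.
#'
#' @param records Data frame of spill records with a `primary_cause`
#'   column (or a character vector of causes).
#' @return A tibble with `cause`, `count`, `percentage`.
#' @export
tabulate_causes <- function(records) {
  causes <- if (is.data.frame(records)) {
    if (!"primary_cause" %in% names(records)) {
      stop("records need a primary_cause column", call. = FALSE)
    }
    records$primary_cause
  } else {
    as.character(records)
  }
  causes[is.na(causes) | causes == ""] <- "Unspecified"
  tab <- table(causes)
  out <- tibble::tibble(cause = names(tab), count = as.integer(tab))
  total <- sum(out$count)
  out$percentage <- round_half_up(100 * out$count / total, 2L)
  out <- out[order(-out$count, out$cause), , drop = FALSE]
  tibble::as_tibble(out)
}
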