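# Elevation grids and D8 overland flow routing.
#
# Grid convention: row 1 is the northernmost row; the centre of cell
# (row, col) sits at origin + (col - 0.5, -(row - 0.5)) * cell_size, where
# the origin is the outer corner of the top-left cell. All coordinates are
# in a projected CRS with metre units; NA marks nodata.

# D8 neighbour order is clockwise starting east; ties in steepest descent
# break to the first direction in this order.
D8_DROW <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DCOL <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
D8_NAMES <- c("E", "SE", "S", "SW", "W", "NW", "N", "NE")
D8_ESRI <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
D8_PIT <- 0L

GEOGRAPHIC_CRS_HINTS <- c("EPSG:4326", "EPSG:4269", "EPSG:4267", "CRS84",
                          "WGS84", "longlat", "OGC:CRS84")

is_projected_crs <- function(label) {
  !any(vapply(GEOGRAPHIC_CRS_HINTS,
              function(h) grepl(h, label, fixed = TRUE), logical(1)))
}

check_projected_crs <- function(label) {
  if (!is_projected_crs(label)) {
    stop("CRS '", label, "' looks geographic (degrees); reproject the data ",
         "to a projected CRS with metre units first.", call. = FALSE)
  }
  invisible(label)
}

#' Create an elevation grid
#'
#' A DEM raster in a projected, metre-unit CRS. Row 1 is the northernmost
#' row and `origin_x`, `origin_y` locate the outer (north-west) corner of
#' the top-left cell.
#'
#' @param values Numeric matrix of elevations (m above sea level); `NA` is
#'   nodata.
#' @param origin_x,origin_y Coordinates of the grid's north-west corner (m).
#' @param cell_size Cell edge length in metres, positive.
#' @param crs Label of the projected CRS the coordinates live in.
#' @return An `elevation_grid` object.
#' @examples
#' dem <- elevation_grid(matrix(9:1, 3, 3), 0, 30, 10)
#' @export
elevation_grid <- function(values, origin_x = 0, origin_y = nrow(values) * cell_size,
                           cell_size = 1, crs = "local-metric") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), cell_size > 0, nrow(values) >= 1,
            ncol(values) >= 1, is.finite(origin_x), is.finite(origin_y))
  if (any(!is.finite(values) & !is.na(values))) {
    stop("elevations must be finite or NA (nodata)", call. = FALSE)
  }
  check_projected_crs(crs)
  structure(
    list(values = values, origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size, n_rows = nrow(values), n_cols = ncol(values),
         crs = crs),
    class = "elevation_grid"
  )
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("<elevation_grid: %d x %d cells of %g m, origin (%g, %g), CRS %s>\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  elevation %g..%g m, %d nodata cell(s)\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Cell centre coordinates and cell lookup
#'
#' `cell_center()` maps (row, col) indices to projected coordinates;
#' `cell_at_xy()` maps coordinates back to indices (NA outside the grid).
#'
#' @param grid An `elevation_grid` (or any grid sharing its metadata).
#' @param row,col Cell indices, 1-based, vectorised.
#' @return `cell_center()`: a tibble with columns `x`, `y`;
#'   `cell_at_xy()`: a tibble with columns `row`, `col`.
#' @export
cell_center <- function(grid, row, col) {
  tibble::tibble(
    x = grid$origin_x + (col - 0.5) * grid$cell_size,
    y = grid$origin_y - (row - 0.5) * grid$cell_size
  )
}

#' @rdname cell_center
#' @param x,y Projected coordinates (m), vectorised.
#' @export
cell_at_xy <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1L
  bad <- row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Elevation at point locations
#' @inheritParams cell_at_xy
#' @param dem An `elevation_grid`.
#' @return Numeric vector of elevations (NA off-grid or on nodata).
#' @export
elevation_at <- function(dem, x, y) {
  rc <- cell_at_xy(dem, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- dem$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Compute D8 flow directions
#'
#' Assigns each cell the direction of its steepest distance-weighted descent
#' among the eight neighbours (drop divided by `cell_size` for cardinal and
#' `cell_size * sqrt(2)` for diagonal moves). Cells without a strictly
#' positive drop are pits (the first pooling point on an unfilled DEM). Ties
#' break to the first direction clockwise from east. Under
#' `edge_policy = "flow_outward"` a border cell with no interior downslope
#' neighbour is pointed off-grid instead of becoming a pit, so traces
#' terminate at the edge there.
#'
#' @param dem An `elevation_grid` with at least one non-nodata cell.
#' @param edge_policy `"stop_at_edge"` (default) or `"flow_outward"`.
#' @return A `flow_grid`: same shape metadata plus `codes`, an integer
#'   matrix with 1..8 = E, SE, S, SW, W, NW, N, NE, 0 = pit, NA = nodata.
#' @export
flow_direction <- function(dem, edge_policy = c("stop_at_edge", "flow_outward")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(inherits(dem, "elevation_grid"))
  z <- dem$values
  if (all(is.na(z))) stop("DEM has no data cells", call. = FALSE)
  nr <- dem$n_rows; nc <- dem$n_cols
  dist <- dem$cell_size * ifelse(D8_DROW != 0L & D8_DCOL != 0L, sqrt(2), 1)

  best_grad <- matrix(0, nr, nc)
  codes <- matrix(D8_PIT, nr, nc)
  for (k in seq_len(8L)) {
    zn <- shift_matrix(z, D8_DROW[k], D8_DCOL[k])
    grad <- (z - zn) / dist[k]
    grad[is.na(grad)] <- -Inf           # off-grid or nodata neighbour
    take <- grad > best_grad            # strict > keeps first clockwise dir
    codes[take] <- k
    best_grad[take] <- grad[take]
  }
  codes[is.na(z)] <- NA_integer_

  if (edge_policy == "flow_outward") {
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (r > 1L && r < nr && cc > 1L && cc < nc) next
      if (is.na(codes[r, cc]) || codes[r, cc] != D8_PIT) next
      codes[r, cc] <- outward_code(r, cc, nr, nc)
    }
  }

  structure(
    list(codes = codes, origin_x = dem$origin_x, origin_y = dem$origin_y,
         cell_size = dem$cell_size, n_rows = nr, n_cols = nc, crs = dem$crs,
         edge_policy = edge_policy),
    class = "flow_grid"
  )
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf("<flow_grid: %d x %d cells, %d pit(s), edge policy %s>\n",
              x$n_rows, x$n_cols, sum(x$codes == D8_PIT, na.rm = TRUE),
              x$edge_policy))
  invisible(x)
}

# neighbour value matrix: entry [r, c] = m[r + drow, c + dcol], NA off-grid
shift_matrix <- function(m, drow, dcol) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + drow
  cs <- seq_len(nc) + dcol
  rok <- rs >= 1L & rs <= nr
  cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

outward_code <- function(r, cc, nr, nc) {
  dr <- (r == nr) - (r == 1L)    # +1 south edge, -1 north edge
  dc <- (cc == nc) - (cc == 1L)  # +1 east edge,  -1 west edge
  which(D8_DROW == dr & D8_DCOL == dc)
}

#' Trace a D8 flowpath from a start point
#'
#' Follows the flow-direction codes from the cell containing `x`, `y`,
#' visiting successive cell centres, until the first pit cell, the grid
#' edge, or a nodata cell. Elevations along the path are strictly
#' decreasing (a zero-drop cell is a pit), so the walk cannot cycle. A
#' start on a pit yields a degenerate single-vertex path.
#'
#' @param fdir A `flow_grid`.
#' @param dem The `elevation_grid` the flow grid was derived from.
#' @param x,y Start coordinates on a non-nodata cell.
#' @return An `sfer_trace`: list with `path` (tibble of `x`, `y`,
#'   `elevation`, `row`, `col`), `end_x`, `end_y`, `end_elevation`,
#'   `reason` (one of `"pit"`, `"edge"`, `"nodata"`), and `length_m`.
#' @export
trace_flowpath <- function(fdir, dem, x, y) {
  stopifnot(inherits(fdir, "flow_grid"), inherits(dem, "elevation_grid"))
  rc <- cell_at_xy(fdir, x, y)
  r <- rc$row[1]; cc <- rc$col[1]
  if (is.na(r)) stop("start point lies outside the grid", call. = FALSE)
  if (is.na(dem$values[r, cc])) stop("start point lies on a nodata cell",
                                     call. = FALSE)
  max_steps <- fdir$n_rows * fdir$n_cols
  rows <- integer(0); cols <- integer(0)
  reason <- NA_character_
  for (step in seq_len(max_steps + 1L)) {
    rows <- c(rows, r); cols <- c(cols, cc)
    code <- fdir$codes[r, cc]
    if (is.na(code)) { reason <- "nodata"; break }
    if (code == D8_PIT) { reason <- "pit"; break }
    nr_ <- r + D8_DROW[code]; nc_ <- cc + D8_DCOL[code]
    if (nr_ < 1L || nr_ > fdir$n_rows || nc_ < 1L || nc_ > fdir$n_cols) {
      reason <- "edge"; break
    }
    if (is.na(dem$values[nr_, nc_])) { reason <- "nodata"; break }
    r <- nr_; cc <- nc_
  }
  ctr <- cell_center(fdir, rows, cols)
  path <- tibble::tibble(
    x = ctr$x, y = ctr$y,
    elevation = dem$values[cbind(rows, cols)],
    row = rows, col = cols
  )
  n <- nrow(path)
  len <- if (n < 2L) 0 else sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
  structure(
    list(path = path, end_x = path$x[n], end_y = path$y[n],
         end_elevation = path$elevation[n], reason = reason, length_m = len),
    class = "sfer_trace"
  )
}

#' @export
print.sfer_trace <- function(x, ...) {
  cat(sprintf("<sfer_trace: %d vertices, %.1f m, ends by %s at (%g, %g)>\n",
              nrow(x$path), x$length_m, x$reason, x$end_x, x$end_y))
  invisible(x)
}

#' Convert a DEM into buffered elevation points
#'
#' One point per non-nodata cell centre, each carrying its elevation and a
#' disc of `point_buffer` metres that stands in for the area of the source
#' cell when accumulation zones are hulled (bare points would underestimate
#' the zone).
#'
#' @param dem An `elevation_grid`.
#' @param point_buffer Disc radius in metres, positive (default 4.5).
#' @param clip Optional geometry; only cell centres inside it are kept.
#' @return A tibble with columns `x`, `y`, `elevation`, `row`, `col`, with
#'   attributes `point_buffer` and `crs`.
#' @export
grid_points <- function(dem, point_buffer = 4.5, clip = NULL) {
  stopifnot(inherits(dem, "elevation_grid"))
  if (!is.numeric(point_buffer) || point_buffer <= 0) {
    stop("point_buffer must be a positive length in metres", call. = FALSE)
  }
  idx <- which(!is.na(dem$values), arr.ind = TRUE)
  ctr <- cell_center(dem, idx[, 1], idx[, 2])
  out <- tibble::tibble(
    x = ctr$x, y = ctr$y,
    elevation = dem$values[idx],
    row = as.integer(idx[, 1]), col = as.integer(idx[, 2])
  )
  if (!is.null(clip)) {
    out <- out[geom_contains_points(clip, out$x, out$y), , drop = FALSE]
  }
  attr(out, "point_buffer") <- point_buffer
  attr(out, "crs") <- dem$crs
  out
}
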