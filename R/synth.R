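# Deterministic synthetic inputs: terrains, spill catalogs, population
# grids and zone tilings. Every generator takes an explicit seed and leaves
# the caller's RNG state untouched, so identical arguments give identical
# outputs on any platform (R's default Mersenne-Twister stream).

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Extent of a grid
#' @param grid An `elevation_grid` or `flow_grid`.
#' @return Named vector xmin, ymin, xmax, ymax (m).
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$origin_x,
    ymin = grid$origin_y - grid$n_rows * grid$cell_size,
    xmax = grid$origin_x + grid$n_cols * grid$cell_size,
    ymax = grid$origin_y)
}

#' Generate a synthetic DEM
#'
#' Terrain families with known analytic structure, mirroring the kinds of
#' relief a spill model meets: `plane` (uniform tilt, closed-form traces),
#' `basin` (Gaussian depression with a unique pooling cell at the centre),
#' `ridge_valley` (a V-shaped valley draining south), and `random_smooth`
#' (seeded noise smoothed by repeated 3x3 mean filtering). The default
#' 10 m cell honours the real scale of 1/3 arc-second elevation tiles.
#'
#' @param kind Terrain family.
#' @param n_rows,n_cols Grid shape.
#' @param cell_size Cell edge (m), default 10.
#' @param origin_x,origin_y North-west corner coordinates.
#' @param z0 Reference elevation (m), default 300.
#' @param slope_x,slope_y Plane gradients (m per m) east-down and
#'   south-down; used by `plane` and as the valley tilt in `ridge_valley`.
#' @param basin_depth,basin_sigma Gaussian basin depth (m) and width (m);
#'   `basin_sigma` defaults to a quarter of the smaller grid extent.
#' @param noise_sd,smooth_passes Noise scale (m) and smoothing passes for
#'   `random_smooth`.
#' @param seed RNG seed (only `random_smooth` draws).
#' @param crs CRS label.
#' @return An `elevation_grid`.
#' @export
make_dem <- function(kind = c("plane", "basin", "ridge_valley", "random_smooth"),
                     n_rows = 40L, n_cols = 40L, cell_size = 10,
                     origin_x = 0, origin_y = n_rows * cell_size,
                     z0 = 300, slope_x = 0.02, slope_y = 0,
                     basin_depth = 20, basin_sigma = NULL,
                     noise_sd = 5, smooth_passes = 3L, seed = 1L,
                     crs = "local-metric") {
  kind <- match.arg(kind)
  stopifnot(n_rows >= 1L, n_cols >= 1L, cell_size > 0)
  # u: metres east of the west edge; v: metres south of the north edge
  u <- outer(rep(1, n_rows), (seq_len(n_cols) - 0.5) * cell_size)
  v <- outer((seq_len(n_rows) - 0.5) * cell_size, rep(1, n_cols))
  z <- switch(kind,
    plane = z0 - slope_x * u - slope_y * v,
    basin = {
      if (is.null(basin_sigma)) {
        basin_sigma <- 0.25 * min(n_rows, n_cols) * cell_size
      }
      du <- u - n_cols * cell_size / 2
      dv <- v - n_rows * cell_size / 2
      z0 - basin_depth * exp(-(du^2 + dv^2) / (2 * basin_sigma^2))
    },
    ridge_valley = {
      umid <- n_cols * cell_size / 2
      z0 + slope_x * abs(u - umid) + slope_y * v
    },
    random_smooth = with_local_seed(seed, {
      m <- matrix(stats::rnorm(n_rows * n_cols, sd = noise_sd), n_rows, n_cols)
      for (p in seq_len(smooth_passes)) m <- smooth3x3(m)
      z0 + m
    })
  )
  elevation_grid(z, origin_x, origin_y, cell_size, crs)
}

smooth3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    s <- shift_matrix(m, dr, dc)
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    cnt <- cnt + ok
  }
  acc / cnt
}

#' Generate a synthetic spill catalog
#'
#' Samples spill origins on distinct non-nodata cells of a DEM with
#' log-uniform volumes (litres). Optional duplicate-location pairs exercise
#' union semantics (record 2j inherits the coordinates of record 2j-1 but
#' keeps its own volume); an optional invalid fraction produces drafts that
#' [validate_spills()] must drop, cycling through missing coordinates,
#' non-positive quantity and an explicit unusable flag.
#'
#' @param dem An `elevation_grid` to place spills on.
#' @param n Number of records.
#' @param q_range Log-uniform volume bounds in litres (default 10–10,000).
#' @param invalid_fraction Fraction of records made unusable (default 0).
#' @param duplicate_pairs Number of duplicate-location pairs (default 0;
#'   needs `2 * duplicate_pairs <= n`).
#' @param seed RNG seed.
#' @return A tibble of spill drafts: `spill_id`, `x`, `y`, `quantity`,
#'   `primary_cause`, `valid`.
#' @export
make_spills <- function(dem, n, q_range = c(10, 10000),
                        invalid_fraction = 0, duplicate_pairs = 0L,
                        seed = 1L) {
  stopifnot(n >= 1L, q_range[1] > 0, q_range[2] > q_range[1],
            2L * duplicate_pairs <= n,
            invalid_fraction >= 0, invalid_fraction <= 1)
  ok <- which(!is.na(dem$values), arr.ind = TRUE)
  if (n > nrow(ok)) stop("more spills requested than available cells",
                         call. = FALSE)
  causes <- c("Debris", "Wet weather", "Grease", "Pipe failure",
              "Equipment failure", "Roots", "Other")
  with_local_seed(seed, {
    pick <- ok[sample.int(nrow(ok), n), , drop = FALSE]
    ctr <- cell_center(dem, pick[, 1], pick[, 2])
    q <- exp(stats::runif(n, log(q_range[1]), log(q_range[2])))
    cause <- sample(causes, n, replace = TRUE)
    out <- tibble::tibble(spill_id = sprintf("s%03d", seq_len(n)),
                          x = ctr$x, y = ctr$y, quantity = q,
                          primary_cause = cause, valid = TRUE)
    for (j in seq_len(duplicate_pairs)) {
      out$x[2L * j] <- out$x[2L * j - 1L]
      out$y[2L * j] <- out$y[2L * j - 1L]
      if (out$quantity[2L * j] == out$quantity[2L * j - 1L]) {
        out$quantity[2L * j] <- out$quantity[2L * j] * 2
      }
    }
    n_bad <- round(invalid_fraction * n)
    if (n_bad > 0) {
      bad <- seq.int(n - n_bad + 1L, n)
      for (i in seq_along(bad)) {
        r <- bad[i]
        mode <- i %% 3L
        if (mode == 1L) {
          out$x[r] <- NA_real_; out$y[r] <- NA_real_
        } else if (mode == 2L) {
          out$quantity[r] <- -abs(out$quantity[r])
        } else {
          out$valid[r] <- FALSE
        }
      }
    }
    out
  })
}

#' Generate a synthetic population grid
#'
#' A LandScan-style grid of person counts on (default) 90 m cells covering
#' an extent, converted to buffered points. Constant counts give
#' closed-form exposure expectations; `lambda` draws Poisson counts.
#'
#' @param extent Named vector xmin, ymin, xmax, ymax, or a grid to take the
#'   extent from.
#' @param cell_size Population cell edge (m), default 90.
#' @param count Constant persons per cell (used when `lambda` is NULL).
#' @param lambda Optional Poisson mean for random counts.
#' @param pop_buffer Disc radius (m), default 35.
#' @param seed RNG seed (used only with `lambda`).
#' @param crs CRS label.
#' @return A [population_cells()] tibble.
#' @export
make_population <- function(extent, cell_size = 90, count = 3, lambda = NULL,
                            pop_buffer = 35, seed = 1L, crs = "local-metric") {
  if (inherits(extent, "elevation_grid") || inherits(extent, "flow_grid")) {
    extent <- grid_extent(extent)
  }
  xs <- seq(extent["xmin"] + cell_size / 2, extent["xmax"], by = cell_size)
  ys <- seq(extent["ymin"] + cell_size / 2, extent["ymax"], by = cell_size)
  gg <- expand.grid(x = xs, y = ys)
  counts <- if (is.null(lambda)) {
    rep(count, nrow(gg))
  } else {
    with_local_seed(seed, stats::rpois(nrow(gg), lambda))
  }
  population_cells(gg$x, gg$y, counts, pop_buffer = pop_buffer, crs = crs)
}

#' Generate a rectangular zone tiling
#'
#' Tiles an extent with `n_rows x n_cols` rectangles of equal, closed-form
#' area. Tract populations are either supplied, summed from a population
#' cell set by containment (so pRisk numerator and denominator share a
#' source), or default to a constant.
#'
#' @param extent Named vector xmin, ymin, xmax, ymax, or a grid.
#' @param n_rows,n_cols Tiling shape.
#' @param kind `"tract"` or `"subwatershed"`.
#' @param populations Optional per-zone populations (row-major order).
#' @param pop Optional [population_cells()]; tract populations become the
#'   sum of contained cell counts.
#' @param default_population Constant population when neither is given.
#' @param crs CRS label.
#' @return A [zone_table()].
#' @export
make_zones <- function(extent, n_rows = 2L, n_cols = 2L,
                       kind = c("tract", "subwatershed"),
                       populations = NULL, pop = NULL,
                       default_population = 100, crs = "local-metric") {
  kind <- match.arg(kind)
  if (inherits(extent, "elevation_grid") || inherits(extent, "flow_grid")) {
    extent <- grid_extent(extent)
  }
  dx <- (extent["xmax"] - extent["xmin"]) / n_cols
  dy <- (extent["ymax"] - extent["ymin"]) / n_rows
  ids <- character(0); geoms <- list(); pops <- numeric(0)
  idx <- 0L
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      idx <- idx + 1L
      xmin <- extent["xmin"] + (cc - 1L) * dx
      ymax <- extent["ymax"] - (r - 1L) * dy
      g <- geom_rect(xmin, ymax - dy, xmin + dx, ymax)
      ids <- c(ids, sprintf("%s_r%dc%d", substr(kind, 1, 2), r, cc))
      geoms <- c(geoms, list(g))
      p <- if (kind == "subwatershed") {
        NA_real_
      } else if (!is.null(populations)) {
        populations[idx]
      } else if (!is.null(pop)) {
        inside <- geom_contains_points(g, pop$x, pop$y)
        sum(pop$count[inside])
      } else {
        default_population
      }
      pops <- c(pops, p)
    }
  }
  zone_table(ids, kind, geoms, pops, crs = crs)
}
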