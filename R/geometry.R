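# Planar geometry toolkit used by the footprint and risk layers.
#
# A geometry ("sfer_geom") is a list of rings, each ring a list(x, y) of
# vertex coordinates in a projected, metre-unit CRS. Ring sets follow the
# even-odd convention: a point is inside the geometry when it is inside an
# odd number of rings, so holes are just rings nested inside outer rings.
# Boolean overlays are delegated to the Clipper engine (polyclip); areas and
# point predicates are computed directly.

new_geom <- function(rings = list()) {
  structure(rings, class = "sfer_geom")
}

#' Build a polygon geometry from vertex coordinates
#'
#' Constructs a single-ring polygon in a projected, metre-unit coordinate
#' system. Rings are closed implicitly (do not repeat the first vertex).
#'
#' @param x,y Numeric vertex coordinates (metres), at least three points.
#' @return A polygon geometry (`sfer_geom`).
#' @examples
#' g <- geom_polygon_xy(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' geom_area(g)
#' @export
geom_polygon_xy <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  # drop an explicitly closed last vertex
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  new_geom(list(list(x = as.numeric(x), y = as.numeric(y))))
}

#' @rdname geom_polygon_xy
#' @param xmin,ymin,xmax,ymax Rectangle bounds (metres).
#' @export
geom_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  geom_polygon_xy(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' @rdname geom_polygon_xy
#' @param cx,cy Disc centre (metres).
#' @param r Disc radius (metres), positive.
#' @param n_segments Number of edges used to discretise the circle.
#' @export
geom_circle <- function(cx, cy, r, n_segments = 64L) {
  stopifnot(r > 0, n_segments >= 8L)
  th <- seq(0, 2 * pi, length.out = n_segments + 1L)[-(n_segments + 1L)]
  geom_polygon_xy(cx + r * cos(th), cy + r * sin(th))
}

geom_empty <- function() new_geom(list())

#' @export
print.sfer_geom <- function(x, ...) {
  cat(sprintf("<sfer_geom: %d ring(s), area %.6g m^2>\n",
              length(x), geom_area(x)))
  invisible(x)
}

#' Test whether a geometry has no rings
#' @param g A geometry.
#' @return Logical scalar.
#' @export
geom_is_empty <- function(g) length(g) == 0L

ring_signed_area <- function(ring) {
  x <- ring$x; y <- ring$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# nesting depth of each ring: how many of the other rings contain its
# first vertex. Even depth = outer boundary, odd depth = hole, independent
# of ring orientation (even-odd convention).
ring_depths <- function(g) {
  k <- length(g)
  if (k == 1L) return(0L)
  vapply(seq_len(k), function(i) {
    xi <- g[[i]]$x[1]; yi <- g[[i]]$y[1]
    sum(vapply(seq_len(k)[-i], function(j) {
      sp::point.in.polygon(xi, yi, g[[j]]$x, g[[j]]$y) == 1L
    }, logical(1)))
  }, integer(1))
}

#' Area of a geometry
#'
#' Shoelace area per ring; rings at odd nesting depth are holes and
#' subtract, whatever their orientation.
#'
#' @param g A geometry.
#' @return Area in square metres.
#' @export
geom_area <- function(g) {
  if (geom_is_empty(g)) return(0)
  a <- abs(vapply(g, ring_signed_area, numeric(1)))
  sum(a * ifelse(ring_depths(g) %% 2L == 0L, 1, -1))
}

as_clip <- function(g) unclass(g)

#' Boolean overlays of two geometries
#'
#' Union and intersection via the Clipper polygon-clipping engine; outputs
#' are normalised ring sets (holes carried as reversed rings).
#'
#' @param a,b Geometries.
#' @return A geometry.
#' @export
geom_union <- function(a, b) {
  if (geom_is_empty(a)) return(b)
  if (geom_is_empty(b)) return(a)
  new_geom(polyclip::polyclip(as_clip(a), as_clip(b), op = "union",
                              fillA = "evenodd", fillB = "evenodd"))
}

#' @rdname geom_union
#' @export
geom_intersection <- function(a, b) {
  if (geom_is_empty(a) || geom_is_empty(b)) return(geom_empty())
  new_geom(polyclip::polyclip(as_clip(a), as_clip(b), op = "intersection",
                              fillA = "evenodd", fillB = "evenodd"))
}

#' @rdname geom_union
#' @param gs A list of geometries to dissolve into one.
#' @export
geom_union_all <- function(gs) {
  gs <- gs[!vapply(gs, geom_is_empty, logical(1))]
  if (length(gs) == 0L) return(geom_empty())
  Reduce(geom_union, gs)
}

#' Buffer a polyline into a corridor polygon
#'
#' Offsets an open path by a fixed half-width with round joins and round end
#' caps, the shape of a worst-case flow corridor.
#'
#' @param x,y Polyline vertex coordinates (metres).
#' @param width Buffer half-width in metres, positive.
#' @return A geometry; empty when the path has fewer than two vertices.
#' @export
geom_buffer_path <- function(x, y, width) {
  stopifnot(width > 0)
  if (length(x) < 2L) return(geom_empty())
  out <- polyclip::polylineoffset(list(list(x = x, y = y)), width,
                                  jointype = "round", endtype = "openround",
                                  arctol = width / 400)
  new_geom(out)
}

#' Point-in-geometry predicate
#'
#' Even-odd test: a point is inside when it falls within an odd number of
#' rings. Points on a ring boundary count as inside.
#'
#' @param g A geometry.
#' @param px,py Point coordinates (vectorised).
#' @return Logical vector.
#' @export
geom_contains_points <- function(g, px, py) {
  if (geom_is_empty(g)) return(rep(FALSE, length(px)))
  inside <- rep(0L, length(px))
  on_edge <- rep(FALSE, length(px))
  for (ring in g) {
    r <- sp::point.in.polygon(px, py, ring$x, ring$y)
    inside <- inside + as.integer(r == 1L)
    on_edge <- on_edge | r >= 2L
  }
  (inside %% 2L == 1L) | on_edge
}

# squared distance from points to one segment (a,b), vectorised over points
.seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

#' Distance from a point to a geometry
#'
#' Zero for points inside (or on the boundary of) the geometry, otherwise
#' the minimum Euclidean distance to any ring edge.
#'
#' @param g A geometry.
#' @param px,py Point coordinates (vectorised).
#' @return Numeric vector of distances in metres.
#' @export
geom_distance_points <- function(g, px, py) {
  n <- length(px)
  if (geom_is_empty(g)) return(rep(Inf, n))
  d2 <- rep(Inf, n)
  for (ring in g) {
    x <- ring$x; y <- ring$y
    m <- length(x)
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      d2 <- pmin(d2, .seg_dist2(px, py, x[i], y[i], x[j], y[j]))
    }
  }
  d <- sqrt(d2)
  d[geom_contains_points(g, px, py)] <- 0
  d
}

#' Area-weighted centroid of a geometry
#' @param g A non-empty geometry.
#' @return Numeric length-2 vector (x, y).
#' @export
geom_centroid <- function(g) {
  stopifnot(!geom_is_empty(g))
  depth <- ring_depths(g)
  cx <- 0; cy <- 0; atot <- 0
  for (i in seq_along(g)) {
    x <- g[[i]]$x; y <- g[[i]]$y
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cr <- x * yn - xn * y
    a <- 0.5 * sum(cr)
    if (abs(a) < .Machine$double.eps) next
    # orient-normalise so outer rings add and holes (odd depth) subtract
    w <- (if (depth[i] %% 2L == 0L) 1 else -1) / sign(a)
    cx <- cx + w * sum((x + xn) * cr) / 6
    cy <- cy + w * sum((y + yn) * cr) / 6
    atot <- atot + w * a
  }
  if (atot == 0) {
    # degenerate: fall back to vertex mean
    allx <- unlist(lapply(g, `[[`, "x")); ally <- unlist(lapply(g, `[[`, "y"))
    return(c(mean(allx), mean(ally)))
  }
  c(cx / atot, cy / atot)
}

#' Bounding box of a geometry
#' @param g A non-empty geometry.
#' @return Named numeric vector xmin, ymin, xmax, ymax.
#' @export
geom_bbox <- function(g) {
  stopifnot(!geom_is_empty(g))
  allx <- unlist(lapply(g, `[[`, "x")); ally <- unlist(lapply(g, `[[`, "y"))
  c(xmin = min(allx), ymin = min(ally), xmax = max(allx), ymax = max(ally))
}

#' Flatten a geometry into a data frame for plotting
#' @param g A geometry.
#' @return A tibble with columns `x`, `y`, `ring`.
#' @export
geom_to_df <- function(g) {
  if (geom_is_empty(g)) {
    return(tibble::tibble(x = numeric(), y = numeric(), ring = integer()))
  }
  purrr::imap_dfr(unclass(g), function(r, i) {
    tibble::tibble(x = r$x, y = r$y, ring = as.integer(i))
  })
}

# ---- concave hull (chi-shape) ------------------------------------------

# Characteristic-shape hull: Delaunay triangulation of the point cloud,
# then boundary triangles adjacent to long boundary edges are shaved off,
# provided removal keeps the shape regular (the exposed vertex must not
# already lie on the boundary). The length threshold interpolates between
# the shortest and longest Delaunay edge; concavity = 1 removes nothing
# and returns the convex hull.

#' Concave hull of a point cloud
#'
#' Characteristic-shape ("chi") hull built on a Delaunay triangulation.
#' `concavity` in (0, 1] sets the edge-length threshold below which boundary
#' edges are kept: 1 yields the convex hull, smaller values dig deeper into
#' concave regions while keeping the boundary a simple polygon.
#'
#' @param x,y Point coordinates (at least three distinct, non-collinear
#'   points for a non-degenerate hull; otherwise the convex hull, possibly
#'   empty, is returned).
#' @param concavity Tightness parameter in (0, 1]; default 0.8.
#' @return A polygon geometry.
#' @export
concave_hull <- function(x, y, concavity = 0.8) {
  stopifnot(length(x) == length(y), concavity > 0, concavity <= 1)
  pts <- unique(data.frame(x = as.numeric(x), y = as.numeric(y)))
  if (nrow(pts) < 3L) return(geom_empty())
  ch <- grDevices::chull(pts$x, pts$y)
  if (length(ch) < 3L) return(geom_empty())  # collinear cloud
  if (concavity >= 1) return(geom_polygon_xy(pts$x[ch], pts$y[ch]))
  tri <- tryCatch(delaunay_triangles(pts$x, pts$y), error = function(e) NULL)
  if (is.null(tri) || nrow(tri) == 0L) {
    return(geom_polygon_xy(pts$x[ch], pts$y[ch]))
  }
  chi_shape(pts$x, pts$y, tri, concavity)
}

# Delaunay triangle faces from the deldir edge list. Triangles are
# recovered as 3-cycles a < b < c with c a common neighbour of edge (a, b);
# when the cycle count exceeds the planar face count E - V + 1 the rare
# non-face cycles (which enclose other vertices) are dropped by a
# point-in-triangle test.
delaunay_triangles <- function(x, y) {
  dd <- suppressMessages(deldir::deldir(x, y, suppressMsge = TRUE))
  e <- cbind(pmin(dd$delsgs$ind1, dd$delsgs$ind2),
             pmax(dd$delsgs$ind1, dd$delsgs$ind2))
  verts <- unique(as.vector(e))
  nE <- nrow(e)
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  tris <- vector("list", nE)
  for (i in seq_len(nE)) {
    a <- e[i, 1]; b <- e[i, 2]
    common <- intersect(adj[[as.character(a)]], adj[[as.character(b)]])
    common <- common[common > b]
    if (length(common)) tris[[i]] <- cbind(a, b, common)
  }
  tri <- do.call(rbind, tris)
  if (is.null(tri)) return(matrix(integer(0), 0L, 3L))
  n_faces <- nE - length(verts) + 1L
  if (nrow(tri) > n_faces) {
    keep <- vapply(seq_len(nrow(tri)), function(i) {
      a <- tri[i, 1]; b <- tri[i, 2]; cc <- tri[i, 3]
      others <- setdiff(verts, tri[i, ])
      inb <- others[x[others] > min(x[tri[i, ]]) & x[others] < max(x[tri[i, ]]) &
                    y[others] > min(y[tri[i, ]]) & y[others] < max(y[tri[i, ]])]
      if (!length(inb)) return(TRUE)
      !any(points_in_triangle(x[inb], y[inb],
                              x[a], y[a], x[b], y[b], x[cc], y[cc]))
    }, logical(1))
    tri <- tri[keep, , drop = FALSE]
  }
  tri
}

points_in_triangle <- function(px, py, ax, ay, bx, by, cx, cy) {
  s1 <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  s2 <- (cx - bx) * (py - by) - (cy - by) * (px - bx)
  s3 <- (ax - cx) * (py - cy) - (ay - cy) * (px - cx)
  (s1 > 0 & s2 > 0 & s3 > 0) | (s1 < 0 & s2 < 0 & s3 < 0)
}

chi_shape <- function(px, py, tri, concavity) {
  nt <- nrow(tri)
  alive <- rep(TRUE, nt)
  # edge table: each triangle contributes 3 undirected edges
  edges <- rbind(tri[, c(1, 2), drop = FALSE],
                 tri[, c(2, 3), drop = FALSE],
                 tri[, c(3, 1), drop = FALSE])
  etri <- rep(seq_len(nt), 3L)               # owning triangle of each row
  key <- paste0(pmin(edges[, 1], edges[, 2]), "_",
                pmax(edges[, 1], edges[, 2]))
  kidx <- match(key, unique(key))            # undirected-edge id per row
  nk <- max(kidx)
  elen <- sqrt((px[edges[, 1]] - px[edges[, 2]])^2 +
               (py[edges[, 1]] - py[edges[, 2]])^2)
  lmin <- min(elen); lmax <- max(elen)
  lambda <- lmin + concavity * (lmax - lmin)

  rows_of_key <- split(seq_along(kidx), kidx) # 1 or 2 rows per edge id
  cnt <- vapply(rows_of_key, length, integer(1))  # alive triangles per edge
  klen <- vapply(rows_of_key, function(r) elen[r[1]], numeric(1))
  ka <- edges[vapply(rows_of_key, `[`, integer(1), 1L), 1]
  kb <- edges[vapply(rows_of_key, `[`, integer(1), 1L), 2]

  on_boundary <- cnt == 1L
  vcount <- tabulate(c(ka[on_boundary], kb[on_boundary]), nbins = length(px))
  blocked <- rep(FALSE, nk)

  set_boundary <- function(k, val) {
    if (on_boundary[k] == val) return(invisible())
    on_boundary[k] <<- val
    d <- if (val) 1L else -1L
    vcount[ka[k]] <<- vcount[ka[k]] + d
    vcount[kb[k]] <<- vcount[kb[k]] + d
  }

  repeat {
    cand <- which(on_boundary & !blocked & klen > lambda)
    if (length(cand) == 0L) break
    k <- cand[which.max(klen[cand])]
    rows <- rows_of_key[[k]]
    r <- rows[alive[etri[rows]]][1]
    t <- etri[r]
    opp <- setdiff(tri[t, ], c(ka[k], kb[k]))
    if (vcount[opp] > 0L) {
      blocked[k] <- TRUE
      next
    }
    # shave triangle t: this edge leaves the boundary, the other two join it
    alive[t] <- FALSE
    for (rr in c(t, nt + t, 2L * nt + t)) {
      kk <- kidx[rr]
      cnt[kk] <- cnt[kk] - 1L
      set_boundary(kk, cnt[kk] == 1L)
    }
  }

  bkeys <- which(on_boundary)
  if (length(bkeys) < 3L) return(geom_empty())
  bed <- cbind(ka[bkeys], kb[bkeys])
  rings <- stitch_rings(bed)
  out <- lapply(rings, function(idx) list(x = px[idx], y = py[idx]))
  new_geom(out)
}

stitch_rings <- function(bed) {
  # bed: matrix of undirected boundary edges (vertex index pairs)
  adj <- list()
  for (i in seq_len(nrow(bed))) {
    a <- as.character(bed[i, 1]); b <- as.character(bed[i, 2])
    adj[[a]] <- c(adj[[a]], bed[i, 2])
    adj[[b]] <- c(adj[[b]], bed[i, 1])
  }
  used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  rings <- list()
  for (i in seq_len(nrow(bed))) {
    k0 <- ekey(bed[i, 1], bed[i, 2])
    if (!is.null(used[[k0]])) next
    ring <- c(bed[i, 1], bed[i, 2])
    used[[k0]] <- TRUE
    repeat {
      cur <- ring[length(ring)]
      nxts <- adj[[as.character(cur)]]
      nxt <- NA_integer_
      for (cn in nxts) {
        if (is.null(used[[ekey(cur, cn)]])) { nxt <- cn; break }
      }
      if (is.na(nxt)) break
      used[[ekey(cur, nxt)]] <- TRUE
      if (nxt == ring[1]) break
      ring <- c(ring, nxt)
    }
    if (length(ring) >= 3L) rings[[length(rings) + 1L]] <- ring
  }
  rings
}
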