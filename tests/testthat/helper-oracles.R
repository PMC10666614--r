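# Independent oracles used across the suite. These deliberately share no
# code with the package internals: plain loops and first-principles
# arithmetic only.

# Exhaustive per-cell neighbour scan for D8 steepest descent:
# for every cell, compare the distance-weighted drop to all 8 neighbours
# and keep the first maximum in clockwise-from-east order.
brute_force_d8 <- function(z, cell_size) {
  drow <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dcol <- c(1, 1, 0, -1, -1, -1, 0, 1)
  dist <- cell_size * ifelse(drow != 0 & dcol != 0, sqrt(2), 1)
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (is.na(z[r, cc])) { out[r, cc] <- NA_integer_; next }
      best <- 0; code <- 0L
      for (k in 1:8) {
        rr <- r + drow[k]; ccc <- cc + dcol[k]
        if (rr < 1 || rr > nr || ccc < 1 || ccc > nc) next
        if (is.na(z[rr, ccc])) next
        g <- (z[r, cc] - z[rr, ccc]) / dist[k]
        if (g > best) { best <- g; code <- k }
      }
      out[r, cc] <- code
    }
  }
  out
}

# Greedy steepest-descent walk on raw elevations (recomputes the best
# neighbour at every step instead of following a precomputed code grid).
greedy_descent_walk <- function(z, cell_size, r0, c0) {
  drow <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dcol <- c(1, 1, 0, -1, -1, -1, 0, 1)
  dist <- cell_size * ifelse(drow != 0 & dcol != 0, sqrt(2), 1)
  nr <- nrow(z); nc <- ncol(z)
  r <- r0; cc <- c0
  path <- list(c(r, cc))
  repeat {
    best <- 0; kbest <- 0L
    for (k in 1:8) {
      rr <- r + drow[k]; ccc <- cc + dcol[k]
      if (rr < 1 || rr > nr || ccc < 1 || ccc > nc) next
      if (is.na(z[rr, ccc])) next
      g <- (z[r, cc] - z[rr, ccc]) / dist[k]
      if (g > best) { best <- g; kbest <- k }
    }
    if (kbest == 0L) break
    r <- r + drow[kbest]; cc <- cc + dcol[kbest]
    path[[length(path) + 1L]] <- c(r, cc)
  }
  do.call(rbind, path)
}

# random DEM with optional nodata holes, wrapped in the package container
random_dem <- function(seed, max_side = 32L, nodata_frac = 0,
                       cell_size = 10) {
  set.seed(seed)
  nr <- sample(3:max_side, 1)
  nc <- sample(3:max_side, 1)
  z <- matrix(round(stats::runif(nr * nc, 0, 100), 3), nr, nc)
  if (nodata_frac > 0) {
    holes <- sample(length(z), max(1L, floor(nodata_frac * length(z))))
    z[holes] <- NA
  }
  elevation_grid(z, 0, nr * cell_size, cell_size)
}

# a catalog of drafts with a known number of unusable rows, cycling the
# three drop reasons
drafts_with_invalid <- function(n_total, n_bad) {
  df <- tibble::tibble(
    spill_id = seq_len(n_total),
    x = as.numeric(seq_len(n_total)),
    y = as.numeric(seq_len(n_total)),
    quantity = rep(1000, n_total),
    valid = TRUE
  )
  if (n_bad > 0) {
    bad <- seq_len(n_bad)
    for (i in bad) {
      mode <- i %% 3L
      if (mode == 1L) df$x[i] <- NA_real_
      else if (mode == 2L) df$quantity[i] <- -1
      else df$valid[i] <- FALSE
    }
  }
  df
}
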