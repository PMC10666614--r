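# broom-style summaries of footprint sets.

#' Tidy a footprint set
#'
#' One row per spill with the scalar footprint summaries (geometry list
#' columns dropped).
#'
#' @param x An `sfer_footprint_set`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sfer_footprint_set <- function(x, ...) {
  keep <- !vapply(x, is.list, logical(1))
  out <- tibble::as_tibble(as.data.frame(x[, keep, drop = FALSE]))
  out
}

#' Glance at a footprint set
#'
#' One-row summary of a modelled catalog: number of footprints, total
#' volume, total (per-spill, undissolved) footprint area, dissolved union
#' area, and counts of trace termination reasons.
#'
#' @param x An `sfer_footprint_set`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.sfer_footprint_set <- function(x, ...) {
  tibble::tibble(
    n_footprints = nrow(x),
    total_quantity_l = sum(x$quantity),
    q_max_l = attr(x, "q_max") %||% max(x$quantity),
    total_area_m2 = sum(x$area_m2),
    union_area_m2 = geom_area(union_footprints(x, "union")),
    median_path_m = stats::median(x$path_length_m),
    n_pit = sum(x$termination_reason == "pit"),
    n_edge = sum(x$termination_reason == "edge"),
    n_nodata = sum(x$termination_reason == "nodata")
  )
}
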