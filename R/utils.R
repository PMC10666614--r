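#' @importFrom rlang %||%
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# pull the footprint geometries out of whatever the caller holds
footprint_geoms <- function(footprints) {
  if (inherits(footprints, "sfer_footprint_set")) return(footprints$footprint)
  if (inherits(footprints, "sfer_footprint")) return(list(footprints$footprint))
  if (inherits(footprints, "sfer_geom")) return(list(footprints))
  if (is.list(footprints)) {
    stopifnot(all(vapply(footprints, inherits, logical(1), "sfer_geom") |
                  vapply(footprints, inherits, logical(1), "sfer_footprint")))
    return(lapply(footprints, function(f) {
      if (inherits(f, "sfer_footprint")) f$footprint else f
    }))
  }
  stop("cannot interpret 'footprints' as footprint geometries", call. = FALSE)
}
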