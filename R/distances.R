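# Distance and geometry helpers. One unit convention package-wide:
# km for distances, km^2 for areas, degrees for geographic coordinates.

# IUGG mean Earth radius, km
EARTH_RADIUS_KM <- 6371.0087714

#' Pairwise distance between coordinate pairs
#'
#' Euclidean distance for planar coordinates (already in km), haversine
#' great-circle distance for geographic coordinates (lon/lat degrees).
#'
#' @param x1,y1,x2,y2 numeric vectors; lon/lat when `coord_mode` is
#'   `"geographic"`, x/y in km when `"planar"`.
#' @param coord_mode `"planar"` or `"geographic"`.
#' @return numeric vector of distances in km.
#' @export
dist_km <- function(x1, y1, x2, y2, coord_mode = c("planar", "geographic")) {
  coord_mode <- match.arg(coord_mode)
  if (coord_mode == "planar") {
    sqrt((x1 - x2)^2 + (y1 - y2)^2)
  } else {
    geosphere::distHaversine(cbind(x1, y1), cbind(x2, y2),
                             r = EARTH_RADIUS_KM * 1000) / 1000
  }
}

# Project geographic coordinates to a local km plane using an
# equirectangular projection about the weighted mean lon/lat. Adequate at
# country scale; planar input is passed through unchanged.
project_km <- function(x, y, w = NULL, coord_mode = "planar") {
  if (coord_mode == "planar") {
    return(cbind(x = x, y = y))
  }
  if (is.null(w)) w <- rep(1, length(x))
  lon0 <- sum(w * x) / sum(w)
  lat0 <- sum(w * y) / sum(w)
  deg <- pi / 180
  cbind(x = EARTH_RADIUS_KM * cos(lat0 * deg) * (x - lon0) * deg,
        y = EARTH_RADIUS_KM * (y - lat0) * deg)
}

# Area (km^2) of the convex hull of a point set on the km plane.
# Fewer than 3 distinct non-collinear points span zero area.
hull_area_km2 <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(idx) < 3) return(0)
  abs(pracma::polyarea(pts[idx, 1], pts[idx, 2]))
}
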