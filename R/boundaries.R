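#' Administrative boundary set
#'
#' A set of simple polygons (single outer ring each, no holes) with a unique
#' `unit_id`, a parent `admin1_id` and arbitrary numeric attributes joinable
#' by `unit_id`. Geometry is stored as a list of two-column (x, y) matrices;
#' rings may be open (first vertex not repeated) or closed.
#'
#' @param units data frame with at least `unit_id` (unique) and `admin1_id`.
#' @param rings list of n x 2 coordinate matrices, one per row of `units`.
#' @return object of class `admin_boundary_set`.
#' @export
admin_boundary_set <- function(units, rings) {
  stopifnot(is.data.frame(units), length(rings) == nrow(units))
  if (anyDuplicated(units$unit_id)) stop("unit_id must be unique")
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || nrow(r) < 3) stop("each ring needs >= 3 (x, y) vertices")
    # drop closing vertex if present
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    r
  })
  structure(list(units = units, rings = rings), class = "admin_boundary_set")
}

#' @export
print.admin_boundary_set <- function(x, ...) {
  cat(sprintf("admin_boundary_set: %d units (%d admin1)\n",
              nrow(x$units), length(unique(x$units$admin1_id))))
  invisible(x)
}

# Shoelace area of one ring.
ring_area <- function(r) {
  n <- nrow(r)
  j <- c(2:n, 1)
  abs(sum(r[, 1] * r[j, 2] - r[j, 1] * r[, 2])) / 2
}

#' Total area of a boundary set (in squared degrees)
#'
#' @param b an `admin_boundary_set`.
#' @return numeric vector of polygon areas, one per unit.
#' @export
boundary_areas <- function(b) {
  vapply(b$rings, ring_area, numeric(1))
}

# Even-odd (ray casting) point-in-polygon test, vectorised over points.
# Points exactly on an edge get a deterministic result from the half-open
# crossing rule; assignment order in rasterize_attribute makes ties go to the
# first polygon in file order.
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  xj <- ring[n, 1]; yj <- ring[n, 2]
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    xj <- xi; yj <- yi
  }
  inside
}

#' Write / read boundaries as GeoJSON
#'
#' Boundaries are exchanged as a GeoJSON FeatureCollection (WGS84 lon/lat,
#' one Polygon feature per unit, attributes as feature properties).
#'
#' @param b an `admin_boundary_set`.
#' @param path file path.
#' @return `read_boundaries_geojson()` returns an `admin_boundary_set` with
#'   features in file order.
#' @export
write_boundaries_geojson <- function(b, path) {
  features <- lapply(seq_len(nrow(b$units)), function(i) {
    ring <- b$rings[[i]]
    ring <- rbind(ring, ring[1, ])  # GeoJSON rings are closed
    coords <- lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1], ring[k, 2]))
    list(type = "Feature",
         properties = as.list(b$units[i, , drop = FALSE]),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = "urn:ogc:def:crs:OGC:1.3:CRS84")),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boundaries_geojson
#' @export
read_boundaries_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  units <- do.call(rbind, lapply(fc$features, function(f) {
    as.data.frame(f$properties, stringsAsFactors = FALSE)
  }))
  rings <- lapply(fc$features, function(f) {
    if (f$geometry$type != "Polygon") stop("only Polygon features supported")
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  })
  admin_boundary_set(units, rings)
}
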