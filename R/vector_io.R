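# Vector output. Polygons are represented in R as lists with elements
#   rings      : list of n x 2 coordinate matrices (first ring = exterior,
#                others = holes); rings need not repeat the first vertex
#   properties : named list of attributes
# and written as GeoJSON FeatureCollections (RFC 7946) via jsonlite.

# Segment-intersection test for ring self-intersection (proper crossings
# between non-adjacent edges). O(n^2); rings here are small pixel boundaries.
#' @noRd
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4L) return(FALSE)
  p <- rbind(ring, ring[1L, , drop = FALSE])
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  segs_cross <- function(a1, a2, b1, b2) {
    d1 <- cross(b1, b2, a1); d2 <- cross(b1, b2, a2)
    d3 <- cross(a1, a2, b1); d4 <- cross(a1, a2, b2)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1L || (i == 1L && j == n) || (i == n && j == 1L)) next
      if (j <= i) next
      if (segs_cross(p[i, ], p[i + 1L, ], p[j, ], p[j + 1L, ])) return(TRUE)
    }
  }
  FALSE
}

#' @noRd
close_ring <- function(ring) {
  if (!isTRUE(all(ring[1L, ] == ring[nrow(ring), ]))) {
    ring <- rbind(ring, ring[1L, , drop = FALSE])
  }
  ring
}

#' Write georeferenced polygons to a vector file
#'
#' @param polygons list of polygons; each a list with `rings` (list of n x 2
#'   coordinate matrices, exterior first) and optional `properties` (named
#'   list). An empty list writes a valid empty FeatureCollection.
#' @param path output file path.
#' @param format only `"GeoJSON"` is supported; `"Shapefile"` raises an
#'   informative error (no GDAL-backed writer is available to this package).
#' @param crs optional CRS identifier recorded as a foreign member.
#' @return `path`, invisibly.
#' @export
write_vector <- function(polygons, path, format = c("GeoJSON", "Shapefile"),
                         crs = NULL) {
  format <- match.arg(format)
  if (format == "Shapefile") {
    stop("Shapefile output is not supported; write GeoJSON instead",
         call. = FALSE)
  }
  features <- vector("list", length(polygons))
  for (i in seq_along(polygons)) {
    poly <- polygons[[i]]
    rings <- poly$rings
    if (is.null(rings)) stop("polygon ", i, " has no rings", call. = FALSE)
    coords <- vector("list", length(rings))
    for (k in seq_along(rings)) {
      ring <- as.matrix(rings[[k]])
      if (ncol(ring) != 2L || nrow(ring) < 3L) {
        stop("polygon ", i, " ring ", k, " is not a valid ring", call. = FALSE)
      }
      if (ring_self_intersects(ring)) {
        stop("polygon ", i, " ring ", k, " is self-intersecting", call. = FALSE)
      }
      coords[[k]] <- close_ring(ring)
    }
    props <- poly$properties %||% stats::setNames(list(), character())
    features[[i]] <- list(
      type = "Feature",
      properties = props,
      geometry = list(type = "Polygon", coordinates = coords)
    )
  }
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(crs) && nzchar(crs)) fc$crs_id <- crs
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection written by [write_vector()]
#'
#' @param path file path.
#' @return list of polygons in the [write_vector()] representation.
#' @export
read_vector <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("'", path, "' is not a GeoJSON FeatureCollection", call. = FALSE)
  }
  lapply(fc$features, function(f) {
    rings <- lapply(f$geometry$coordinates, function(rg) {
      do.call(rbind, lapply(rg, function(pt) c(pt[[1]], pt[[2]])))
    })
    list(rings = rings, properties = f$properties)
  })
}

#' @noRd
shoelace_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}
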