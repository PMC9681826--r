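# Georeferencing helpers. The geotransform follows the GDAL convention:
# a numeric vector gt of length 6 with, for 0-based (col, row) pixel-corner
# coordinates,
#   x = gt[1] + col * gt[2] + row * gt[3]
#   y = gt[4] + col * gt[5] + row * gt[6]
# so gt[1], gt[4] locate the outer corner of the top-left pixel and pixel
# centers sit at (col + 0.5, row + 0.5). Rows run top-down (gt[6] < 0 for
# north-up rasters).

#' Construct a geotransform
#'
#' @param x0,y0 map coordinates of the outer corner of the top-left pixel.
#' @param px_x pixel width in map units (positive).
#' @param px_y pixel height in map units (positive; stored negative because
#'   rows run top-down).
#' @return numeric vector of length 6 (GDAL ordering).
#' @export
geotransform <- function(x0 = 0, y0 = 0, px_x = 1, px_y = px_x) {
  stopifnot(is.numeric(x0), is.numeric(y0), px_x > 0, px_y > 0)
  c(x0, px_x, 0, y0, 0, -px_y)
}

#' @noRd
check_geotransform <- function(gt) {
  if (!is.numeric(gt) || length(gt) != 6L || any(!is.finite(gt))) {
    stop("geotransform must be 6 finite numbers (GDAL ordering)", call. = FALSE)
  }
  if (gt[2] == 0 || gt[6] == 0) {
    stop("geotransform has zero pixel size", call. = FALSE)
  }
  invisible(gt)
}

#' @noRd
pixel_size <- function(gt) c(x = abs(gt[2]), y = abs(gt[6]))

# Map coordinates of pixel centers for 1-based (row, col).
#' @noRd
pixel_center_xy <- function(gt, row, col) {
  cc <- col - 0.5
  rr <- row - 0.5
  list(x = gt[1] + cc * gt[2] + rr * gt[3],
       y = gt[4] + cc * gt[5] + rr * gt[6])
}

# Map coordinates of a pixel-corner lattice point (0-based corner indices).
#' @noRd
corner_xy <- function(gt, corner_row, corner_col) {
  list(x = gt[1] + corner_col * gt[2] + corner_row * gt[3],
       y = gt[4] + corner_col * gt[5] + corner_row * gt[6])
}

# Heuristic CRS classification: the package never reprojects, but metric
# operations (prescription gridding) must refuse degree-unit CRSs.
#' @noRd
crs_is_projected <- function(crs) {
  if (is.null(crs) || !nzchar(crs)) return(NA)
  s <- toupper(crs)
  geographic_epsg <- c("4326", "4269", "4258", "4490")
  if (grepl("EPSG", s)) {
    code <- sub(".*EPSG[:]{1,2}\\s*([0-9]+).*", "\\1", s)
    if (code %in% geographic_epsg) return(FALSE)
    return(TRUE)
  }
  if (grepl("LONGLAT|DEGREE", s)) return(FALSE)
  if (grepl("PROJCS|PROJCRS|\\+PROJ=", s)) return(TRUE)
  if (grepl("GEOGCS|GEOGCRS", s)) return(FALSE)
  NA
}
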