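#' Band name to band index mapping for a five-band multispectral sensor
#'
#' The pipeline assumes a five-band sensor covering blue (B), green (G),
#' red (R), red edge (RE) and near infrared (NIR). A `band_map` records, for
#' each band name, which band (page) of the source raster holds it and the
#' band's center wavelength and half-width in nanometres. Center wavelengths
#' must increase strictly in the order B < G < R < RE < NIR.
#'
#' @param index named integer vector giving the source band index for each of
#'   `B, G, R, RE, NIR` (1-based).
#' @param center named numeric vector of center wavelengths in nm.
#' @param half_width named numeric vector of half-widths in nm.
#' @return A `band_map` object (a data frame with columns `band`, `index`,
#'   `center_nm`, `half_width_nm`).
#' @examples
#' band_map() # the default 450/560/650/730/840 nm layout
#' @export
band_map <- function(index = c(B = 1L, G = 2L, R = 3L, RE = 4L, NIR = 5L),
                     center = c(B = 450, G = 560, R = 650, RE = 730, NIR = 840),
                     half_width = c(B = 16, G = 16, R = 16, RE = 16, NIR = 26)) {
  bands <- c("B", "G", "R", "RE", "NIR")
  for (arg in list(index, center, half_width)) {
    nm <- names(arg)
    if (is.null(nm) || !setequal(nm, bands) || anyDuplicated(nm)) {
      stop("band_map arguments must be named with exactly B, G, R, RE, NIR",
           call. = FALSE)
    }
  }
  index <- as.integer(index[bands])
  center <- as.numeric(center[bands])
  half_width <- as.numeric(half_width[bands])
  if (any(index < 1L)) stop("band indices must be >= 1", call. = FALSE)
  if (anyDuplicated(index)) stop("band indices must be distinct", call. = FALSE)
  if (any(diff(center) <= 0)) {
    stop("center wavelengths must increase strictly in the order ",
         "B < G < R < RE < NIR", call. = FALSE)
  }
  if (any(half_width <= 0)) stop("half-widths must be positive", call. = FALSE)
  structure(
    data.frame(band = bands, index = index, center_nm = center,
               half_width_nm = half_width, stringsAsFactors = FALSE),
    class = c("band_map", "data.frame")
  )
}

#' @export
print.band_map <- function(x, ...) {
  cat("<band_map> five-band multispectral layout\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @noRd
band_names <- function() c("B", "G", "R", "RE", "NIR")
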