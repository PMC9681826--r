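# Radiometric calibration and vegetation indices.
#
# The weed discrimination index family is built in two steps: every band is
# first expressed as a ratio to a chosen "transfer" band x_t, and the index is
# the base-10 log of the quotient of two such ratios,
#
#   WDVI = log10( (x_b / x_t) / (x_a / x_t) )
#
# The transfer band cancels algebraically, so the index reduces to
# log10(x_b / x_a); the computation below nevertheless follows the two-ratio
# construction literally, and a property test asserts the cancellation.

#' Reference-panel calibration constants
#'
#' Single-point linear calibration through the origin: a Lambertian panel of
#' known reflectance is imaged alongside the scene, and each band's mean panel
#' digital number (DN) anchors the DN-to-reflectance scale for that band.
#'
#' @param panel_reflectance panel reflectance in (0, 1]; gray reference panels
#'   of 0.60 reflectance are typical for paddy surveys.
#' @param panel_dn named numeric vector of mean panel DN per band
#'   (`B, G, R, RE, NIR`), strictly positive.
#' @return A `panel_calibration` object.
#' @export
panel_calibration <- function(panel_reflectance = 0.60,
                              panel_dn = c(B = 1, G = 1, R = 1, RE = 1, NIR = 1)) {
  if (!is.numeric(panel_reflectance) || length(panel_reflectance) != 1L ||
      panel_reflectance <= 0 || panel_reflectance > 1) {
    stop("panel_reflectance must be a single value in (0, 1]", call. = FALSE)
  }
  nm <- names(panel_dn)
  if (is.null(nm) || !setequal(nm, band_names())) {
    stop("panel_dn must be named with exactly B, G, R, RE, NIR", call. = FALSE)
  }
  panel_dn <- as.numeric(panel_dn[band_names()])
  names(panel_dn) <- band_names()
  if (any(!is.finite(panel_dn)) || any(panel_dn <= 0)) {
    stop("panel_dn must be strictly positive in every band", call. = FALSE)
  }
  structure(list(panel_reflectance = panel_reflectance, panel_dn = panel_dn),
            class = "panel_calibration")
}

#' @export
print.panel_calibration <- function(x, ...) {
  cat(sprintf("<panel_calibration> panel reflectance %.2f\n",
              x$panel_reflectance))
  print(x$panel_dn)
  invisible(x)
}

#' Calibrate raw digital numbers to reflectance
#'
#' Per band, `reflectance = DN * panel_reflectance / panel_dn[band]`. Values
#' may exceed 1 (e.g. specular water glint); they are not clipped, but a
#' warning reports how many calibrated pixels exceed 1.
#'
#' @param dn_image a [multispec_image()] holding raw DN values.
#' @param cal a [panel_calibration()].
#' @return A [multispec_image()] in reflectance units; the valid mask is
#'   preserved.
#' @export
calibrate_reflectance <- function(dn_image, cal) {
  stopifnot(inherits(dn_image, "multispec_image"),
            inherits(cal, "panel_calibration"))
  bands <- dn_image$bands
  n_over <- 0L
  for (nm in band_names()) {
    refl <- bands[[nm]] * cal$panel_reflectance / cal$panel_dn[[nm]]
    n_over <- n_over + sum(refl[dn_image$valid_mask] > 1)
    bands[[nm]] <- refl
  }
  if (n_over > 0L) {
    warning(n_over, " calibrated pixel value(s) exceed reflectance 1 ",
            "(not clipped)", call. = FALSE)
  }
  multispec_image(bands, valid_mask = dn_image$valid_mask,
                  geotransform = dn_image$geotransform, crs = dn_image$crs,
                  band_map = dn_image$band_map)
}

#' Specification of one weed-discrimination index variant
#'
#' @param numerator_band band name whose transfer ratio forms the numerator.
#' @param denominator_band band name whose transfer ratio forms the
#'   denominator; must differ from `numerator_band`.
#' @param transfer_band band name used as the (cancelling) transfer band;
#'   must differ from both.
#' @return A `wdvi_spec` object.
#' @export
wdvi_spec <- function(numerator_band, denominator_band, transfer_band = "NIR") {
  bn <- band_names()
  for (b in c(numerator_band, denominator_band, transfer_band)) {
    if (!b %in% bn) stop("unknown band name '", b, "'", call. = FALSE)
  }
  if (numerator_band == denominator_band ||
      numerator_band == transfer_band || denominator_band == transfer_band) {
    stop("numerator, denominator and transfer bands must be three distinct ",
         "bands", call. = FALSE)
  }
  structure(list(numerator_band = numerator_band,
                 denominator_band = denominator_band,
                 transfer_band = transfer_band),
            class = "wdvi_spec")
}

# The five named variants of the family (transfer band NIR), plus the
# flagship WDVI_NIR (green over red-edge through NIR), which coincides with
# variant 1.
#' @noRd
wdvi_variant_table <- function() {
  list(
    WDVI1 = c("G", "RE"),
    WDVI2 = c("R", "RE"),
    WDVI3 = c("RE", "R"),
    WDVI4 = c("R", "G"),
    WDVI5 = c("G", "R")
  )
}

#' @noRd
wdvi_name_for <- function(spec) {
  for (nm in names(wdvi_variant_table())) {
    v <- wdvi_variant_table()[[nm]]
    if (spec$numerator_band == v[1] && spec$denominator_band == v[2]) {
      return(if (nm == "WDVI1") "WDVI_NIR" else nm)
    }
  }
  sprintf("WDVI(%s/%s|%s)", spec$numerator_band, spec$denominator_band,
          spec$transfer_band)
}

#' Compute a weed-discrimination index raster
#'
#' Evaluates `log10((x_b / x_t) / (x_a / x_t))` per pixel, where `x_b`, `x_a`
#' and `x_t` are the numerator, denominator and transfer bands of `spec`.
#' Pixels where any of the three bands is not strictly positive are
#' invalidated (not epsilon-clamped: a clamped pixel would fabricate an
#' extreme index value that could survive thresholding) and their count is
#' reported as a warning.
#'
#' @param image a [multispec_image()] in reflectance units.
#' @param spec a [wdvi_spec()].
#' @return An [index_raster()]; `index_name` is `WDVI_NIR` for the
#'   green/red-edge variant, `WDVI2`..`WDVI5` for the other named variants.
#' @examples
#' img <- generate_scene(scene_spec(shape = c(32, 32)))$image
#' wd <- compute_wdvi(img, wdvi_spec("G", "RE", "NIR"))
#' @export
compute_wdvi <- function(image, spec) {
  stopifnot(inherits(image, "multispec_image"), inherits(spec, "wdvi_spec"))
  xb <- image$bands[[spec$numerator_band]]
  xa <- image$bands[[spec$denominator_band]]
  xt <- image$bands[[spec$transfer_band]]
  ok <- image$valid_mask & xb > 0 & xa > 0 & xt > 0
  n_dropped <- sum(image$valid_mask) - sum(ok)
  if (n_dropped > 0L) {
    warning(n_dropped, " pixel(s) with non-positive band values invalidated ",
            "for ", wdvi_name_for(spec), call. = FALSE)
  }
  wf <- xb / xt
  bf <- xa / xt
  vals <- matrix(NA_real_, nrow(xb), ncol(xb))
  vals[ok] <- log10(wf[ok] / bf[ok])
  index_raster(vals, valid_mask = ok, geotransform = image$geotransform,
               crs = image$crs, index_name = wdvi_name_for(spec))
}

#' Enumerate the five named index variants
#'
#' Returns the five band combinations of the family (all with transfer band
#' NIR): green/red-edge, red/red-edge, red-edge/red, red/green and green/red,
#' in that order.
#'
#' @param image a [multispec_image()].
#' @return list of five elements, each `list(spec = wdvi_spec, raster =
#'   index_raster)`, named `WDVI1`..`WDVI5`.
#' @export
enumerate_wdvi_family <- function(image) {
  out <- list()
  for (nm in names(wdvi_variant_table())) {
    v <- wdvi_variant_table()[[nm]]
    spec <- wdvi_spec(v[1], v[2], "NIR")
    out[[nm]] <- list(spec = spec, raster = compute_wdvi(image, spec))
  }
  out
}

#' Compute a classical comparison vegetation index
#'
#' Standard literature definitions:
#' \describe{
#'   \item{NDVI}{`(NIR - R) / (NIR + R)`}
#'   \item{GNDVI}{`(NIR - G) / (NIR + G)`}
#'   \item{NDRE}{`(NIR - RE) / (NIR + RE)`}
#'   \item{LCI}{`(NIR - RE) / (NIR + R)`}
#'   \item{OSAVI}{`(NIR - R) / (NIR + R + 0.16)`}
#' }
#' Pixels with a zero denominator or any required band invalid are
#' invalidated and counted.
#'
#' @param image a [multispec_image()] in reflectance units.
#' @param name one of `"NDVI"`, `"GNDVI"`, `"LCI"`, `"NDRE"`, `"OSAVI"`.
#' @return An [index_raster()].
#' @export
compute_comparison_index <- function(image,
                                     name = c("NDVI", "GNDVI", "LCI", "NDRE",
                                              "OSAVI")) {
  stopifnot(inherits(image, "multispec_image"))
  name <- match.arg(name)
  b <- image$bands
  num <- switch(name,
    NDVI  = b$NIR - b$R,
    GNDVI = b$NIR - b$G,
    NDRE  = b$NIR - b$RE,
    LCI   = b$NIR - b$RE,
    OSAVI = b$NIR - b$R
  )
  den <- switch(name,
    NDVI  = b$NIR + b$R,
    GNDVI = b$NIR + b$G,
    NDRE  = b$NIR + b$RE,
    LCI   = b$NIR + b$R,
    OSAVI = b$NIR + b$R + 0.16
  )
  ok <- image$valid_mask & den != 0
  n_dropped <- sum(image$valid_mask) - sum(ok)
  if (n_dropped > 0L) {
    warning(n_dropped, " pixel(s) with zero denominator invalidated for ",
            name, call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow(num), ncol(num))
  vals[ok] <- num[ok] / den[ok]
  index_raster(vals, valid_mask = ok, geotransform = image$geotransform,
               crs = image$crs, index_name = name)
}

#' Compute any supported index by name
#'
#' Convenience dispatcher used by the pipeline and command line: accepts the
#' named family variants (`WDVI_NIR`, `WDVI1`..`WDVI5`) and the comparison
#' indices.
#'
#' @param image a [multispec_image()].
#' @param name index name.
#' @return An [index_raster()].
#' @export
compute_index <- function(image, name) {
  if (name %in% c("NDVI", "GNDVI", "LCI", "NDRE", "OSAVI")) {
    return(compute_comparison_index(image, name))
  }
  key <- if (identical(name, "WDVI_NIR")) "WDVI1" else name
  tab <- wdvi_variant_table()
  if (!key %in% names(tab)) {
    stop("unknown index name '", name, "'", call. = FALSE)
  }
  v <- tab[[key]]
  compute_wdvi(image, wdvi_spec(v[1], v[2], "NIR"))
}
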