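# Core in-memory containers. All grids are base matrices indexed [row, col]
# with row 1 at the top, matching the raster file layout.

#' Five-band multispectral reflectance image
#'
#' @param bands named list of five numeric matrices (names `B, G, R, RE, NIR`),
#'   all of identical dimension, holding surface reflectance (or raw digital
#'   numbers prior to [calibrate_reflectance()]).
#' @param valid_mask logical matrix, `TRUE` where the pixel is valid in every
#'   band. A pixel invalid in any band is invalid in all: index arithmetic
#'   needs the full spectrum.
#' @param geotransform numeric length-6 geotransform (see [geotransform()]).
#' @param crs character CRS identifier (e.g. `"EPSG:32651"`); may be `""`.
#' @param band_map a [band_map()] describing the sensor layout.
#' @return A `multispec_image` object.
#' @export
multispec_image <- function(bands, valid_mask = NULL,
                            geotransform = paddyweed::geotransform(),
                            crs = "", band_map = paddyweed::band_map()) {
  if (!is.list(bands) || !setequal(names(bands), band_names())) {
    stop("bands must be a named list with exactly B, G, R, RE, NIR",
         call. = FALSE)
  }
  bands <- bands[band_names()]
  lapply(bands, assert_matrix2d, what = "band")
  dims <- lapply(bands, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all bands must share identical dimensions", call. = FALSE)
  }
  if (is.null(valid_mask)) {
    valid_mask <- Reduce(`&`, lapply(bands, function(b) is.finite(b)))
  }
  assert_matrix2d(valid_mask, "valid_mask")
  storage.mode(valid_mask) <- "logical"
  if (!same_dim(valid_mask, bands[[1]])) {
    stop("valid_mask dimensions must match the bands", call. = FALSE)
  }
  valid_mask[is.na(valid_mask)] <- FALSE
  check_geotransform(geotransform)
  bad <- vapply(bands, function(b) {
    any(valid_mask & (!is.finite(b) | b < 0))
  }, logical(1))
  if (any(bad)) {
    stop("non-finite or negative values on valid pixels in band(s): ",
         paste(names(bands)[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    list(bands = bands, valid_mask = valid_mask,
         geotransform = as.numeric(geotransform), crs = as.character(crs),
         band_map = band_map),
    class = "multispec_image"
  )
}

#' @export
print.multispec_image <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<multispec_image> %d x %d pixels, 5 bands (B G R RE NIR)\n",
              d[1], d[2]))
  cat(sprintf("  valid pixels : %d / %d\n", sum(x$valid_mask), prod(d)))
  cat(sprintf("  pixel size   : %g x %g map units\n",
              pixel_size(x$geotransform)["x"], pixel_size(x$geotransform)["y"]))
  if (nzchar(x$crs)) cat("  crs          :", x$crs, "\n")
  invisible(x)
}

#' @export
dim.multispec_image <- function(x) dim(x$bands[[1]])

#' Single-band vegetation-index raster
#'
#' @param values numeric matrix of index values.
#' @param valid_mask logical matrix; `FALSE` pixels carry no value.
#' @param geotransform,crs georeferencing, as in [multispec_image()].
#' @param index_name label such as `"WDVI_NIR"` or `"NDVI"`.
#' @return An `index_raster` object.
#' @export
index_raster <- function(values, valid_mask = NULL,
                         geotransform = paddyweed::geotransform(), crs = "",
                         index_name = "index") {
  assert_matrix2d(values, "values")
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  assert_matrix2d(valid_mask, "valid_mask")
  storage.mode(valid_mask) <- "logical"
  valid_mask[is.na(valid_mask)] <- FALSE
  if (!same_dim(values, valid_mask)) {
    stop("values and valid_mask dimensions differ", call. = FALSE)
  }
  if (any(valid_mask & !is.finite(values))) {
    stop("non-finite index values on valid pixels", call. = FALSE)
  }
  check_geotransform(geotransform)
  structure(
    list(values = values, valid_mask = valid_mask,
         geotransform = as.numeric(geotransform), crs = as.character(crs),
         index_name = as.character(index_name)),
    class = "index_raster"
  )
}

#' @export
print.index_raster <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[x$valid_mask]
  cat(sprintf("<index_raster> %s, %d x %d pixels\n", x$index_name, d[1], d[2]))
  if (length(v)) {
    cat(sprintf("  range on valid pixels: [%.5g, %.5g]\n", min(v), max(v)))
  }
  invisible(x)
}

#' @export
dim.index_raster <- function(x) dim(x$values)

#' Quantized gray-level raster
#'
#' Integer grid with values in `[0, L-1]` on valid pixels; the domain of
#' density slicing. `scaling` records the (min, max) index values mapped to
#' gray levels 0 and L-1, so a slice threshold is transferable between images.
#'
#' @param values integer matrix.
#' @param levels number of gray levels L (>= 2).
#' @param valid_mask logical matrix.
#' @param geotransform,crs georeferencing.
#' @param scaling numeric length-2 `(min, max)` used by the quantization.
#' @return A `gray_raster` object.
#' @export
gray_raster <- function(values, levels, valid_mask = NULL,
                        geotransform = paddyweed::geotransform(), crs = "",
                        scaling = c(NA_real_, NA_real_)) {
  assert_matrix2d(values, "values")
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (is.null(valid_mask)) valid_mask <- !is.na(values)
  storage.mode(valid_mask) <- "logical"
  valid_mask[is.na(valid_mask)] <- FALSE
  storage.mode(values) <- "integer"
  v <- values[valid_mask]
  if (length(v) && (anyNA(v) || min(v) < 0L || max(v) > levels - 1L)) {
    stop("gray values on valid pixels must lie in [0, L-1]", call. = FALSE)
  }
  check_geotransform(geotransform)
  structure(
    list(values = values, levels = levels, valid_mask = valid_mask,
         geotransform = as.numeric(geotransform), crs = as.character(crs),
         scaling = as.numeric(scaling)),
    class = "gray_raster"
  )
}

#' @export
print.gray_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gray_raster> %d x %d pixels, L = %d\n", d[1], d[2], x$levels))
  if (all(is.finite(x$scaling))) {
    cat(sprintf("  scaling: index [%.5g, %.5g] -> gray [0, %d]\n",
                x$scaling[1], x$scaling[2], x$levels - 1L))
  }
  invisible(x)
}

#' Binary weed mask
#'
#' Boolean grid (`TRUE` = weed) with georeferencing and a provenance list
#' recording every processing step (density slice, majority filter, clump)
#' with its parameters, so a classification is auditable and reproducible.
#'
#' @param values logical matrix, `TRUE` where weed.
#' @param valid_mask logical matrix; weed pixels must be a subset of valid.
#' @param geotransform,crs georeferencing.
#' @param provenance list of processing-step records.
#' @return A `weed_mask` object.
#' @export
weed_mask <- function(values, valid_mask = NULL,
                      geotransform = paddyweed::geotransform(), crs = "",
                      provenance = list()) {
  assert_matrix2d(values, "values")
  storage.mode(values) <- "logical"
  if (is.null(valid_mask)) valid_mask <- !is.na(values)
  storage.mode(valid_mask) <- "logical"
  valid_mask[is.na(valid_mask)] <- FALSE
  if (!same_dim(values, valid_mask)) {
    stop("values and valid_mask dimensions differ", call. = FALSE)
  }
  values[is.na(values)] <- FALSE
  if (any(values & !valid_mask)) {
    stop("weed pixels must be a subset of valid pixels", call. = FALSE)
  }
  check_geotransform(geotransform)
  structure(
    list(values = values, valid_mask = valid_mask,
         geotransform = as.numeric(geotransform), crs = as.character(crs),
         provenance = provenance),
    class = "weed_mask"
  )
}

#' @export
print.weed_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<weed_mask> %d x %d pixels, %d weed / %d valid\n",
              d[1], d[2], sum(x$values), sum(x$valid_mask)))
  if (length(x$provenance)) {
    cat("  provenance:\n")
    for (p in x$provenance) {
      pars <- p[setdiff(names(p), "step")]
      cat(sprintf("   - %s(%s)\n", p$step,
                  paste(names(pars), vapply(pars, function(z)
                    paste(format(z), collapse = ","), ""),
                    sep = "=", collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
dim.weed_mask <- function(x) dim(x$values)

#' @noRd
append_provenance <- function(mask, step, ...) {
  mask$provenance <- c(mask$provenance, list(c(list(step = step), list(...))))
  mask
}

#' @noRd
check_same_georef <- function(a, b, what = "rasters") {
  if (!same_dim(a$values %||% a$bands[[1]], b$values %||% b$bands[[1]])) {
    stop(what, " have different dimensions", call. = FALSE)
  }
  if (!isTRUE(all.equal(a$geotransform, b$geotransform, tolerance = 1e-9))) {
    stop(what, " have different geotransforms", call. = FALSE)
  }
  if (nzchar(a$crs) && nzchar(b$crs) && !identical(a$crs, b$crs)) {
    stop(what, " have different CRSs", call. = FALSE)
  }
  invisible(TRUE)
}
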