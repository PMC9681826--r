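# Raster file I/O.
#
# On-disk format: a multi-page TIFF (one page per band, plus a trailing 0/1
# validity-mask page) accompanied by two sidecars:
#   <path>.aux.json  - grid type, band names, value scaling, geotransform, CRS
#   <basename>.tfw   - ESRI world file (pixel-center convention), so GDAL-based
#                      tools can georeference the TIFF directly
# Real-valued grids are affine-scaled into [0, 1] before float32 storage (the
# TIFF baseline float path clamps values outside [0, 1]); the scaling is
# recorded in the sidecar and undone on read, so round trips are exact to
# float32 precision. Integer and boolean grids are stored as unsigned 8- or
# 16-bit samples and round-trip exactly.

AUX_FORMAT_VERSION <- 1L

#' @noRd
aux_path <- function(path) paste0(path, ".aux.json")

#' @noRd
world_file_path <- function(path) paste0(tools::file_path_sans_ext(path), ".tfw")

# World file lines: px_x, rot_y, rot_x, px_y(negative), x_center_TL, y_center_TL
#' @noRd
write_world_file <- function(gt, path) {
  ctr <- pixel_center_xy(gt, 1, 1)
  writeLines(format(c(gt[2], gt[5], gt[3], gt[6], ctr$x, ctr$y), digits = 17),
             world_file_path(path))
}

#' @noRd
read_world_file <- function(path) {
  wf <- world_file_path(path)
  if (!file.exists(wf)) return(NULL)
  v <- as.numeric(readLines(wf, n = 6))
  if (length(v) != 6 || anyNA(v)) return(NULL)
  # invert the pixel-center convention back to the corner-anchored transform
  gt <- c(NA, v[1], v[3], NA, v[2], v[4])
  gt[1] <- v[5] - 0.5 * gt[2] - 0.5 * gt[3]
  gt[4] <- v[6] - 0.5 * gt[5] - 0.5 * gt[6]
  gt
}

#' @noRd
write_aux <- function(path, meta) {
  jsonlite::write_json(meta, aux_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' @noRd
read_aux <- function(path) {
  ap <- aux_path(path)
  if (!file.exists(ap)) return(NULL)
  jsonlite::read_json(ap, simplifyVector = TRUE)
}

#' @noRd
grid_type_of <- function(grid) {
  if (is.logical(grid)) "boolean"
  else if (is.integer(grid)) "integer"
  else "real"
}

# Encode one data page for TIFF storage; returns list(page, bits, scaling)
#' @noRd
encode_page <- function(values, valid, type, scaling = NULL) {
  v <- values
  v[!valid] <- 0
  if (type == "boolean") {
    list(page = matrix(as.numeric(v) / 255, nrow(v), ncol(v)),
         bits = 8L, scaling = NULL)
  } else if (type == "integer") {
    vmax <- max(v, 0L)
    if (vmax > 65535L) stop("integer grids above 65535 are not supported",
                            call. = FALSE)
    bits <- if (vmax > 255L) 16L else 8L
    list(page = v / (2^bits - 1), bits = bits, scaling = NULL)
  } else {
    if (is.null(scaling)) {
      fin <- values[valid & is.finite(values)]
      scaling <- if (length(fin)) range(fin) else c(0, 1)
      if (scaling[1] == scaling[2]) scaling[2] <- scaling[1] + 1
    }
    sc <- (v - scaling[1]) / (scaling[2] - scaling[1])
    sc[!valid | !is.finite(sc)] <- 0
    sc[sc < 0] <- 0
    sc[sc > 1] <- 1
    list(page = sc, bits = 32L, scaling = scaling)
  }
}

#' @noRd
decode_page <- function(page, type, scaling = NULL) {
  if (type == "boolean") {
    storage.mode(page) <- "logical"
    page
  } else if (type == "integer") {
    storage.mode(page) <- "integer"
    page
  } else {
    scaling[1] + page * (scaling[2] - scaling[1])
  }
}

#' Write a single-band georeferenced raster
#'
#' Writes a matrix (real, integer or boolean) or a package raster object
#' ([index_raster()], [gray_raster()], [weed_mask()]) as a multi-page TIFF
#' with a validity-mask page and JSON/world-file sidecars. Booleans are stored
#' as 0/1.
#'
#' @param grid matrix or raster object to write.
#' @param georef list with elements `geotransform` (length-6 numeric) and
#'   `crs` (character); ignored when `grid` carries its own georeferencing.
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @seealso [read_raster()]
#' @export
write_raster <- function(grid, georef = NULL, path) {
  extra <- list()
  if (inherits(grid, c("index_raster", "gray_raster", "weed_mask"))) {
    georef <- list(geotransform = grid$geotransform, crs = grid$crs)
    if (inherits(grid, "gray_raster")) {
      extra <- list(levels = grid$levels, scaling_gray = grid$scaling)
    }
    if (inherits(grid, "index_raster")) extra <- list(index_name = grid$index_name)
    valid <- grid$valid_mask
    grid <- grid$values
  } else {
    valid <- if (is.logical(grid)) !is.na(grid) else is.finite(grid) | is.na(grid)
    valid <- valid & !is.na(grid)
  }
  assert_matrix2d(grid, "grid")
  if (is.null(georef) || is.null(georef$geotransform)) {
    stop("georef with a geotransform is required", call. = FALSE)
  }
  check_geotransform(georef$geotransform)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  type <- grid_type_of(grid)
  enc <- encode_page(grid, valid, type)
  mask_div <- if (enc$bits == 32L) 1 else 2^enc$bits - 1
  mask_page <- matrix(as.numeric(valid) / mask_div, nrow(grid), ncol(grid))
  ok <- try(suppressWarnings(
    tiff::writeTIFF(list(enc$page, mask_page), path,
                    bits.per.sample = enc$bits)), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("cannot write raster to '", path, "': ",
         attr(ok, "condition")$message, call. = FALSE)
  }
  meta <- c(list(format_version = AUX_FORMAT_VERSION, type = type,
                 n_pages = 2L, mask_page = 2L,
                 scaling = enc$scaling,
                 geotransform = georef$geotransform,
                 crs = georef$crs %||% ""),
            extra)
  write_aux(path, meta)
  write_world_file(georef$geotransform, path)
  invisible(path)
}

# Read all pages of a TIFF as a list of plain matrices (multi-sample pages are
# split into per-sample matrices).
#' @noRd
read_tiff_pages <- function(path, as_is = FALSE) {
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = as_is))
  out <- list()
  for (p in pages) {
    if (length(dim(p)) == 3L) {
      for (s in seq_len(dim(p)[3])) out <- c(out, list(p[, , s]))
    } else {
      out <- c(out, list(p))
    }
  }
  out
}

#' Read a single-band raster written by [write_raster()]
#'
#' @param path file path.
#' @return list with `values` (matrix; `NA` on invalid pixels for real grids),
#'   `valid_mask`, `geotransform`, `crs`, `type` and any extra metadata stored
#'   in the sidecar.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  meta <- read_aux(path)
  if (is.null(meta)) stop("missing sidecar '", aux_path(path),
                          "'; not a raster written by this package",
                          call. = FALSE)
  as_is <- meta$type %in% c("integer", "boolean")
  pages <- read_tiff_pages(path, as_is = as_is)
  mask_raw <- pages[[meta$mask_page]]
  valid <- matrix(as.vector(mask_raw) > 0, nrow(mask_raw), ncol(mask_raw))
  values <- decode_page(pages[[1L]], meta$type, meta$scaling)
  if (meta$type == "real") values[!valid] <- NA_real_
  res <- list(values = values, valid_mask = valid,
              geotransform = as.numeric(meta$geotransform),
              crs = meta$crs %||% "", type = meta$type)
  for (nm in setdiff(names(meta),
                     c("format_version", "type", "n_pages", "mask_page",
                       "scaling", "geotransform", "crs"))) {
    res[[nm]] <- meta[[nm]]
  }
  res
}

#' Write a five-band multispectral image
#'
#' Band pages are written in B, G, R, RE, NIR order with a trailing validity
#' mask page; a shared value scaling is recorded in the sidecar.
#'
#' @param image a [multispec_image()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_multispectral <- function(image, path) {
  stopifnot(inherits(image, "multispec_image"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  allv <- unlist(lapply(image$bands, function(b) b[image$valid_mask]))
  scaling <- if (length(allv)) range(allv[is.finite(allv)]) else c(0, 1)
  if (scaling[1] == scaling[2]) scaling[2] <- scaling[1] + 1
  pages <- lapply(image$bands, function(b) {
    encode_page(b, image$valid_mask, "real", scaling)$page
  })
  pages <- c(unname(pages), list(matrix(as.numeric(image$valid_mask),
                                        nrow(image$valid_mask),
                                        ncol(image$valid_mask))))
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  write_aux(path, list(
    format_version = AUX_FORMAT_VERSION, type = "multispectral",
    n_pages = 6L, mask_page = 6L, band_names = band_names(),
    scaling = scaling, geotransform = image$geotransform, crs = image$crs,
    band_index = as.list(stats::setNames(image$band_map$index,
                                         image$band_map$band)),
    center_nm = as.list(stats::setNames(image$band_map$center_nm,
                                        image$band_map$band))
  ))
  write_world_file(image$geotransform, path)
  invisible(path)
}

#' Read a five-band multispectral image from a (Geo-referenced) TIFF
#'
#' Reads either a file written by [write_multispectral()] or a foreign
#' multi-page TIFF with at least five band pages. Georeferencing comes from
#' the JSON sidecar if present, otherwise from a world file; a file with
#' neither is rejected. For sidecar-less files a `nodata` value may be given;
#' a pixel equal to `nodata` in any band is invalid in all bands.
#'
#' @param path file path.
#' @param band_map a [band_map()] giving source page index per band name.
#' @param nodata optional nodata value for foreign files.
#' @param crs optional CRS override for foreign files.
#' @return A [multispec_image()].
#' @export
read_multispectral <- function(path, band_map = paddyweed::band_map(),
                               nodata = NULL, crs = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  meta <- read_aux(path)
  pages <- read_tiff_pages(path, as_is = FALSE)
  is_native <- !is.null(meta) && identical(meta$type, "multispectral")
  n_data_pages <- if (is_native) meta$n_pages - 1L else length(pages)
  if (max(band_map$index) > n_data_pages) {
    stop("file has ", n_data_pages, " band page(s) but band_map needs index ",
         max(band_map$index), call. = FALSE)
  }
  gt <- if (!is.null(meta)) as.numeric(meta$geotransform) else read_world_file(path)
  if (is.null(gt)) {
    stop("no geotransform: '", path, "' has neither a JSON sidecar nor a ",
         "world file (", world_file_path(path), ")", call. = FALSE)
  }
  bands <- list()
  for (i in seq_len(nrow(band_map))) {
    b <- pages[[band_map$index[i]]]
    if (is_native) b <- decode_page(b, "real", meta$scaling)
    bands[[band_map$band[i]]] <- b
  }
  if (is_native) {
    mask_raw <- pages[[meta$mask_page]]
    valid <- matrix(as.vector(mask_raw) > 0, nrow(mask_raw), ncol(mask_raw))
  } else {
    valid <- Reduce(`&`, lapply(bands, is.finite))
    if (!is.null(nodata)) {
      valid <- valid & Reduce(`&`, lapply(bands, function(b) b != nodata))
    }
  }
  for (nm in names(bands)) bands[[nm]][!valid] <- 0
  multispec_image(bands, valid_mask = valid, geotransform = gt,
                  crs = crs %||% (if (!is.null(meta)) meta$crs %||% "" else ""),
                  band_map = band_map)
}

#' Read a multispectral image delivered as one file per band
#'
#' Multispectral cameras commonly write one monochrome frame per band. This
#' reader stacks such files after checking that every file has identical
#' dimensions and geotransform.
#'
#' @param paths named character vector of file paths, names `B, G, R, RE, NIR`.
#' @param band_map a [band_map()] (wavelength bookkeeping; each file's first
#'   page is used).
#' @param nodata optional shared nodata value.
#' @param crs optional CRS.
#' @return A [multispec_image()].
#' @export
read_multispectral_stack <- function(paths, band_map = paddyweed::band_map(),
                                     nodata = NULL, crs = NULL) {
  if (is.null(names(paths)) || !setequal(names(paths), band_names())) {
    stop("paths must be named with exactly B, G, R, RE, NIR", call. = FALSE)
  }
  bands <- list()
  gt0 <- NULL
  for (nm in band_names()) {
    p <- paths[[nm]]
    if (!file.exists(p)) stop("no such file: '", p, "'", call. = FALSE)
    meta <- read_aux(p)
    pages <- read_tiff_pages(p, as_is = FALSE)
    b <- pages[[1L]]
    if (!is.null(meta) && identical(meta$type, "real")) {
      b <- decode_page(b, "real", meta$scaling)
      mask_raw <- pages[[meta$mask_page]]
      b[!(as.vector(mask_raw) > 0)] <- NA_real_
    }
    gt <- if (!is.null(meta)) as.numeric(meta$geotransform) else read_world_file(p)
    if (is.null(gt)) stop("no geotransform for band file '", p, "'",
                          call. = FALSE)
    if (is.null(gt0)) {
      gt0 <- gt
      dim0 <- dim(b)
    } else {
      if (!identical(dim(b), dim0)) {
        stop("band file '", p, "' has mismatching dimensions", call. = FALSE)
      }
      if (!isTRUE(all.equal(gt, gt0, tolerance = 1e-9))) {
        stop("band file '", p, "' has a mismatching geotransform", call. = FALSE)
      }
    }
    bands[[nm]] <- b
  }
  valid <- Reduce(`&`, lapply(bands, is.finite))
  if (!is.null(nodata)) {
    valid <- valid & Reduce(`&`, lapply(bands, function(b) b != nodata))
  }
  for (nm in names(bands)) bands[[nm]][!valid] <- 0
  multispec_image(bands, valid_mask = valid, geotransform = gt0,
                  crs = crs %||% "", band_map = band_map)
}
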