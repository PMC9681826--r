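# Seeded synthetic paddy scenes: four spectral classes (transplanted rice
# rows over standing water, weed patches, floating algae mats), per-class
# band signatures, additive Gaussian sensor noise, and an exact ground-truth
# weed mask. The generator exists so every pipeline stage - and the
# end-to-end accuracy study - runs without field imagery.

#' Default per-class band reflectance signatures
#'
#' Invented working values, not field measurements: no reflectance spectra
#' are published for the survey this pipeline follows. They are constrained
#' to reproduce the qualitative spectral relationships that make the method
#' work: (i) weeds (barnyard grass / monochoria) carry a higher green to
#' red-edge ratio than rice, so `log10(G/RE)` separates weed from rice,
#' algae and water by several noise standard deviations; (ii) floating algae
#' ("water cotton") is green vegetation with NIR reflectance overlapping
#' weeds, so NDVI confuses the two; (iii) the flooded background is dark and
#' declines toward the NIR.
#'
#' @return 4 x 5 numeric matrix, rows `rice, weed, water_algae, soil`,
#'   columns `B, G, R, RE, NIR`, all values in (0, 1).
#' @export
default_signatures <- function() {
  sig <- rbind(
    rice        = c(B = 0.040, G = 0.080, R = 0.050, RE = 0.300, NIR = 0.500),
    weed        = c(B = 0.050, G = 0.120, R = 0.060, RE = 0.220, NIR = 0.480),
    water_algae = c(B = 0.040, G = 0.100, R = 0.050, RE = 0.280, NIR = 0.450),
    soil        = c(B = 0.080, G = 0.070, R = 0.050, RE = 0.040, NIR = 0.030)
  )
  colnames(sig) <- band_names()
  sig
}

#' Synthetic paddy scene specification
#'
#' @param shape `(M, N)` scene size in pixels.
#' @param pixel_size ground sampling distance in metres (0.05 m ~ a low
#'   multispectral survey altitude).
#' @param class_signatures 4 x 5 matrix as [default_signatures()].
#' @param noise_sd additive Gaussian noise standard deviation, one value for
#'   all bands or a length-5 per-band vector (reflectance units).
#' @param weed_patches list with `count`, `radius` (mean, pixels) and
#'   `radius_spread` (half-range of the uniform radius draw).
#' @param algae_patches list with `count` and `radius`; algae mats are larger
#'   and smoother than weed patches and are confined to the flooded inter-row
#'   water when `row_structure` is set.
#' @param row_structure rice row spacing in pixels (rows of rice alternate
#'   with standing water), or `NULL` for a closed rice canopy.
#' @param crs CRS identifier for the generated scene (a metric UTM zone by
#'   default so prescription gridding works).
#' @param seed integer random seed; the same spec and seed reproduce the
#'   scene exactly.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(shape = c(512L, 512L), pixel_size = 0.05,
                       class_signatures = default_signatures(),
                       noise_sd = 0.005,
                       weed_patches = list(count = 10L, radius = 8,
                                           radius_spread = 3),
                       algae_patches = list(count = 3L, radius = 20),
                       row_structure = 6L,
                       crs = "EPSG:32651", seed = 42L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 8L)) {
    stop("shape must be two integers >= 8", call. = FALSE)
  }
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  sig <- as.matrix(class_signatures)
  if (!identical(rownames(sig), c("rice", "weed", "water_algae", "soil")) ||
      ncol(sig) != 5L) {
    stop("class_signatures must be the 4 x 5 matrix layout of ",
         "default_signatures()", call. = FALSE)
  }
  if (any(sig <= 0) || any(sig >= 1)) {
    stop("signatures must lie strictly in (0, 1)", call. = FALSE)
  }
  noise_sd <- as.numeric(noise_sd)
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, 5L)
  if (length(noise_sd) != 5L || any(noise_sd < 0)) {
    stop("noise_sd must be one value or five nonnegative values", call. = FALSE)
  }
  names(noise_sd) <- band_names()
  if ((weed_patches$count %||% 0) < 0 || (algae_patches$count %||% 0) < 0) {
    stop("patch counts must be >= 0", call. = FALSE)
  }
  structure(list(shape = shape, pixel_size = pixel_size,
                 class_signatures = sig, noise_sd = noise_sd,
                 weed_patches = weed_patches, algae_patches = algae_patches,
                 row_structure = if (is.null(row_structure)) NULL
                                 else as.integer(row_structure),
                 crs = crs, seed = as.integer(seed)),
            class = "scene_spec")
}

# Stamp a filled random ellipse onto a logical matrix; returns the matrix.
# Centers are drawn so the ellipse bounding box stays inside the extent.
#' @noRd
stamp_ellipse <- function(canvas, a, b, angle, M, N) {
  rmax <- ceiling(max(a, b))
  if (2 * rmax + 1 > min(M, N)) {
    stop("patch radius ", rmax, " is too large for a ", M, " x ", N, " scene",
         call. = FALSE)
  }
  cr <- stats::runif(1, 1 + rmax, M - rmax)
  cc <- stats::runif(1, 1 + rmax, N - rmax)
  rows <- max(1L, floor(cr - rmax)):min(M, ceiling(cr + rmax))
  cols <- max(1L, floor(cc - rmax)):min(N, ceiling(cc + rmax))
  rg <- matrix(rows - cr, length(rows), length(cols))
  cg <- matrix(cols - cc, length(rows), length(cols), byrow = TRUE)
  u <- cos(angle) * cg + sin(angle) * rg
  w <- -sin(angle) * cg + cos(angle) * rg
  inside <- (u / a)^2 + (w / b)^2 <= 1
  canvas[rows, cols] <- canvas[rows, cols] | inside
  canvas
}

#' Generate a synthetic paddy scene
#'
#' Builds the class map (rice rows over water, then algae mats, then weed
#' patches on top), assigns each pixel its class signature plus independent
#' Gaussian band noise truncated at zero, and returns the image together with
#' the exact ground truth.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (a [multispec_image()]), `truth` (a
#'   [weed_mask()], `TRUE` exactly where the class map says weed) and
#'   `class_map` (integer matrix, 1 = rice, 2 = weed, 3 = water_algae,
#'   4 = soil/water).
#' @examples
#' sc <- generate_scene(scene_spec(shape = c(64, 64), seed = 1))
#' table(sc$class_map)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  M <- spec$shape[1]; N <- spec$shape[2]
  CLASS_RICE <- 1L; CLASS_WEED <- 2L; CLASS_ALGAE <- 3L; CLASS_SOIL <- 4L
  # background: rice rows over flooded soil/water, or closed canopy
  if (!is.null(spec$row_structure)) {
    sp <- spec$row_structure
    rice_rows <- (seq_len(M) - 1L) %% sp < ceiling(sp / 2)
    class_map <- matrix(ifelse(rice_rows, CLASS_RICE, CLASS_SOIL), M, N)
  } else {
    class_map <- matrix(CLASS_RICE, M, N)
  }
  # algae mats: larger smooth blobs, kept off the rice rows when rows exist
  ap <- spec$algae_patches
  if ((ap$count %||% 0) > 0) {
    algae <- matrix(FALSE, M, N)
    for (i in seq_len(ap$count)) {
      a <- stats::runif(1, 0.7, 1.3) * ap$radius
      b <- stats::runif(1, 0.7, 1.3) * ap$radius
      algae <- stamp_ellipse(algae, a, b, stats::runif(1, 0, pi), M, N)
    }
    if (!is.null(spec$row_structure)) algae <- algae & class_map == CLASS_SOIL
    class_map[algae] <- CLASS_ALGAE
  }
  # weed patches: smaller blobs, anywhere (weeds emerge through the canopy)
  wp <- spec$weed_patches
  weed <- matrix(FALSE, M, N)
  if ((wp$count %||% 0) > 0) {
    spread <- wp$radius_spread %||% 0
    for (i in seq_len(wp$count)) {
      a <- stats::runif(1, wp$radius - spread, wp$radius + spread)
      b <- stats::runif(1, wp$radius - spread, wp$radius + spread)
      weed <- stamp_ellipse(weed, max(a, 1), max(b, 1), stats::runif(1, 0, pi),
                            M, N)
    }
    class_map[weed] <- CLASS_WEED
  }
  sig <- spec$class_signatures
  bands <- list()
  for (j in seq_along(band_names())) {
    nm <- band_names()[j]
    mean_b <- matrix(sig[class_map, j], M, N)
    noisy <- mean_b + stats::rnorm(M * N, sd = spec$noise_sd[j])
    bands[[nm]] <- pmax(noisy, 0)
  }
  gt <- geotransform(x0 = 500000, y0 = 4534000, px_x = spec$pixel_size)
  image <- multispec_image(bands, valid_mask = matrix(TRUE, M, N),
                           geotransform = gt, crs = spec$crs)
  truth <- weed_mask(class_map == CLASS_WEED,
                     valid_mask = matrix(TRUE, M, N),
                     geotransform = gt, crs = spec$crs,
                     provenance = list(list(step = "synthetic_truth",
                                            seed = spec$seed)))
  list(image = image, truth = truth, class_map = class_map)
}

#' Convert a reflectance scene to raw digital numbers
#'
#' Inverse of [calibrate_reflectance()] for testing and simulation:
#' `DN = round(reflectance * panel_dn[band] * gain / panel_reflectance)`.
#' `gain` models a sensor gain applied equally to scene and panel, so a
#' calibration whose `panel_dn` is scaled by the same gain recovers the
#' reflectances to within half a DN step.
#'
#' @param image a [multispec_image()] in reflectance units.
#' @param cal a [panel_calibration()].
#' @param gain positive sensor gain multiplier (default 1).
#' @return A [multispec_image()] holding integer-valued DN grids.
#' @export
scene_to_dn <- function(image, cal, gain = 1) {
  stopifnot(inherits(image, "multispec_image"),
            inherits(cal, "panel_calibration"))
  if (gain <= 0) stop("gain must be positive", call. = FALSE)
  bands <- image$bands
  for (nm in band_names()) {
    bands[[nm]] <- round_half_up(
      bands[[nm]] * cal$panel_dn[[nm]] * gain / cal$panel_reflectance)
  }
  multispec_image(bands, valid_mask = image$valid_mask,
                  geotransform = image$geotransform, crs = image$crs,
                  band_map = image$band_map)
}
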