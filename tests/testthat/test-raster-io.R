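test_that("band_map defaults match the five-band sensor layout", {
  bm <- band_map()
  expect_identical(bm$band, c("B", "G", "R", "RE", "NIR"))
  expect_identical(bm$center_nm, c(450, 560, 650, 730, 840))
  expect_identical(bm$half_width_nm, c(16, 16, 16, 16, 26))
})

test_that("band_map rejects wavelength-order violations and bad names", {
  expect_error(band_map(center = c(B = 560, G = 450, R = 650, RE = 730,
                                   NIR = 840)),
               "increase strictly")
  # every permutation that breaks the ordering is rejected
  base <- c(450, 560, 650, 730, 840)
  nm <- c("B", "G", "R", "RE", "NIR")
  for (i in 1:10) {
    perm <- sample(5)
    centers <- stats::setNames(base[perm], nm)
    if (all(diff(base[perm]) > 0)) {
      expect_s3_class(band_map(center = centers), "band_map")
    } else {
      expect_error(band_map(center = centers), "increase strictly")
    }
  }
  expect_error(band_map(index = c(B = 1, G = 2, R = 3, RE = 4, XX = 5)),
               "exactly B, G, R, RE, NIR")
  expect_error(band_map(index = c(B = 1, G = 1, R = 3, RE = 4, NIR = 5)),
               "distinct")
})

test_that("integer and boolean rasters round-trip exactly", {
  td <- withr::local_tempdir()
  georef <- list(geotransform = geotransform(10, 20, 0.5), crs = "EPSG:32651")

  gi <- matrix(sample.int(256L, 16, replace = TRUE) - 1L, 4, 4)
  p <- file.path(td, "int.tif")
  write_raster(gi, georef, p)
  r <- read_raster(p)
  expect_identical(r$values, gi)
  expect_identical(r$type, "integer")
  expect_equal(r$geotransform, georef$geotransform)

  bl <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2)
  pb <- file.path(td, "bool.tif")
  write_raster(bl, georef, pb)
  rb <- read_raster(pb)
  expect_identical(rb$values, bl)
  # on-disk samples are literally 0/1
  raw <- suppressWarnings(tiff::readTIFF(pb, all = TRUE, as.is = TRUE))
  expect_setequal(unique(as.vector(raw[[1]])), c(0L, 1L))
})

test_that("real rasters preserve values and nodata through a round trip", {
  td <- withr::local_tempdir()
  georef <- list(geotransform = geotransform(0, 0, 0.1), crs = "EPSG:32651")
  v <- matrix(stats::rnorm(64, sd = 3), 8, 8)
  v[2, 3] <- NA # nodata pixel
  p <- file.path(td, "real.tif")
  write_raster(v, georef, p)
  r <- read_raster(p)
  expect_false(r$valid_mask[2, 3])
  expect_true(is.na(r$values[2, 3]))
  rng <- diff(range(v, na.rm = TRUE))
  expect_lt(max(abs(r$values - v), na.rm = TRUE), 1e-7 * rng)
  # a second trip through the float32 representation stays stable
  write_raster(r$values, georef, p)
  r2 <- read_raster(p)
  expect_equal(r2$values, r$values, tolerance = 1e-6)
})

test_that("multispectral write/read preserves bands, mask and georeferencing", {
  td <- withr::local_tempdir()
  img <- random_image(6, 7)
  img$valid_mask[1, 1] <- FALSE
  for (nm in names(img$bands)) img$bands[[nm]][1, 1] <- 0
  p <- file.path(td, "scene.tif")
  write_multispectral(img, p)
  back <- read_multispectral(p)
  expect_false(back$valid_mask[1, 1])
  for (nm in names(img$bands)) {
    expect_lt(max(abs(back$bands[[nm]][back$valid_mask] -
                      img$bands[[nm]][img$valid_mask])), 1e-6)
  }
  expect_equal(back$geotransform, img$geotransform)
  expect_identical(back$crs, img$crs)
  # identity band order: G is stored as page 2
  pages <- suppressWarnings(tiff::readTIFF(p, all = TRUE))
  meta <- jsonlite::read_json(paste0(p, ".aux.json"), simplifyVector = TRUE)
  g_decoded <- meta$scaling[1] + pages[[2]] * diff(meta$scaling)
  expect_lt(max(abs(g_decoded[img$valid_mask] -
                    img$bands$G[img$valid_mask])), 1e-6)
})

test_that("foreign TIFFs need a world file and enough bands", {
  td <- withr::local_tempdir()
  img <- random_image(5, 5)
  p <- file.path(td, "scene.tif")
  write_multispectral(img, p)

  # drop the JSON sidecar: the world file alone must georeference the file
  file.remove(paste0(p, ".aux.json"))
  back <- read_multispectral(p)
  expect_equal(back$geotransform, img$geotransform)

  # remove the world file too -> explicit geotransform error
  file.remove(paste0(tools::file_path_sans_ext(p), ".tfw"))
  expect_error(read_multispectral(p), "geotransform")

  # too few band pages for the requested mapping
  p2 <- file.path(td, "thin.tif")
  suppressWarnings(tiff::writeTIFF(list(matrix(0.5, 4, 4)), p2,
                                   bits.per.sample = 32))
  writeLines(format(c(1, 0, 0, -1, 0.5, -0.5)), file.path(td, "thin.tfw"))
  expect_error(read_multispectral(p2), "band")

  expect_error(read_multispectral(file.path(td, "absent.tif")), "no such file")
})

test_that("foreign nodata values invalidate pixels in all bands", {
  td <- withr::local_tempdir()
  pages <- lapply(1:5, function(i) matrix(0.4, 4, 4))
  pages[[3]][2, 2] <- 0 # nodata in one band only
  p <- file.path(td, "fgn.tif")
  suppressWarnings(tiff::writeTIFF(pages, p, bits.per.sample = 32))
  writeLines(format(c(1, 0, 0, -1, 0.5, -0.5)), file.path(td, "fgn.tfw"))
  img <- read_multispectral(p, nodata = 0)
  expect_false(img$valid_mask[2, 2])
  expect_equal(sum(!img$valid_mask), 1L)
})

test_that("per-band file stacking checks shape and geotransform", {
  td <- withr::local_tempdir()
  img <- random_image(6, 6)
  paths <- character(0)
  for (nm in names(img$bands)) {
    p <- file.path(td, paste0(nm, ".tif"))
    write_raster(img$bands[[nm]],
                 list(geotransform = img$geotransform, crs = img$crs), p)
    paths[nm] <- p
  }
  back <- read_multispectral_stack(paths)
  expect_lt(max(abs(back$bands$RE - img$bands$RE)), 1e-6)

  # a band with a different geotransform is rejected
  write_raster(img$bands$NIR, list(geotransform = geotransform(99, 0, 0.05),
                                   crs = img$crs), paths["NIR"])
  expect_error(read_multispectral_stack(paths), "geotransform")
})

test_that("GeoJSON writing preserves feature count and geometry", {
  td <- withr::local_tempdir()
  p <- file.path(td, "v.geojson")

  write_vector(list(), p)
  fc <- jsonlite::read_json(p)
  expect_identical(fc$type, "FeatureCollection")
  expect_length(fc$features, 0)

  sq <- list(rings = list(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))),
             properties = list(id = 1))
  write_vector(list(sq), p)
  polys <- read_vector(p)
  expect_length(polys, 1)
  expect_equal(abs(shoelace <- {
    r <- polys[[1]]$rings[[1]]
    r <- r[-nrow(r), , drop = FALSE]
    x <- r[, 1]; y <- r[, 2]; n <- length(x); j <- c(n, seq_len(n - 1))
    sum(x[j] * y - x * y[j]) / 2
  }), 1)

  squares <- lapply(0:2, function(k) {
    list(rings = list(cbind(x = c(0, 1, 1, 0) + 3 * k, y = c(0, 0, 1, 1))),
         properties = list(id = k))
  })
  write_vector(squares, p)
  expect_length(read_vector(p), 3)

  bow <- list(rings = list(cbind(x = c(0, 1, 1, 0), y = c(0, 1, 0, 1))))
  expect_error(write_vector(list(sq, bow), p), "polygon 2")
  expect_error(write_vector(list(sq), p, format = "Shapefile"),
               "not supported")
})
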