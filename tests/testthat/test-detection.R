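mk_index <- function(values, valid = NULL) {
  index_raster(values, valid_mask = valid, geotransform = geotransform(),
               crs = "EPSG:32651")
}

test_that("quantization maps endpoints, midpoints and clips as documented", {
  v <- matrix(c(0, 0.5, 1, 0.25), 2, 2)
  g <- quantize_to_gray(mk_index(v), L = 256, range = c(0, 1))
  expect_identical(g$values[1, 1], 0L)       # v = min -> 0
  expect_identical(g$values[1, 2], 255L)     # v = max -> L-1
  expect_identical(g$values[2, 1], 128L)     # round-half-up of 127.5
  expect_identical(g$values[2, 2], 64L)      # 0.25 * 255 = 63.75 -> 64
  expect_equal(g$scaling, c(0, 1))

  out <- quantize_to_gray(mk_index(matrix(c(-2, 5), 1, 2)), L = 16,
                          range = c(0, 1))
  expect_identical(out$values, matrix(c(0L, 15L), 1, 2))

  expect_error(quantize_to_gray(mk_index(matrix(1, 3, 3)), L = 8),
               "constant raster")
  expect_error(quantize_to_gray(mk_index(v), L = 1), "L must be >= 2")
  # auto range uses valid pixels only
  vv <- matrix(c(0, 10, 100, 20), 2, 2)
  valid <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  g2 <- quantize_to_gray(mk_index(vv, valid), L = 11)
  expect_equal(g2$scaling, c(0, 20))
  expect_identical(g2$values[2, 1], 5L)
})

test_that("density slicing selects the gray interval and partitions validly", {
  g <- gray_raster(matrix(c(0L, 6L, 3L, 255L), 2, 2), levels = 256,
                   geotransform = geotransform())
  m <- density_slice(g, slice_threshold(0, 5))
  expect_identical(m$values, matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))

  # full interval -> everything weed
  all_in <- density_slice(g, slice_threshold(0, 255))
  expect_true(all(all_in$values))

  # weed count equals a brute-force membership scan; inside/outside partition
  set.seed(31)
  vals <- matrix(sample(0L:63L, 900, replace = TRUE), 30, 30)
  valid <- matrix(stats::runif(900) > 0.1, 30, 30)
  gr <- gray_raster(vals, levels = 64, valid_mask = valid,
                    geotransform = geotransform())
  th <- slice_threshold(10, 25)
  inside <- density_slice(gr, th, weed_inside = TRUE)
  outside <- density_slice(gr, th, weed_inside = FALSE)
  brute <- 0L
  for (i in 1:30) for (j in 1:30) {
    if (valid[i, j] && vals[i, j] >= 10 && vals[i, j] <= 25) brute <- brute + 1L
  }
  expect_identical(sum(inside$values), brute)
  expect_identical(inside$values & outside$values, matrix(FALSE, 30, 30))
  expect_identical(inside$values | outside$values, valid)

  expect_error(density_slice(gr, slice_threshold(0, 64)), "exceeds")
  expect_error(slice_threshold(-1, 5), "0 <= low")
})

test_that("majority filter removes isolated pixels and honors unanimity", {
  lone <- matrix(FALSE, 9, 9); lone[5, 5] <- TRUE
  out <- majority_filter(mk_mask(lone), 3)
  expect_false(any(out$values))

  solid <- mk_mask(matrix(TRUE, 7, 7))
  for (k in c(3, 5, 7)) {
    expect_true(all(majority_filter(solid, k)$values))
  }
  expect_error(majority_filter(solid, 4), "odd")
  expect_error(majority_filter(solid, 1), "odd integer >= 3")
})

test_that("majority filter equals the brute-force windowed vote", {
  set.seed(37)
  for (k in c(3, 5, 7)) {
    v <- matrix(stats::runif(32 * 32) < 0.45, 32, 32)
    valid <- matrix(stats::runif(32 * 32) > 0.05, 32, 32)
    m <- mk_mask(v & valid, valid)
    got <- majority_filter(m, k)
    want <- oracle_majority(m$values, valid, k)
    expect_identical(got$values, want)
  }
})

test_that("majority filter never creates weed where the window has none", {
  set.seed(41)
  v <- matrix(stats::runif(40 * 40) < 0.1, 40, 40)
  m <- mk_mask(v)
  out <- majority_filter(m, 5)
  # any output weed pixel must have at least one input weed pixel in reach
  dil <- oracle_clump(v, 5, 1)
  expect_true(all(!out$values | dil))
})

test_that("clump bridges small gaps and preserves isolated pixels", {
  empty <- mk_mask(matrix(FALSE, 6, 6))
  expect_false(any(clump(empty, 3, 3)$values))

  gap <- matrix(FALSE, 5, 7)
  gap[3, 3] <- TRUE; gap[3, 5] <- TRUE
  closed <- clump(mk_mask(gap), 3, 3)
  expect_true(closed$values[3, 4])   # 1-pixel gap bridged
  expect_true(all(closed$values[3, 3:5]))

  lone <- matrix(FALSE, 7, 7); lone[4, 4] <- TRUE
  out <- clump(mk_mask(lone), 3, 3)
  expect_identical(out$values, lone)
  expect_error(clump(mk_mask(lone), 0, 3), ">= 1")
})

test_that("clump equals brute-force set morphology, including even kernels", {
  set.seed(43)
  for (kk in list(c(2, 2), c(3, 3), c(4, 4), c(3, 2), c(2, 4))) {
    v <- matrix(stats::runif(24 * 24) < 0.3, 24, 24)
    got <- clump(mk_mask(v), kk[1], kk[2])
    want <- oracle_clump(v, kk[1], kk[2])
    expect_identical(got$values, want)
  }
})

test_that("closing (equal kernels) is idempotent", {
  set.seed(47)
  for (k in c(2, 3, 4)) {
    v <- matrix(stats::runif(30 * 30) < 0.35, 30, 30)
    once <- clump(mk_mask(v), k, k)
    twice <- clump(once, k, k)
    expect_identical(twice$values, once$values)
  }
})

test_that("nodata pixels never vote and never become weed", {
  v <- matrix(TRUE, 5, 5)
  valid <- matrix(TRUE, 5, 5); valid[3, 3] <- FALSE
  v[3, 3] <- FALSE
  m <- mk_mask(v, valid)
  mf <- majority_filter(m, 3)
  expect_false(mf$values[3, 3])
  cl <- clump(m, 3, 3)
  expect_false(cl$values[3, 3])
  expect_true(all(!cl$values | cl$valid_mask))
})

test_that("detect composes the stages and records full provenance", {
  set.seed(53)
  img <- random_image(32, 32)
  idx <- compute_index(img, "WDVI_NIR")

  cfg_off <- detection_config(levels = 256, slice = c(0, 120),
                              majority = NULL, clump_kernels = NULL)
  direct <- density_slice(quantize_to_gray(idx, 256), slice_threshold(0, 120))
  expect_identical(detect(idx, cfg_off)$values, direct$values)

  # survey defaults run end-to-end without error
  full <- detect(idx, detection_config())
  steps <- vapply(full$provenance, function(p) p$step, "")
  expect_identical(steps, c("quantize_to_gray", "density_slice",
                            "majority_filter", "clump"))
  expect_equal(full$provenance[[3]]$kernel, 27L)
  expect_equal(full$provenance[[4]]$dilate_kernel, 3L)
})

test_that("slice selection covers labelled weed levels", {
  set.seed(59)
  vals <- matrix(sample(0L:255L, 400, replace = TRUE), 20, 20)
  weed <- matrix(FALSE, 20, 20)
  weed[1:5, 1:8] <- TRUE
  vals[weed] <- sample(40L:60L, sum(weed), replace = TRUE)
  g <- gray_raster(vals, 256, geotransform = geotransform())
  ref <- mk_mask(weed)
  th <- select_slice_threshold(g, ref, coverage = 1)
  expect_identical(th$low, min(vals[weed]))
  expect_identical(th$high, max(vals[weed]))
  th99 <- select_slice_threshold(g, ref, coverage = 0.99)
  expect_gte(th99$low, th$low)
  expect_lte(th99$high, th$high)
  expect_error(select_slice_threshold(g, ref, coverage = 0), "coverage")
})

test_that("optimal_slice matches exhaustive interval search", {
  set.seed(61)
  L <- 16L
  vals <- matrix(sample(0L:(L - 1L), 300, replace = TRUE), 15, 20)
  weed <- matrix(stats::runif(300) < 0.3, 15, 20)
  g <- gray_raster(vals, L, geotransform = geotransform())
  ref <- mk_mask(weed)
  got <- optimal_slice(g, ref)
  best_oa <- 0
  n <- 300
  for (lo in 0:(L - 1L)) for (hi in lo:(L - 1L)) {
    pred <- vals >= lo & vals <= hi
    oa <- sum(pred == weed) / n
    if (oa > best_oa) best_oa <- oa
  }
  # also the empty prediction
  best_oa <- max(best_oa, sum(!weed) / n)
  expect_equal(got$oa, best_oa)
})
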