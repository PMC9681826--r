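test_that("perfect, chance-level and tabulated agreements score correctly", {
  m <- matrix(stats::runif(100) < 0.4, 10, 10)
  r <- evaluate_mask(mk_mask(m), mk_mask(m))
  expect_equal(r$overall_accuracy, 1)
  expect_equal(r$kappa, 1)
  expect_equal(r$n_evaluated, 100)

  # tabulated case: tp 90, fn 10, fp 5, tn 95
  # p_e = (95*100 + 105*100) / 200^2 = 0.5, kappa = 0.425 / 0.5 = 0.85
  # (cross-checked against caret::confusionMatrix)
  cm <- mk_count_masks(90, 5, 10, 95)
  rep <- evaluate_mask(cm$pred, cm$ref)
  expect_equal(rep$overall_accuracy, 185 / 200)
  expect_equal(rep$expected_agreement, (95 * 100 + 105 * 100) / 200^2)
  expect_equal(rep$kappa, 0.85, tolerance = 1e-12)

  # constant predictor against a half-weed reference: OA 0.5, kappa 0
  ref <- matrix(c(rep(TRUE, 50), rep(FALSE, 50)), 10, 10)
  pred <- matrix(FALSE, 10, 10)
  rc <- evaluate_mask(mk_mask(pred), mk_mask(ref))
  expect_equal(rc$overall_accuracy, 0.5)
  expect_equal(rc$kappa, 0)
})

test_that("evaluate matches the hand formula on random contingency tables", {
  set.seed(67)
  for (i in 1:300) {
    counts <- sample(0:40, 4, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    cm <- mk_count_masks(counts[1], counts[2], counts[3], counts[4])
    rep <- evaluate_mask(cm$pred, cm$ref)
    expect_identical(c(rep$tp, rep$fp, rep$fn, rep$tn), as.numeric(counts))
    expect_equal(rep$kappa,
                 oracle_kappa(counts[1], counts[2], counts[3], counts[4]),
                 tolerance = 1e-12)
  }
  # degenerate single-class tables
  for (counts in list(c(10, 0, 0, 0), c(0, 0, 0, 10), c(0, 10, 0, 0),
                      c(0, 0, 10, 0))) {
    cm <- mk_count_masks(counts[1], counts[2], counts[3], counts[4])
    rep <- evaluate_mask(cm$pred, cm$ref)
    expect_equal(rep$kappa,
                 oracle_kappa(counts[1], counts[2], counts[3], counts[4]))
  }
})

test_that("evaluation is symmetric under a simultaneous label flip", {
  set.seed(71)
  p <- matrix(stats::runif(400) < 0.3, 20, 20)
  r <- matrix(stats::runif(400) < 0.4, 20, 20)
  a <- evaluate_mask(mk_mask(p), mk_mask(r))
  b <- evaluate_mask(mk_mask(!p), mk_mask(!r))
  expect_equal(a$overall_accuracy, b$overall_accuracy)
  expect_equal(a$kappa, b$kappa)
  expect_identical(c(a$tp, a$fp, a$fn, a$tn), c(b$tn, b$fn, b$fp, b$tp))
})

test_that("kappa is centred at zero under independent predictions", {
  set.seed(73)
  n <- 10000
  ref_v <- stats::runif(n) < 0.35
  ref <- mk_mask(matrix(ref_v, 100, 100))
  kappas <- numeric(1000)
  pred_v <- ref_v
  for (i in seq_len(1000)) {
    pred_v <- sample(pred_v) # shuffling destroys spatial association
    kappas[i] <- evaluate_mask(mk_mask(matrix(pred_v, 100, 100)), ref)$kappa
  }
  expect_lt(mean(abs(kappas)), 0.02)
})

test_that("evaluation excludes pixels invalid in either mask", {
  p <- matrix(TRUE, 4, 4)
  pv <- matrix(TRUE, 4, 4); pv[1, ] <- FALSE
  r <- matrix(TRUE, 4, 4)
  rv <- matrix(TRUE, 4, 4); rv[, 1] <- FALSE
  rep <- evaluate_mask(mk_mask(p & pv, pv), mk_mask(r & rv, rv))
  expect_equal(rep$n_evaluated, 9)
  expect_error(evaluate_mask(mk_mask(p), mk_mask(matrix(TRUE, 5, 5))),
               "dimensions")
  m1 <- mk_mask(p)
  m2 <- weed_mask(r, geotransform = geotransform(5, 5, 2), crs = "EPSG:32651")
  expect_error(evaluate_mask(m1, m2), "geotransform")
})

test_that("kernel sweeps trace the accuracy curve and pick the argmax", {
  set.seed(79)
  sc <- generate_scene(scene_spec(shape = c(96, 96), seed = 5))
  idx <- compute_index(sc$image, "WDVI_NIR")
  g <- quantize_to_gray(idx, 256)
  th <- select_slice_threshold(g, sc$truth)
  cfg <- detection_config(slice = c(th$low, th$high), majority = NULL,
                          clump_kernels = NULL)

  # the survey's 16-kernel list produces 16 rows
  kernels <- seq(3, 33, 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  sw <- sweep_majority_kernel(idx, sc$truth, cfg, kernels, csv = csv)
  df <- as.data.frame(sw)
  expect_equal(nrow(df), 16)
  expect_true(sw$best %in% kernels)
  expect_true(all(df$oa[df$value == sw$best] >= df$oa))
  on_disk <- utils::read.csv(csv)
  expect_identical(names(on_disk),
                   c("kernel", "tp", "fp", "fn", "tn", "oa", "kappa"))
  expect_equal(nrow(on_disk), 16)

  # singleton sweep returns its element; ties break to the smaller kernel
  s1 <- sweep_majority_kernel(idx, sc$truth, cfg, kernels = 5)
  expect_equal(s1$best, 5)
  expect_error(sweep_majority_kernel(idx, sc$truth, cfg, kernels = c(3, 4)),
               "odd")
  expect_error(sweep_majority_kernel(idx, sc$truth, cfg, kernels = integer(0)),
               "non-empty")

  swc <- sweep_clump_kernel(idx, sc$truth, cfg, kernels = 3:9)
  dfc <- as.data.frame(swc)
  expect_equal(nrow(dfc), 7)
  expect_true(all(dfc$oa[dfc$value == swc$best] >= dfc$oa))
  s2 <- sweep_clump_kernel(idx, sc$truth, cfg, kernels = 4)
  expect_equal(s2$best, 4)
})

test_that("majority filtering at the swept kernel removes salt noise", {
  # a scene plus salt noise: the best kernel must beat no/minimal filtering
  set.seed(83)
  sc <- generate_scene(scene_spec(shape = c(96, 96), seed = 9))
  idx <- compute_index(sc$image, "WDVI_NIR")
  g <- quantize_to_gray(idx, 256)
  th <- select_slice_threshold(g, sc$truth)
  base <- density_slice(g, th)
  salt <- base$values
  flip <- matrix(stats::runif(length(salt)) < 0.02, nrow(salt))
  noisy <- weed_mask(xor(salt, flip) & base$valid_mask,
                     valid_mask = base$valid_mask,
                     geotransform = base$geotransform, crs = base$crs)
  oa_raw <- evaluate_mask(noisy, sc$truth)$overall_accuracy
  best_oa <- -Inf
  for (k in c(3, 5, 7, 9)) {
    oa_k <- evaluate_mask(majority_filter(noisy, k),
                          sc$truth)$overall_accuracy
    best_oa <- max(best_oa, oa_k)
  }
  expect_gte(best_oa, oa_raw)
})

test_that("reference masks load with class counts, rejecting bad values", {
  td <- withr::local_tempdir()
  georef <- list(geotransform = geotransform(px_x = 0.05), crs = "EPSG:32651")

  # the survey's labelling volume: 48,255 weed + 93,228 non-weed pixels
  v <- matrix(FALSE, 3, 47161)
  v[seq_len(48255)] <- TRUE
  p <- file.path(td, "ref.tif")
  write_raster(v, georef, p)
  expect_message(ref <- load_reference_mask(p), "48255 weed, 93228 non-weed")
  expect_equal(sum(ref$valid_mask), 141483)
  expect_equal(sum(ref$values), 48255)

  # all-weed raster: weed count equals valid count
  p2 <- file.path(td, "allweed.tif")
  write_raster(matrix(TRUE, 4, 4), georef, p2)
  ref2 <- suppressMessages(load_reference_mask(p2))
  expect_equal(sum(ref2$values), sum(ref2$valid_mask))

  # integer 0/1 rasters are accepted; other values rejected
  p3 <- file.path(td, "int01.tif")
  write_raster(matrix(c(0L, 1L, 1L, 0L), 2, 2), georef, p3)
  ref3 <- suppressMessages(load_reference_mask(p3))
  expect_equal(sum(ref3$values), 2)
  p4 <- file.path(td, "bad.tif")
  write_raster(matrix(c(0L, 2L, 1L, 0L), 2, 2), georef, p4)
  expect_error(load_reference_mask(p4), "0/1")
})
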