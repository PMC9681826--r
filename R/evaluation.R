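# Map-accuracy assessment: 2x2 confusion counts, overall accuracy, Cohen's
# kappa, and the kernel-selection sweeps used to pick post-processing
# parameters.

#' @noRd
new_eval_report <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  n <- tp + fp + fn + tn
  if (n == 0L) stop("no co-valid pixels to evaluate", call. = FALSE)
  oa <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe >= 1) {
    # degenerate: both rater marginals concentrated in one class
    if (oa == 1) 1 else 0
  } else {
    (oa - pe) / (1 - pe)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 n_evaluated = n, overall_accuracy = oa,
                 expected_agreement = pe, kappa = kappa),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> weed = positive class\n")
  cat(sprintf("  confusion: TP %d  FP %d  FN %d  TN %d  (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n_evaluated))
  cat(sprintf("  overall accuracy: %.4f\n", x$overall_accuracy))
  cat(sprintf("  kappa           : %.4f\n", x$kappa))
  invisible(x)
}

#' Evaluate a predicted weed mask against a reference mask
#'
#' Pixel-wise comparison restricted to pixels valid in both masks; weed is the
#' positive class. Overall accuracy is `(TP + TN) / n` and kappa is
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` computed from
#' the confusion-matrix marginals. In the degenerate case `p_e = 1` (both
#' masks single-class), kappa is 1 for perfect agreement and 0 otherwise.
#'
#' @param pred,ref [weed_mask()] objects of identical shape and
#'   georeferencing.
#' @return An `eval_report` with counts, `overall_accuracy`, `kappa` and
#'   `n_evaluated`.
#' @examples
#' m <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
#' evaluate_mask(weed_mask(m), weed_mask(m))$kappa # 1
#' @export
evaluate_mask <- function(pred, ref) {
  stopifnot(inherits(pred, "weed_mask"), inherits(ref, "weed_mask"))
  check_same_georef(pred, ref, "prediction and reference")
  both <- pred$valid_mask & ref$valid_mask
  p <- pred$values[both]
  r <- ref$values[both]
  new_eval_report(tp = sum(p & r), fp = sum(p & !r),
                  fn = sum(!p & r), tn = sum(!p & !r))
}

#' @noRd
sweep_result <- function(parameter, rows) {
  oa <- vapply(rows, function(r) r$report$overall_accuracy, numeric(1))
  vals <- vapply(rows, function(r) r$value, numeric(1))
  best <- vals[which.max(oa)] # which.max takes the first (smallest) maximizer
  structure(list(parameter = parameter, rows = rows, best = best),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> parameter '%s', best = %g\n", x$parameter,
              x$best))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  do.call(rbind, lapply(x$rows, function(r) {
    data.frame(value = r$value, tp = r$report$tp, fp = r$report$fp,
               fn = r$report$fn, tn = r$report$tn,
               oa = r$report$overall_accuracy, kappa = r$report$kappa)
  }))
}

#' @noRd
run_sweep <- function(parameter, values, make_config, index, ref, csv) {
  rows <- lapply(values, function(v) {
    mask <- detect(index, make_config(v))
    list(value = as.numeric(v), report = evaluate_mask(mask, ref))
  })
  res <- sweep_result(parameter, rows)
  if (!is.null(csv)) {
    df <- as.data.frame(res)
    names(df)[1] <- "kernel"
    utils::write.csv(df, csv, row.names = FALSE)
  }
  res
}

#' Sweep the majority-filter kernel size
#'
#' Runs the detection chain once per kernel (all other stages fixed by
#' `config`), evaluates each result against the reference, and reports the
#' accuracy curve with the accuracy-maximizing kernel (ties break toward the
#' smaller kernel — the least smoothing that attains the maximum).
#'
#' @param index an [index_raster()].
#' @param ref reference [weed_mask()].
#' @param config a [detection_config()]; its `majority` entry is overridden.
#' @param kernels odd kernel sizes to try, e.g. `seq(3, 33, 2)`.
#' @param csv optional path for a CSV of `(kernel, tp, fp, fn, tn, oa, kappa)`.
#' @return A `sweep_result`.
#' @export
sweep_majority_kernel <- function(index, ref, config = detection_config(),
                                  kernels = seq(3L, 33L, 2L), csv = NULL) {
  kernels <- as.integer(kernels)
  if (!length(kernels)) stop("kernels must be non-empty", call. = FALSE)
  if (any(kernels %% 2L == 0L)) {
    stop("majority kernels must all be odd", call. = FALSE)
  }
  run_sweep("majority_kernel", kernels, function(k) {
    cfg <- config; cfg$majority <- k; cfg
  }, index, ref, csv)
}

#' Sweep the clump kernel size
#'
#' As [sweep_majority_kernel()], varying the clump stage with dilation and
#' erosion kernels set equal (a closing of that size).
#'
#' @param index an [index_raster()].
#' @param ref reference [weed_mask()].
#' @param config a [detection_config()]; its `clump_kernels` entry is
#'   overridden.
#' @param kernels kernel sizes to try, e.g. `3:9`.
#' @param csv optional CSV path.
#' @return A `sweep_result`.
#' @export
sweep_clump_kernel <- function(index, ref, config = detection_config(),
                               kernels = 3:9, csv = NULL) {
  kernels <- as.integer(kernels)
  if (!length(kernels)) stop("kernels must be non-empty", call. = FALSE)
  run_sweep("clump_kernel", kernels, function(k) {
    cfg <- config; cfg$clump_kernels <- c(k, k); cfg
  }, index, ref, csv)
}

#' Load a reference weed mask from a raster file
#'
#' Accepts a `{0, 1}` raster (written by [write_raster()] or a foreign TIFF
#' with a world file). Values other than 0/1/nodata are rejected. Class
#' counts are reported as a message.
#'
#' @param path file path.
#' @return A [weed_mask()].
#' @export
load_reference_mask <- function(path) {
  r <- read_raster(path)
  v <- r$values
  if (is.logical(v)) {
    m <- v
  } else {
    vv <- v[r$valid_mask]
    if (length(setdiff(unique(vv), c(0, 1)))) {
      stop("reference raster values must be 0/1 (plus nodata)", call. = FALSE)
    }
    m <- matrix(FALSE, nrow(v), ncol(v))
    m[r$valid_mask] <- v[r$valid_mask] == 1
  }
  m[!r$valid_mask] <- FALSE
  msk <- weed_mask(m, valid_mask = r$valid_mask, geotransform = r$geotransform,
                   crs = r$crs)
  message(sprintf("reference mask: %d weed, %d non-weed (n = %d)",
                  sum(msk$values), sum(msk$valid_mask) - sum(msk$values),
                  sum(msk$valid_mask)))
  msk
}
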