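# Detection chain: real-valued index -> gray levels -> density slice ->
# majority-filter small-patch removal -> clump (dilate-erode) smoothing.

#' Quantize an index raster to integer gray levels
#'
#' Linear min-max scaling with round-half-up:
#' `g = round((v - min) / (max - min) * (L - 1))`, clipped to `[0, L-1]`.
#' When `range` is omitted it is taken from the valid pixels; the scaling is
#' recorded on the result so slice thresholds are transferable between images.
#'
#' @param index an [index_raster()].
#' @param L number of gray levels (>= 2); 256 gives the familiar 8-bit scale.
#' @param range optional numeric `(min, max)` defining the stretch; values
#'   outside are clipped to 0 or `L-1`.
#' @return A [gray_raster()].
#' @export
quantize_to_gray <- function(index, L = 256L, range = NULL) {
  stopifnot(inherits(index, "index_raster"))
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("L must be >= 2", call. = FALSE)
  v <- index$values[index$valid_mask]
  if (is.null(range)) {
    if (!length(v)) stop("no valid pixels to derive a range from", call. = FALSE)
    range <- c(min(v), max(v))
    if (range[1] == range[2]) {
      stop("constant raster: supply an explicit range", call. = FALSE)
    }
  }
  range <- as.numeric(range)
  if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2]) {
    stop("range must be two finite values with min < max", call. = FALSE)
  }
  g <- matrix(0L, nrow(index$values), ncol(index$values))
  scaled <- (index$values - range[1]) / (range[2] - range[1]) * (L - 1)
  gv <- round_half_up(scaled)
  gv <- pmin(pmax(gv, 0), L - 1)
  g[index$valid_mask] <- as.integer(gv[index$valid_mask])
  gray_raster(g, levels = L, valid_mask = index$valid_mask,
              geotransform = index$geotransform, crs = index$crs,
              scaling = range)
}

#' Gray-level interval used by density slicing
#'
#' @param low,high integer gray levels with `0 <= low <= high <= L-1`.
#' @return A `slice_threshold` object.
#' @export
slice_threshold <- function(low, high) {
  low <- as.integer(low); high <- as.integer(high)
  if (is.na(low) || is.na(high) || low < 0L || high < low) {
    stop("need 0 <= low <= high", call. = FALSE)
  }
  structure(list(low = low, high = high), class = "slice_threshold")
}

#' Classify a gray raster by density slicing
#'
#' Two-class gray-level partition: a pixel is weed iff its gray level lies in
#' `[low, high]` (or the complement when `weed_inside = FALSE`). This is a
#' two-sided generalization of the classical single-threshold partition that
#' maps levels up to a threshold t to one class and the rest to the other.
#'
#' @param gray a [gray_raster()].
#' @param th a [slice_threshold()] (or numeric `c(low, high)`).
#' @param weed_inside if `TRUE` (default) the selected slice is the weed
#'   class; the complement within valid pixels otherwise.
#' @return A [weed_mask()] with provenance.
#' @export
density_slice <- function(gray, th, weed_inside = TRUE) {
  stopifnot(inherits(gray, "gray_raster"))
  if (!inherits(th, "slice_threshold")) th <- slice_threshold(th[1], th[2])
  if (th$high > gray$levels - 1L) {
    stop("threshold exceeds L-1 = ", gray$levels - 1L, call. = FALSE)
  }
  inside <- gray$values >= th$low & gray$values <= th$high
  weed <- if (weed_inside) inside else !inside
  weed <- weed & gray$valid_mask
  m <- weed_mask(weed, valid_mask = gray$valid_mask,
                 geotransform = gray$geotransform, crs = gray$crs)
  append_provenance(m, "density_slice", low = th$low, high = th$high,
                    weed_inside = weed_inside, levels = gray$levels,
                    scaling = gray$scaling)
}

#' Remove small patches with a majority filter
#'
#' Each pixel takes the majority class among the valid pixels of its
#' `k x k` window; windows are cropped at image borders and nodata pixels
#' never vote. With odd `k` and a full window the vote cannot tie; where
#' cropping leaves an even number of voters, a tied pixel keeps its input
#' class (conservative and deterministic). Invalid pixels are never converted
#' to weed.
#'
#' @param mask a [weed_mask()].
#' @param kernel odd window size `k >= 3`.
#' @return A filtered [weed_mask()] with provenance.
#' @export
majority_filter <- function(mask, kernel) {
  stopifnot(inherits(mask, "weed_mask"))
  k <- as.integer(kernel)
  if (is.na(k) || k < 3L || k %% 2L == 0L) {
    stop("kernel must be an odd integer >= 3", call. = FALSE)
  }
  h <- (k - 1L) %/% 2L
  w <- mask$values
  valid_num <- matrix(as.numeric(mask$valid_mask), nrow(w), ncol(w))
  weed_num <- matrix(as.numeric(w & mask$valid_mask), nrow(w), ncol(w))
  voters <- window_sums(valid_num, h)
  weed_votes <- window_sums(weed_num, h)
  out <- w
  out[2 * weed_votes > voters] <- TRUE
  out[2 * weed_votes < voters] <- FALSE
  # ties (possible only with an even cropped voter count) keep the input value
  out <- out & mask$valid_mask
  m <- weed_mask(out, valid_mask = mask$valid_mask,
                 geotransform = mask$geotransform, crs = mask$crs,
                 provenance = mask$provenance)
  append_provenance(m, "majority_filter", kernel = k)
}

# Structuring-element offsets for a solid k x k square of ones with the
# top-left-of-center anchor: offsets -a .. k-1-a where a = floor((k-1)/2).
#' @noRd
se_offsets <- function(k) {
  a <- (k - 1L) %/% 2L
  seq.int(-a, k - 1L - a)
}

# Binary dilation / erosion on the unbounded plane (image embedded in FALSE
# background): the grid is padded before shifting so structure created just
# outside the frame participates in a following erosion, matching the set
# definition of morphology.
#' @noRd
morph_binary <- function(values, dilate_k = NULL, erode_k = NULL) {
  pad <- max(c(dilate_k, erode_k, 1L))
  M <- nrow(values); N <- ncol(values)
  big <- matrix(FALSE, M + 2L * pad, N + 2L * pad)
  big[pad + seq_len(M), pad + seq_len(N)] <- values
  if (!is.null(dilate_k)) {
    offs <- se_offsets(dilate_k)
    acc <- matrix(FALSE, nrow(big), ncol(big))
    for (dr in offs) for (dc in offs) {
      acc <- acc | shift_matrix(big, dr, dc, fill = FALSE)
    }
    big <- acc
  }
  if (!is.null(erode_k)) {
    offs <- se_offsets(erode_k)
    acc <- matrix(TRUE, nrow(big), ncol(big))
    for (dr in offs) for (dc in offs) {
      acc <- acc & shift_matrix(big, -dr, -dc, fill = FALSE)
    }
    big <- acc
  }
  big[pad + seq_len(M), pad + seq_len(N)]
}

#' Clump smoothing (morphological dilate-erode)
#'
#' Dilation by a `dilate_kernel x dilate_kernel` solid square of ones followed
#' by erosion by an `erode_kernel x erode_kernel` square — a morphological
#' closing when the kernels are equal, which merges nearby weed patches and
#' fills small gaps. Even-sized squares use the top-left-of-center anchor.
#' Morphology is computed on the padded plane (set definition), then invalid
#' pixels are cleared: nodata never becomes weed.
#'
#' @param mask a [weed_mask()].
#' @param dilate_kernel,erode_kernel integer kernel sizes `>= 1`.
#' @return A smoothed [weed_mask()] with provenance.
#' @export
clump <- function(mask, dilate_kernel = 3L, erode_kernel = dilate_kernel) {
  stopifnot(inherits(mask, "weed_mask"))
  dk <- as.integer(dilate_kernel); ek <- as.integer(erode_kernel)
  if (is.na(dk) || dk < 1L || is.na(ek) || ek < 1L) {
    stop("kernels must be integers >= 1", call. = FALSE)
  }
  out <- morph_binary(mask$values, dilate_k = dk, erode_k = ek)
  out <- out & mask$valid_mask
  m <- weed_mask(out, valid_mask = mask$valid_mask,
                 geotransform = mask$geotransform, crs = mask$crs,
                 provenance = mask$provenance)
  append_provenance(m, "clump", dilate_kernel = dk, erode_kernel = ek)
}

#' Detection parameters
#'
#' Bundles the parameters of the full detection chain. Any stage can be
#' skipped by setting its parameter to `NULL`. The defaults are the
#' field-survey values: 256 gray levels, slice `[0, 5]`, majority kernel 27,
#' clump kernels 3/3 (note the slice levels refer to the min-max stretch of
#' the index recorded in the gray raster, so their meaning travels with the
#' quantization).
#'
#' @param levels gray levels L for quantization.
#' @param range optional fixed quantization range `(min, max)`.
#' @param slice numeric `c(low, high)` gray-level interval, or `NULL` to skip
#'   slicing (then the chain must start from a mask).
#' @param weed_inside whether the slice interval is the weed class.
#' @param majority odd majority-filter kernel, or `NULL` to skip.
#' @param clump_kernels integer `c(dilate, erode)`, or `NULL` to skip.
#' @return A `detection_config` object.
#' @export
detection_config <- function(levels = 256L, range = NULL, slice = c(0L, 5L),
                             weed_inside = TRUE, majority = 27L,
                             clump_kernels = c(3L, 3L)) {
  structure(list(levels = levels, range = range, slice = slice,
                 weed_inside = weed_inside, majority = majority,
                 clump_kernels = clump_kernels),
            class = "detection_config")
}

#' Run the full detection chain on an index raster
#'
#' Quantize, density-slice, majority-filter and clump in that order, per the
#' supplied [detection_config()]. Full provenance is recorded on the result.
#'
#' @param index an [index_raster()].
#' @param config a [detection_config()].
#' @return A [weed_mask()].
#' @examples
#' sc <- generate_scene(scene_spec(shape = c(64, 64)))
#' idx <- compute_index(sc$image, "WDVI_NIR")
#' mask <- detect(idx, detection_config(slice = c(200, 255), majority = 3,
#'                                      clump_kernels = c(3, 3)))
#' @export
detect <- function(index, config = detection_config()) {
  stopifnot(inherits(index, "index_raster"))
  if (!inherits(config, "detection_config")) {
    stop("config must be a detection_config", call. = FALSE)
  }
  if (is.null(config$slice)) {
    stop("detect needs a slice threshold in config", call. = FALSE)
  }
  gray <- quantize_to_gray(index, L = config$levels, range = config$range)
  mask <- density_slice(gray, slice_threshold(config$slice[1], config$slice[2]),
                        weed_inside = isTRUE(config$weed_inside))
  mask$provenance <- c(list(list(step = "quantize_to_gray", levels = gray$levels,
                                 scaling = gray$scaling)), mask$provenance)
  if (!is.null(config$majority)) {
    mask <- majority_filter(mask, config$majority)
  }
  if (!is.null(config$clump_kernels)) {
    mask <- clump(mask, config$clump_kernels[1], config$clump_kernels[2])
  }
  mask
}

#' Choose a slice interval covering labelled weed pixels
#'
#' Automates the manual slice-selection rule used in field surveys — widen the
#' gray-level interval until the sliced layer covers the weeds — given a
#' reference labelling: the interval is the central `coverage` quantile range
#' of the gray levels observed on reference weed pixels (with `coverage = 1`,
#' their exact min-max). A small tail is excluded by default so single noisy
#' pixels do not drag the interval across neighbouring classes.
#'
#' @param gray a [gray_raster()].
#' @param reference a [weed_mask()] with reference weed labels.
#' @param coverage fraction of reference weed pixels the interval must cover
#'   (default 0.99).
#' @return A [slice_threshold()].
#' @export
select_slice_threshold <- function(gray, reference, coverage = 0.99) {
  stopifnot(inherits(gray, "gray_raster"), inherits(reference, "weed_mask"))
  check_same_georef(gray, reference, "gray raster and reference")
  if (coverage <= 0 || coverage > 1) {
    stop("coverage must be in (0, 1]", call. = FALSE)
  }
  g <- gray$values[reference$values & gray$valid_mask]
  if (!length(g)) stop("reference contains no valid weed pixels", call. = FALSE)
  tail <- (1 - coverage) / 2
  qs <- stats::quantile(g, probs = c(tail, 1 - tail), names = FALSE, type = 1)
  slice_threshold(qs[1], qs[2])
}

#' Accuracy-optimal slice interval for a gray raster
#'
#' Finds the gray-level interval `[low, high]` maximizing overall accuracy
#' against a reference mask, by maximum-subarray search over the per-level
#' difference between weed and non-weed pixel counts (O(L) after one
#' histogram pass). Used to compare the discriminative power of competing
#' indices on equal footing.
#'
#' @param gray a [gray_raster()].
#' @param reference a [weed_mask()] with reference labels.
#' @return list with `threshold` (a [slice_threshold()]), `oa` (the overall
#'   accuracy attained) and `n` (pixels evaluated).
#' @export
optimal_slice <- function(gray, reference) {
  stopifnot(inherits(gray, "gray_raster"), inherits(reference, "weed_mask"))
  check_same_georef(gray, reference, "gray raster and reference")
  both <- gray$valid_mask & reference$valid_mask
  g <- gray$values[both]
  w <- reference$values[both]
  L <- gray$levels
  weed_counts <- tabulate(g[w] + 1L, nbins = L)
  non_counts <- tabulate(g[!w] + 1L, nbins = L)
  gain <- weed_counts - non_counts
  # maximum-subarray (Kadane) with earliest-interval tie-break
  best_sum <- -Inf; best <- c(1L, 1L)
  cur <- 0; cur_start <- 1L
  for (i in seq_len(L)) {
    if (cur <= 0) { cur <- gain[i]; cur_start <- i } else cur <- cur + gain[i]
    if (cur > best_sum) { best_sum <- cur; best <- c(cur_start, i) }
  }
  n <- length(g)
  total_non <- sum(non_counts)
  if (best_sum < 0) { # predicting no weed anywhere beats every interval
    oa <- total_non / n
    th <- slice_threshold(0L, 0L)
    attr(th, "empty") <- TRUE
  } else {
    correct <- sum(weed_counts[best[1]:best[2]]) +
      (total_non - sum(non_counts[best[1]:best[2]]))
    oa <- correct / n
    th <- slice_threshold(best[1] - 1L, best[2] - 1L)
  }
  list(threshold = th, oa = oa, n = n)
}
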