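# Brute-force reference implementations, deliberately written as plain double
# loops over pixels so they share no code with the vectorized package paths.

# Majority vote over the k x k window cropped to in-image valid pixels;
# ties keep the input value; invalid pixels are never weed.
oracle_majority <- function(values, valid, k) {
  M <- nrow(values); N <- ncol(values)
  h <- (k - 1L) %/% 2L
  out <- matrix(FALSE, M, N)
  for (r in seq_len(M)) {
    for (c in seq_len(N)) {
      if (!valid[r, c]) next
      rs <- max(1, r - h):min(M, r + h)
      cs <- max(1, c - h):min(N, c + h)
      v <- valid[rs, cs]
      voters <- sum(v)
      weed_votes <- sum(values[rs, cs] & v)
      out[r, c] <- if (2 * weed_votes > voters) TRUE
                   else if (2 * weed_votes < voters) FALSE
                   else values[r, c]
    }
  }
  out
}

# Set-definition morphology on the plane (image embedded in FALSE background):
# dilation = union of the structuring element translated to every foreground
# pixel; erosion = pixels whose whole (anchored) neighborhood is foreground.
# Solid k x k square, top-left-of-center anchor.
oracle_se_offsets <- function(k) {
  a <- (k - 1L) %/% 2L
  seq.int(-a, k - 1L - a)
}

oracle_dilate <- function(values, k, pad) {
  M <- nrow(values); N <- ncol(values)
  big <- matrix(FALSE, M + 2L * pad, N + 2L * pad)
  offs <- oracle_se_offsets(k)
  for (r in seq_len(M)) for (c in seq_len(N)) {
    if (!values[r, c]) next
    for (dr in offs) for (dc in offs) {
      big[pad + r + dr, pad + c + dc] <- TRUE
    }
  }
  big
}

oracle_erode_cropped <- function(big, k, pad, M, N) {
  offs <- oracle_se_offsets(k)
  out <- matrix(FALSE, M, N)
  for (r in seq_len(M)) for (c in seq_len(N)) {
    all_true <- TRUE
    for (dr in offs) {
      for (dc in offs) {
        if (!big[pad + r + dr, pad + c + dc]) { all_true <- FALSE; break }
      }
      if (!all_true) break
    }
    out[r, c] <- all_true
  }
  out
}

oracle_clump <- function(values, dilate_k, erode_k) {
  pad <- max(dilate_k, erode_k)
  big <- oracle_dilate(values, dilate_k, pad)
  oracle_erode_cropped(big, erode_k, pad, nrow(values), ncol(values))
}

# Signed shoelace area of a ring given as an n x 2 matrix (closing vertex
# optional).
shoelace_ring <- function(ring) {
  if (all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x); j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Hand kappa from 2x2 counts.
oracle_kappa <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (pe >= 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# Build a weed_mask from a logical matrix with a simple metric georef.
mk_mask <- function(values, valid = NULL, px = 1, crs = "EPSG:32651") {
  weed_mask(values, valid_mask = valid,
            geotransform = geotransform(px_x = px), crs = crs)
}

# Build an eval pair realizing given 2x2 counts (1-row masks).
mk_count_masks <- function(tp, fp, fn, tn) {
  p <- c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, fn), rep(FALSE, tn))
  r <- c(rep(TRUE, tp), rep(FALSE, fp), rep(TRUE, fn), rep(FALSE, tn))
  list(pred = mk_mask(matrix(p, 1)), ref = mk_mask(matrix(r, 1)))
}

# Random positive five-band image (reflectance-like values in (lo, hi)).
random_image <- function(M, N, lo = 0.02, hi = 0.9) {
  bands <- stats::setNames(lapply(1:5, function(i) {
    matrix(stats::runif(M * N, lo, hi), M, N)
  }), c("B", "G", "R", "RE", "NIR"))
  multispec_image(bands, geotransform = geotransform(px_x = 0.05),
                  crs = "EPSG:32651")
}
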