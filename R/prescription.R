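# From the final weed mask to sprayer-facing products: weed polygons and a
# coarse metric spray/no-spray grid.

#' Label 4-connected components of a weed mask
#'
#' @param mask a [weed_mask()] (or logical matrix).
#' @return integer matrix; 0 for background, 1..n_components for weed pixels.
#' @export
label_components <- function(mask) {
  v <- if (inherits(mask, "weed_mask")) mask$values else mask
  M <- nrow(v); N <- ncol(v)
  lab <- matrix(0L, M, N)
  cur <- 0L
  queue <- integer(M * N)
  for (start in which(v)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% M) + 1L
      c <- ((p - 1L) %/% M) + 1L
      if (r > 1L) { q <- p - 1L
        if (v[q] && lab[q] == 0L) { lab[q] <- cur; tail <- tail + 1L; queue[tail] <- q } }
      if (r < M) { q <- p + 1L
        if (v[q] && lab[q] == 0L) { lab[q] <- cur; tail <- tail + 1L; queue[tail] <- q } }
      if (c > 1L) { q <- p - M
        if (v[q] && lab[q] == 0L) { lab[q] <- cur; tail <- tail + 1L; queue[tail] <- q } }
      if (c < N) { q <- p + M
        if (v[q] && lab[q] == 0L) { lab[q] <- cur; tail <- tail + 1L; queue[tail] <- q } }
    }
  }
  lab
}

# Trace the boundary rings of one labelled component. Directed boundary edges
# run along the pixel-corner lattice with the component interior kept on the
# walker's right; at ambiguous (bowtie) corners the sharpest right turn is
# taken, which keeps every emitted ring simple.
#' @noRd
trace_component_rings <- function(v, M, N) {
  # edges keyed by start corner id; corner id = row * (N + 1) + col (0-based)
  starts <- integer(0); ends <- integer(0)
  pix <- which(v)
  rr <- ((pix - 1L) %% M) + 1L
  cc <- ((pix - 1L) %/% M) + 1L
  has <- function(r, c) r >= 1L & r <= M & c >= 1L & c <= N &
    v[cbind(pmax(pmin(r, M), 1L), pmax(pmin(c, N), 1L))]
  cid <- function(r, c) r * (N + 1L) + c
  add <- function(s, e) { starts <<- c(starts, s); ends <<- c(ends, e) }
  up <- !has(rr - 1L, cc); right <- !has(rr, cc + 1L)
  down <- !has(rr + 1L, cc); left <- !has(rr, cc - 1L)
  # top edge rightward / right edge downward / bottom leftward / left upward
  if (any(up))    add(cid(rr[up] - 1L, cc[up] - 1L),    cid(rr[up] - 1L, cc[up]))
  if (any(right)) add(cid(rr[right] - 1L, cc[right]),   cid(rr[right], cc[right]))
  if (any(down))  add(cid(rr[down], cc[down]),          cid(rr[down], cc[down] - 1L))
  if (any(left))  add(cid(rr[left], cc[left] - 1L),     cid(rr[left] - 1L, cc[left] - 1L))
  n_edge <- length(starts)
  used <- logical(n_edge)
  by_start <- split(seq_len(n_edge), starts)
  rings <- list()
  dir_of <- function(i) { # (drow, dcol) of edge i on the corner lattice
    s <- starts[i]; e <- ends[i]
    c((e %/% (N + 1L)) - (s %/% (N + 1L)), (e %% (N + 1L)) - (s %% (N + 1L)))
  }
  for (e0 in seq_len(n_edge)) {
    if (used[e0]) next
    ring <- integer(0)
    i <- e0
    repeat {
      used[i] <- TRUE
      ring <- c(ring, starts[i])
      nxt_vertex <- ends[i]
      if (nxt_vertex == starts[e0]) break
      cand <- by_start[[as.character(nxt_vertex)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break # should not happen: edge degrees balance
      if (length(cand) == 1L) {
        i <- cand
      } else {
        d <- dir_of(i)
        pref <- list(c(d[2], -d[1]), d, c(-d[2], d[1])) # right, straight, left
        pick <- cand[1L]
        for (p in pref) {
          hit <- cand[vapply(cand, function(j) identical(dir_of(j), p), logical(1))]
          if (length(hit)) { pick <- hit[1L]; break }
        }
        i <- pick
      }
    }
    rings[[length(rings) + 1L]] <- ring
  }
  lapply(rings, function(r) cbind(row = r %/% (N + 1L), col = r %% (N + 1L)))
}

#' Vectorize a weed mask into polygons
#'
#' One polygon per 4-connected weed component, with holes, in map
#' coordinates. Each polygon carries `area` (pixel count times pixel area),
#' `n_pixels` and `component` attributes.
#'
#' @param mask a [weed_mask()].
#' @return list of polygons in the [write_vector()] representation (possibly
#'   empty).
#' @export
vectorize_mask <- function(mask) {
  stopifnot(inherits(mask, "weed_mask"))
  lab <- label_components(mask)
  n_comp <- max(lab)
  if (n_comp == 0L) return(list())
  gt <- mask$geotransform
  px_area <- prod(pixel_size(gt))
  M <- nrow(lab); N <- ncol(lab)
  out <- vector("list", n_comp)
  for (k in seq_len(n_comp)) {
    v <- lab == k
    rings_px <- trace_component_rings(v, M, N)
    rings_xy <- lapply(rings_px, function(rc) {
      xy <- corner_xy(gt, rc[, "row"], rc[, "col"])
      cbind(x = xy$x, y = xy$y)
    })
    areas <- vapply(rings_xy, shoelace_area, numeric(1))
    ord <- order(abs(areas), decreasing = TRUE) # exterior ring first
    rings_xy <- rings_xy[ord]
    n_pix <- sum(v)
    out[[k]] <- list(
      rings = rings_xy,
      properties = list(component = k, n_pixels = n_pix,
                        area = n_pix * px_area)
    )
  }
  out
}

#' Coarse spray/no-spray prescription grid
#'
#' Aggregates a weed mask onto a metric grid of `cell_size` x `cell_size`
#' cells aligned to the mask's top-left corner. Each cell's `weed_fraction`
#' is weed pixels / valid pixels within the cell (`NA` where a cell contains
#' no valid pixel). The spray rule is: with `theta = 0`, spray wherever any
#' weed pixel falls in the cell (`weed_fraction > 0`); with `theta > 0`,
#' spray where `weed_fraction >= theta`, so `theta = 1` sprays only cells
#' fully covered by weed. Lowering `theta` never un-sprays a cell.
#'
#' @param mask a [weed_mask()] in a projected (metric) CRS.
#' @param cell_size cell edge length in map units (default 1 m, the working
#'   grid of plant-protection UAV sprayers).
#' @param theta weed-fraction threshold in `[0, 1]`.
#' @return A `prescription_grid` with matrices `weed_fraction` and `spray`,
#'   plus `cell_size`, `theta` and georeferencing.
#' @export
resample_to_grid <- function(mask, cell_size = 1, theta = 0) {
  stopifnot(inherits(mask, "weed_mask"))
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop("cell_size must be positive", call. = FALSE)
  }
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]", call. = FALSE)
  proj <- crs_is_projected(mask$crs)
  if (isFALSE(proj)) {
    stop("mask CRS '", mask$crs, "' is geographic (degree units); reproject ",
         "to a metric CRS before building a prescription grid", call. = FALSE)
  }
  gt <- mask$geotransform
  if (gt[3] != 0 || gt[5] != 0) {
    stop("rotated geotransforms are not supported for gridding", call. = FALSE)
  }
  px <- pixel_size(gt)
  M <- nrow(mask$values); N <- ncol(mask$values)
  n_rows <- ceiling(M * px["y"] / cell_size)
  n_cols <- ceiling(N * px["x"] / cell_size)
  # cell of each pixel, by pixel-center offset from the mask's top-left corner
  row_cell <- pmin(1L + floor((seq_len(M) - 0.5) * px["y"] / cell_size), n_rows)
  col_cell <- pmin(1L + floor((seq_len(N) - 0.5) * px["x"] / cell_size), n_cols)
  cell_id <- matrix(row_cell, M, N) + (matrix(col_cell, M, N, byrow = TRUE) - 1L) * n_rows
  n_cells <- n_rows * n_cols
  valid_per <- tabulate(cell_id[mask$valid_mask], nbins = n_cells)
  weed_per <- tabulate(cell_id[mask$values], nbins = n_cells)
  frac <- ifelse(valid_per > 0, weed_per / pmax(valid_per, 1L), NA_real_)
  frac_m <- matrix(frac, n_rows, n_cols)
  spray_m <- if (theta == 0) frac_m > 0 else frac_m >= theta
  spray_m[is.na(frac_m)] <- NA
  grid_gt <- c(gt[1], cell_size, 0, gt[4], 0, -cell_size)
  structure(list(weed_fraction = frac_m, spray = spray_m,
                 valid_pixels = matrix(valid_per, n_rows, n_cols),
                 cell_size = cell_size, theta = theta,
                 geotransform = grid_gt, crs = mask$crs),
            class = "prescription_grid")
}

#' @export
print.prescription_grid <- function(x, ...) {
  d <- dim(x$spray)
  n_data <- sum(!is.na(x$spray))
  cat(sprintf("<prescription_grid> %d x %d cells of %g map units (theta = %g)\n",
              d[1], d[2], x$cell_size, x$theta))
  cat(sprintf("  spray cells: %d / %d\n", sum(x$spray, na.rm = TRUE), n_data))
  invisible(x)
}

#' Write a prescription grid to file
#'
#' @param grid a `prescription_grid` from [resample_to_grid()].
#' @param path output path.
#' @param format `"GeoTIFF"` writes the 0/1 spray flags at cell resolution
#'   (with nodata for empty cells); `"GeoJSON"` writes one square feature per
#'   data cell with `weed_fraction` and `spray` attributes.
#' @return `path`, invisibly.
#' @export
write_prescription <- function(grid, path, format = c("GeoTIFF", "GeoJSON")) {
  stopifnot(inherits(grid, "prescription_grid"))
  format <- match.arg(format)
  if (format == "GeoTIFF") {
    flags <- grid$spray
    storage.mode(flags) <- "logical"
    write_raster(flags, georef = list(geotransform = grid$geotransform,
                                      crs = grid$crs), path = path)
  } else {
    gt <- grid$geotransform
    polys <- list()
    for (j in seq_len(ncol(grid$spray))) {
      for (i in seq_len(nrow(grid$spray))) {
        if (is.na(grid$spray[i, j])) next
        tl <- corner_xy(gt, i - 1L, j - 1L)
        br <- corner_xy(gt, i, j)
        ring <- cbind(x = c(tl$x, br$x, br$x, tl$x),
                      y = c(tl$y, tl$y, br$y, br$y))
        polys[[length(polys) + 1L]] <- list(
          rings = list(ring),
          properties = list(row = i, col = j,
                            weed_fraction = grid$weed_fraction[i, j],
                            spray = unname(grid$spray[i, j]))
        )
      }
    }
    write_vector(polys, path, format = "GeoJSON", crs = grid$crs)
  }
  invisible(path)
}
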