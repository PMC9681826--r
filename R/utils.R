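# Internal numeric and raster helpers shared across modules.

#' @keywords internal
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# Summed-area table with a zero guard row/column so rectangle sums are
# sat[r2+1, c2+1] - sat[r1, c2+1] - sat[r2+1, c1] + sat[r1, c1].
#' @noRd
summed_area <- function(m) {
  M <- nrow(m)
  N <- ncol(m)
  down <- apply(m, 2L, cumsum)            # cumulative down rows
  if (M == 1L) down <- matrix(down, 1L, N)
  acc <- if (N == 1L) down else t(apply(down, 1L, cumsum)) # then across cols
  s <- matrix(0, M + 1L, N + 1L)
  s[-1L, -1L] <- acc
  s
}

# Vectorized rectangle sums over every pixel for a window of half-width h
# (cropped at image borders). Returns an M x N matrix of sums.
#' @noRd
window_sums <- function(m, h) {
  M <- nrow(m)
  N <- ncol(m)
  s <- summed_area(m)
  r1 <- pmax(seq_len(M) - h, 1L)
  r2 <- pmin(seq_len(M) + h, M)
  c1 <- pmax(seq_len(N) - h, 1L)
  c2 <- pmin(seq_len(N) + h, N)
  # index into the (M+1) x (N+1) guard-padded table
  R1 <- matrix(r1, M, N)
  R2 <- matrix(r2 + 1L, M, N)
  C1 <- matrix(c1, M, N, byrow = TRUE)
  C2 <- matrix(c2 + 1L, M, N, byrow = TRUE)
  idx <- function(R, C) s[cbind(as.vector(R), as.vector(C))]
  matrix(idx(R2, C2) - idx(R1, C2) - idx(R2, C1) + idx(R1, C1), M, N)
}

# Shift a logical matrix by (dr, dc), filling vacated cells with `fill`.
#' @noRd
shift_matrix <- function(m, dr, dc, fill = FALSE) {
  M <- nrow(m)
  N <- ncol(m)
  out <- matrix(fill, M, N)
  rs <- seq_len(M)
  cs <- seq_len(N)
  src_r <- rs - dr
  src_c <- cs - dc
  keep_r <- src_r >= 1L & src_r <= M
  keep_c <- src_c >= 1L & src_c <= N
  if (any(keep_r) && any(keep_c)) {
    out[rs[keep_r], cs[keep_c]] <- m[src_r[keep_r], src_c[keep_c]]
  }
  out
}

#' @noRd
assert_matrix2d <- function(x, what = "grid") {
  if (!is.matrix(x) || nrow(x) < 1L || ncol(x) < 1L) {
    stop(what, " must be a non-empty 2-D matrix", call. = FALSE)
  }
  invisible(x)
}

#' @noRd
same_dim <- function(a, b) identical(dim(a), dim(b))

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
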