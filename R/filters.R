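# Separable filtering primitives shared by the illumination estimator and the
# pixel-classification feature bank. All filters use reflective padding so a
# constant image is exactly reproduced and finite differences of a constant
# are exactly zero.

gauss_kernel <- function(sigma, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# reflect indices 1..n for out-of-range positions (mirror without repeating
# the edge sample twice would need n >= 2; simple edge-inclusive mirroring
# is used: ... 3 2 1 | 1 2 3 ... n | n n-1 ...)
reflect_idx <- function(i, n) {
  i <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n) + 1L
  ifelse(i > n, 2L * n + 1L - i, i)
}

# filter along the row index (i.e., vertically) with a centred 1-D kernel
filter_rows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- reflect_idx(seq.int(1L - r, n + r), n)
  pad <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * pad[(j - 1L) + seq_len(n), , drop = FALSE]
  out
}

filter_sep <- function(m, k_row, k_col) {
  t(filter_rows(t(filter_rows(m, k_row)), k_col))
}

gauss_smooth <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  filter_sep(m, k, k)
}

# first and second central differences (unit spacing)
D1 <- c(-0.5, 0, 0.5)
D2 <- c(1, -2, 1)
DELTA <- 1

deriv_row <- function(m) filter_rows(m, rev(D1))  # d/d(row)
deriv_col <- function(m) t(filter_rows(t(m), rev(D1)))
deriv_row2 <- function(m) filter_rows(m, rev(D2))
deriv_col2 <- function(m) t(filter_rows(t(m), rev(D2)))

# eigenvalues of the symmetric 2x2 field [[a, c], [c, b]], vectorized;
# returns list(hi, lo) with hi >= lo elementwise
sym_eigen2 <- function(a, b, c) {
  tr2 <- (a + b) / 2
  disc <- sqrt(pmax(((a - b) / 2)^2 + c^2, 0))
  list(hi = tr2 + disc, lo = tr2 - disc)
}

# 3x3 box-structuring-element binary erosion; pixels outside the matrix are
# treated as background
erode_bin <- function(b) {
  n <- nrow(b); m <- ncol(b)
  p <- matrix(FALSE, n + 2L, m + 2L)
  p[2:(n + 1L), 2:(m + 1L)] <- b
  out <- b
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out & p[2:(n + 1L) + dr, 2:(m + 1L) + dc, drop = FALSE]
  }
  out
}

dilate_bin <- function(b) {
  n <- nrow(b); m <- ncol(b)
  p <- matrix(FALSE, n + 2L, m + 2L)
  p[2:(n + 1L), 2:(m + 1L)] <- b
  out <- b
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out | p[2:(n + 1L) + dr, 2:(m + 1L) + dc, drop = FALSE]
  }
  out
}

dilate_bin_n <- function(b, n_px) {
  for (i in seq_len(n_px)) b <- dilate_bin(b)
  b
}
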