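# Internal numerical kernels: separable Gaussian smoothing, finite-difference
# gradients, and pyramid resampling.  All operate on plain 3-D arrays.

# Dense 1-D Gaussian smoothing operator of size n, kernel truncated at 4*sigma,
# rows renormalised so boundaries do not darken.
gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  G <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  G[abs(outer(idx, idx, "-")) > ceiling(4 * sigma)] <- 0
  G / rowSums(G)
}

# Separable Gaussian smoothing of a 3-D array (per-axis sigmas in voxels).
gaussian_smooth <- function(arr, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim(arr)
  if (sigma[1] > 0) {
    G <- gauss_matrix(d[1], sigma[1])
    arr <- array(G %*% matrix(arr, d[1], d[2] * d[3]), dim = d)
  }
  if (sigma[2] > 0) {
    G <- gauss_matrix(d[2], sigma[2])
    tmp <- aperm(arr, c(2, 1, 3))
    tmp <- array(G %*% matrix(tmp, d[2], d[1] * d[3]), dim = c(d[2], d[1], d[3]))
    arr <- aperm(tmp, c(2, 1, 3))
  }
  if (sigma[3] > 0) {
    G <- gauss_matrix(d[3], sigma[3])
    tmp <- aperm(arr, c(3, 2, 1))
    tmp <- array(G %*% matrix(tmp, d[3], d[2] * d[1]), dim = c(d[3], d[2], d[1]))
    arr <- aperm(tmp, c(3, 2, 1))
  }
  arr
}

# Central differences in the interior, one-sided at the boundary faces.
# Returns the derivative of `arr` along `axis`, in per-voxel units.
diff_axis <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  if (n < 2L)
    validation_error("cannot differentiate along an axis of length %d", n)
  idx_hi <- pmin(seq_len(n) + 1L, n)
  idx_lo <- pmax(seq_len(n) - 1L, 1L)
  denom <- idx_hi - idx_lo            # 2 interior, 1 at the two faces
  slice <- function(i) {
    switch(axis,
           arr[i, , , drop = FALSE],
           arr[, i, , drop = FALSE],
           arr[, , i, drop = FALSE])
  }
  out <- (slice(idx_hi) - slice(idx_lo))
  # divide by the per-position step along `axis`
  if (axis == 1L) out <- out / denom
  if (axis == 2L) out <- sweep(out, 2L, denom, "/")
  if (axis == 3L) out <- sweep(out, 3L, denom, "/")
  array(out, dim = d)
}

# Downsample a 3-D array by 2 with a light anti-alias blur; output size
# ceiling(n/2), sampling the blurred array at coarse centres 2k.
downsample2 <- function(arr) {
  d <- dim(arr)
  sm <- gaussian_smooth(arr, 0.85)
  ix <- seq(1L, d[1], by = 2L)
  iy <- seq(1L, d[2], by = 2L)
  iz <- seq(1L, d[3], by = 2L)
  sm[ix, iy, iz, drop = FALSE]
}

# Upsample a displacement-field component array from a coarse grid to a fine
# grid (trilinear); `scale` is the per-axis fine/coarse size ratio.  Vector
# magnitudes are handled by the caller.
upsample_to <- function(arr, fine_dim, scale) {
  g <- coord_grids(fine_dim)
  array(sample_trilinear(arr, g$x / scale[1], g$y / scale[2], g$z / scale[3]),
        dim = fine_dim)
}
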