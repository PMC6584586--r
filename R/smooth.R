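# Separable Gaussian and box filtering implemented as banded-matrix
# multiplies along each axis. At the grid sizes this package targets
# (<= 128 per axis) a dense n x n kernel matrix times an n x m slab is
# faster in R than explicit convolution loops, and BLAS does the work.

.kernel_cache <- new.env(parent = emptyenv())

# reflective-boundary Gaussian kernel matrix for axis length n
gauss_kernel_matrix <- function(n, sigma) {
  key <- sprintf("g:%d:%.6g", n, sigma)
  K <- .kernel_cache[[key]]
  if (!is.null(K)) return(K)
  r <- max(1L, ceiling(3 * sigma))
  w <- dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    j <- seq_len(n) + o
    j[j < 1L] <- 2L - j[j < 1L]        # reflect at the lower edge
    j[j > n] <- 2L * n - j[j > n]      # and at the upper edge
    for (i in seq_len(n)) K[i, j[i]] <- K[i, j[i]] + w[o + r + 1L]
  }
  .kernel_cache[[key]] <- K
  K
}

# zero-truncated box-sum matrix (uniform weights, window radius r)
box_sum_matrix <- function(n, r) {
  key <- sprintf("b:%d:%d", n, r)
  K <- .kernel_cache[[key]]
  if (!is.null(K)) return(K)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    K[i, j] <- 1
  }
  .kernel_cache[[key]] <- K
  K
}

apply_axis <- function(a, K, axis) {
  d <- dim(a)
  if (axis == 1L) {
    array(K %*% matrix(a, d[1]), d)
  } else if (axis == 2L) {
    p <- aperm(a, c(2L, 1L, 3L))
    aperm(array(K %*% matrix(p, d[2]), c(d[2], d[1], d[3])), c(2L, 1L, 3L))
  } else {
    p <- aperm(a, c(3L, 1L, 2L))
    aperm(array(K %*% matrix(p, d[3]), c(d[3], d[1], d[2])), c(2L, 3L, 1L))
  }
}

gauss_weights <- function(sigma) {
  key <- sprintf("w:%.6g", sigma)
  w <- .kernel_cache[[key]]
  if (is.null(w)) {
    r <- max(1L, ceiling(3 * sigma))
    w <- dnorm(seq(-r, r), sd = sigma)
    w <- w / sum(w)
    .kernel_cache[[key]] <- w
  }
  w
}

# Gaussian smoothing of a plain 3-D array, sigma in voxels, reflective edges
smooth_array <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  array(smooth3_cpp(as.double(a), as.integer(d), gauss_weights(sigma)), d)
}

# box-filter local sums over a cubic window of radius r (zero outside grid)
box_sum_array <- function(a, r) {
  d <- dim(a)
  for (ax in 1:3) a <- apply_axis(a, box_sum_matrix(d[ax], r), ax)
  a
}

smooth_field_arrays <- function(v, sigma) {
  if (sigma <= 0) return(v)
  for (k in 1:3) v[, , , k] <- smooth_array(v[, , , k], sigma)
  v
}

#' Gaussian-smooth a scalar map
#'
#' Isotropic Gaussian convolution with reflective boundaries; `sigma = 0`
#' is the identity. Used to smooth log-Jacobian and other contrast maps
#' before voxelwise statistics (default pipeline sigma: 3 voxels).
#'
#' @param vol a `scalar_volume`.
#' @param sigma kernel standard deviation in voxels.
#' @return a smoothed `scalar_volume`.
#' @export
smooth_map <- function(vol, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(vol)
  scalar_volume(smooth_array(vol$data, sigma), vol$grid, vol$contrast)
}
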