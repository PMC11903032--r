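# Separable Gaussian smoothing of 3-D arrays, plus the analytic kernel
# quantities (variance shrinkage, autocorrelation) that keep smoothed
# white noise calibrated.

FWHM_SIGMA <- 2 * sqrt(2 * log(2))  # fwhm = sigma * 2.3548

#' @keywords internal
fwhm_to_sigma_vox <- function(fwhm_mm, voxel_size_mm) {
  fwhm_mm / voxel_size_mm / FWHM_SIGMA
}

gaussian_kernel_1d <- function(sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(truncate * sigma_vox))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

conv_matrix <- function(n, kernel) {
  # banded convolution matrix with edge renormalization (rows sum to 1)
  half <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- kernel[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  K
}

#' Smooth a 3-D array with a separable Gaussian kernel
#'
#' Edge voxels use a renormalized (truncated) kernel so the local mean is
#' preserved everywhere.
#'
#' @param arr 3-D numeric array.
#' @param sigma_vox Gaussian SD per axis in voxel units (length 1 or 3);
#'   axes with sigma 0 are left untouched.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  stopifnot(length(d) == 3)
  sigma_vox <- rep_len(sigma_vox, 3)
  if (sigma_vox[1] > 0) {
    K <- conv_matrix(d[1], gaussian_kernel_1d(sigma_vox[1]))
    arr <- array(K %*% matrix(arr, d[1]), d)
  }
  if (sigma_vox[2] > 0) {
    K <- conv_matrix(d[2], gaussian_kernel_1d(sigma_vox[2]))
    a <- aperm(arr, c(2, 1, 3))
    a <- array(K %*% matrix(a, d[2]), c(d[2], d[1], d[3]))
    arr <- aperm(a, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    K <- conv_matrix(d[3], gaussian_kernel_1d(sigma_vox[3]))
    arr <- array(matrix(arr, d[1] * d[2]) %*% t(K), d)
  }
  arr
}

# variance of interior voxels after smoothing unit white noise
smooth_variance_factor <- function(sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  prod(vapply(sigma_vox, function(s) sum(gaussian_kernel_1d(s)^2), 0))
}

#' Smoothed unit-variance white-noise field
#'
#' Draws white Gaussian noise on `dims`, smooths it, and rescales by the
#' analytic interior variance factor so interior voxels have (marginal)
#' unit variance.
#'
#' @keywords internal
smooth_unit_noise <- function(dims, sigma_vox) {
  arr <- array(rnorm(prod(dims)), dims)
  sigma_vox <- rep_len(sigma_vox, 3)
  if (all(sigma_vox <= 0)) return(arr)
  gaussian_smooth3d(arr, sigma_vox) / sqrt(smooth_variance_factor(sigma_vox))
}

# per-axis lag autocorrelation of smoothed white noise (interior voxels)
kernel_acf_1d <- function(sigma_vox, max_lag) {
  k <- gaussian_kernel_1d(sigma_vox)
  n <- length(k)
  vapply(0:max_lag, function(d) {
    if (d >= n) return(0)
    sum(k[1:(n - d)] * k[(1 + d):n])
  }, 0) / sum(k^2)
}

# variance of the mean over mask voxels of unit-variance smoothed noise,
# relative to a single voxel (equals 1/n for white noise)
mask_mean_noise_factor <- function(mask, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  n <- mask$n_voxels
  if (all(sigma_vox <= 0)) return(1 / n)
  co <- mask$coords
  rng <- apply(co, 2, function(x) diff(range(x)))
  acf <- lapply(1:3, function(a) kernel_acf_1d(sigma_vox[a], rng[a]))
  tot <- 0
  for (i in seq_len(n)) {
    dd <- abs(sweep(co, 2, co[i, ]))
    tot <- tot + sum(acf[[1]][dd[, 1] + 1] * acf[[2]][dd[, 2] + 1] *
                       acf[[3]][dd[, 3] + 1])
  }
  tot / n^2
}
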