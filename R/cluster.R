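# Cluster-extent inference: residual-based smoothness estimation, a
# Monte-Carlo (AlphaSim-style) null distribution of maximum cluster size
# within the analysis mask, and connected-component labeling of
# supra-threshold voxels.

#' Estimate map smoothness from residual maps
#'
#' Per axis, the effective Gaussian FWHM is derived from the ratio of the
#' variance of first spatial differences to the map variance:
#' `FWHM_a = voxel_size_a * sqrt(-2 * log(2) / log(1 - s2_delta / (2 * s2)))`,
#' computed per residual map and averaged over the maps for which the
#' ratio is estimable (inside (0, 1)). For white noise convolved with a
#' Gaussian kernel this recovers the kernel FWHM in expectation.
#'
#' @param residual_maps map x voxel matrix (>= 2 rows), e.g. per-subject
#'   group-median-centered FC residuals.
#' @param mask a [fc_mask]; differences are taken only between pairs of
#'   in-mask neighbors.
#' @param source label recorded on the estimate (which maps it came from).
#' @return A `smoothness_estimate`: list with `fwhm` (mm per axis, 0 where
#'   non-estimable), `fwhm_iso` (geometric mean) and `source`.
#' @export
estimate_fwhm <- function(residual_maps, mask, source = "residual maps") {
  residual_maps <- as.matrix(residual_maps)
  if (nrow(residual_maps) < 2)
    stop("need at least 2 residual maps", call. = FALSE)
  shape <- mask$grid$shape
  inmask <- array(FALSE, shape)
  inmask[mask$linear] <- TRUE
  pair_ok <- lapply(1:3, function(a) {
    both <- shift_axis(inmask, a) & inmask
    which(both)  # linear indices of voxels whose +1 neighbor is in mask
  })
  fwhm_sum <- numeric(3)
  fwhm_n <- integer(3)
  for (m in seq_len(nrow(residual_maps))) {
    arr <- array(0, shape)
    arr[mask$linear] <- residual_maps[m, ]
    s2 <- var(residual_maps[m, ])
    for (a in 1:3) {
      idx <- pair_ok[[a]]
      if (length(idx) < 2 || s2 == 0) next
      dvals <- shift_axis(arr, a)[idx] - arr[idx]
      ratio <- var(dvals) / (2 * s2)
      if (ratio > 0 && ratio < 1) {
        fwhm_sum[a] <- fwhm_sum[a] +
          mask$grid$voxel_size[a] * sqrt(-2 * log(2) / log(1 - ratio))
        fwhm_n[a] <- fwhm_n[a] + 1L
      }
    }
  }
  fwhm <- ifelse(fwhm_n > 0, fwhm_sum / pmax(fwhm_n, 1L), 0)
  if (any(fwhm_n == 0))
    warning("smoothness non-estimable along axis ",
            paste(which(fwhm_n == 0), collapse = ", "), "; reported as 0")
  structure(list(fwhm = fwhm, fwhm_iso = prod(fwhm)^(1 / 3), source = source),
            class = "smoothness_estimate")
}

# value of the +1 neighbor along `axis` (zero-padded at the far edge)
shift_axis <- function(arr, axis) {
  d <- dim(arr)
  out <- array(if (is.logical(arr)) FALSE else 0, d)
  switch(axis,
         `1` = {out[1:(d[1] - 1), , ] <- arr[2:d[1], , ]},
         `2` = {out[, 1:(d[2] - 1), ] <- arr[, 2:d[2], ]},
         `3` = {out[, , 1:(d[3] - 1)] <- arr[, , 2:d[3]]})
  out
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness> fwhm = (%s) mm, iso %.2f mm [%s]\n",
              paste(format(x$fwhm, digits = 3), collapse = ", "),
              x$fwhm_iso, x$source))
  invisible(x)
}

#' Monte-Carlo cluster-extent threshold
#'
#' Repeatedly fills the analysis mask with white Gaussian noise, convolves
#' it to the target smoothness, re-standardizes within the mask,
#' thresholds at the two-tailed z quantile of `voxel_p`, and records the
#' maximum supra-threshold cluster size. The returned extent threshold is
#' the smallest integer s such that a max cluster of size >= s arises in at
#' most `corrected_alpha` of the iterations, i.e. clusters of that size
#' control family-wise error at `corrected_alpha` within the mask.
#'
#' @param mask a [fc_mask] (the gray-matter analysis domain).
#' @param smoothness a `smoothness_estimate` (or numeric fwhm mm, length 1
#'   or 3).
#' @param voxel_p voxel-forming p threshold (two-tailed), in (0, 1).
#' @param corrected_alpha target family-wise error level.
#' @param n_iterations Monte-Carlo iterations (>= 100; 1000 is ample for
#'   the mask sizes this package targets, 100000 supported).
#' @param connectivity 6 (faces, default), 18 or 26.
#' @param rng_seed integer seed.
#' @return integer cluster-size threshold, with attributes `max_sizes`
#'   (the simulated maxima) and `attained_alpha`.
#' @export
monte_carlo_cluster_threshold <- function(mask, smoothness, voxel_p = 0.05,
                                          corrected_alpha = 0.05,
                                          n_iterations = 1000,
                                          connectivity = 6, rng_seed = 1L) {
  stopifnot(voxel_p > 0, voxel_p < 1, n_iterations >= 100)
  fwhm <- if (inherits(smoothness, "smoothness_estimate")) smoothness$fwhm
          else rep_len(smoothness, 3)
  sigma_vox <- fwhm_to_sigma_vox(fwhm, mask$grid$voxel_size)
  zc <- qnorm(1 - voxel_p / 2)
  shape <- mask$grid$shape
  lin <- mask$linear
  supra <- array(FALSE, shape)
  max_sizes <- integer(n_iterations)
  with_seed(rng_seed, {
    for (it in seq_len(n_iterations)) {
      field <- array(rnorm(prod(shape)), shape)
      if (any(sigma_vox > 0)) field <- gaussian_smooth3d(field, sigma_vox)
      v <- field[lin]
      v <- (v - mean(v)) / sd(v)
      supra[] <- FALSE
      supra[lin] <- abs(v) > zc
      max_sizes[it] <- max_component_size_cpp(as.vector(supra), shape,
                                              connectivity)
    }
  })
  # smallest s with P(max size >= s) <= alpha
  tab <- rev(cumsum(rev(tabulate(max_sizes + 1L, max(max_sizes) + 1L))))
  frac <- tab / n_iterations  # frac[s + 1] = P(max >= s)
  s_ok <- which(frac <= corrected_alpha) - 1L
  thr <- if (length(s_ok)) min(s_ok) else max(max_sizes) + 1L
  structure(as.integer(thr),
            max_sizes = max_sizes,
            attained_alpha = mean(max_sizes >= thr))
}

#' Label and vet supra-threshold clusters
#'
#' Connected components of `{p < voxel_p}` under the chosen neighborhood;
#' components smaller than `size_threshold` are dropped. Cluster ids are
#' deterministic: ordered by size descending, ties broken by peak
#' coordinate.
#'
#' @param stat a [stat_map] carrying a mask.
#' @param voxel_p voxel-forming p threshold.
#' @param size_threshold minimum cluster extent in voxels (e.g. from
#'   [monte_carlo_cluster_threshold()]).
#' @param connectivity 6, 18 or 26.
#' @param corrected_alpha recorded on the result for provenance.
#' @return A `cluster_set`: list with `labels` (per-mask-voxel cluster id,
#'   0 = background), `clusters` (data frame: id, size, peak_stat,
#'   peak_i/j/k), and the vetting parameters.
#' @export
label_clusters <- function(stat, voxel_p = 0.05, size_threshold = 0,
                           connectivity = 6, corrected_alpha = NA) {
  stopifnot(inherits(stat, "stat_map"))
  mask <- stat$mask
  if (is.null(mask)) stop("stat map carries no mask", call. = FALSE)
  shape <- mask$grid$shape
  supra <- array(FALSE, shape)
  supra[mask$linear] <- stat$p < voxel_p & !stat$degenerate
  raw <- label_components_cpp(as.vector(supra), shape, connectivity)
  raw_mask <- raw[mask$linear]
  sizes <- tabulate(raw_mask)
  keep <- which(sizes >= max(size_threshold, 1L))
  labels <- integer(mask$n_voxels)
  clusters <- data.frame(id = integer(), size = integer(),
                         peak_stat = numeric(), peak_i = integer(),
                         peak_j = integer(), peak_k = integer())
  if (length(keep)) {
    info <- lapply(keep, function(g) {
      vox <- which(raw_mask == g)
      s <- stat$statistic[vox]
      pk <- vox[order(-abs(s), vox)[1]]
      c(size = length(vox), peak_stat = stat$statistic[pk],
        i = mask$coords[pk, 1], j = mask$coords[pk, 2],
        k = mask$coords[pk, 3])
    })
    info <- do.call(rbind, info)
    ord <- order(-info[, "size"], info[, "i"], info[, "j"], info[, "k"])
    for (new_id in seq_along(ord)) {
      g <- keep[ord[new_id]]
      labels[raw_mask == g] <- new_id
    }
    clusters <- data.frame(id = seq_along(ord),
                           size = as.integer(info[ord, "size"]),
                           peak_stat = info[ord, "peak_stat"],
                           peak_i = as.integer(info[ord, "i"]),
                           peak_j = as.integer(info[ord, "j"]),
                           peak_k = as.integer(info[ord, "k"]))
    rownames(clusters) <- NULL
  }
  structure(list(labels = labels, clusters = clusters, mask = mask,
                 size_threshold = as.integer(size_threshold),
                 voxel_p = voxel_p, connectivity = connectivity,
                 corrected_alpha = corrected_alpha),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) >= %d voxels (voxel p < %g, %d-connectivity)\n",
              nrow(x$clusters), x$size_threshold, x$voxel_p, x$connectivity))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
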