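test_that("smoothness estimator distinguishes white from smoothed noise", {
  grid <- voxel_grid(c(20, 20, 20), c(2, 2, 2))
  mask <- full_mask(grid)
  set.seed(31)
  white <- matrix(rnorm(6 * mask$n_voxels), 6)
  est_w <- estimate_fwhm(white, mask)
  expect_lt(est_w$fwhm_iso, 1.2 * 2)  # below 1.2 voxels

  # a known 6 mm kernel on a 2 mm grid is recovered within [4.8, 7.2] mm
  sm <- t(vapply(1:6, function(i)
    as.vector(gaussian_smooth3d(array(rnorm(20^3), c(20, 20, 20)),
                                6 / 2 / (2 * sqrt(2 * log(2))))),
    numeric(mask$n_voxels)))
  est_s <- estimate_fwhm(sm, mask)
  expect_gt(est_s$fwhm_iso, 4.8)
  expect_lt(est_s$fwhm_iso, 7.2)
})

test_that("a spatially constant map is flagged non-estimable", {
  grid <- voxel_grid(c(8, 8, 8), c(2, 2, 2))
  mask <- full_mask(grid)
  # zero spatial variance: the difference-variance ratio is undefined
  maps <- rbind(rep(1, mask$n_voxels), rep(2.5, mask$n_voxels))
  expect_warning(est <- estimate_fwhm(maps, mask), "non-estimable")
  expect_equal(est$fwhm_iso, 0)
  expect_error(estimate_fwhm(maps[1, , drop = FALSE], mask), "at least 2")
})

test_that("cluster labeling obeys the connectivity contract", {
  grid <- voxel_grid(c(10, 10, 10), c(2, 2, 2))
  mask <- full_mask(grid)
  p <- rep(1, mask$n_voxels)
  sm <- stat_map(rep(0, mask$n_voxels), p, c(1, 8), "t", mask = mask)
  expect_equal(nrow(label_clusters(sm, 0.05, 0)$clusters), 0)

  # a hand-built 10-voxel face-connected blob survives threshold 5
  blob <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2), c(4, 3, 2), c(4, 4, 2),
                c(4, 4, 3), c(4, 4, 4), c(5, 4, 4), c(6, 4, 4), c(6, 5, 4))
  lin <- blob[, 1] + (blob[, 2] - 1) * 10 + (blob[, 3] - 1) * 100
  p2 <- rep(1, mask$n_voxels)
  p2[match(lin, mask$linear)] <- 0.001
  stat <- rep(0, mask$n_voxels); stat[match(lin, mask$linear)] <- 5
  sm2 <- stat_map(stat, p2, c(1, 8), "t", mask = mask)
  cl <- label_clusters(sm2, 0.05, 5)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$size, 10)

  # two blobs touching only at a corner: separate under 6, merged under 26
  pc <- rep(1, mask$n_voxels)
  blk1 <- box_mask(grid, c(1, 1, 1), c(2, 2, 2))
  blk2 <- box_mask(grid, c(3, 3, 3), c(4, 4, 4))
  pc[match(c(blk1$linear, blk2$linear), mask$linear)] <- 0.001
  sm3 <- stat_map(rep(1, mask$n_voxels), pc, c(1, 8), "t", mask = mask)
  expect_equal(nrow(label_clusters(sm3, 0.05, 0, connectivity = 6)$clusters), 2)
  expect_equal(nrow(label_clusters(sm3, 0.05, 0, connectivity = 26)$clusters), 1)
})

test_that("cluster ids are deterministic across voxel orderings", {
  grid <- voxel_grid(c(8, 8, 8), c(2, 2, 2))
  mask <- full_mask(grid)
  set.seed(44)
  p <- runif(mask$n_voxels)
  sm <- stat_map(rnorm(mask$n_voxels), p, c(1, 8), "t", mask = mask)
  cl1 <- label_clusters(sm, 0.2, 2)
  cl2 <- label_clusters(sm, 0.2, 2)
  expect_identical(cl1$labels, cl2$labels)
  expect_identical(cl1$clusters, cl2$clusters)
  # ordered by size descending
  expect_true(all(diff(cl1$clusters$size) <= 0))
})

test_that("Monte-Carlo threshold calibrates and is monotone in its drivers", {
  grid <- voxel_grid(c(10, 10, 10), c(2, 2, 2))
  mask <- full_mask(grid)
  thr_white <- monte_carlo_cluster_threshold(mask, c(0, 0, 0),
                                             n_iterations = 300, rng_seed = 2)
  thr_smooth <- monte_carlo_cluster_threshold(mask, c(6, 6, 6),
                                              n_iterations = 300, rng_seed = 2)
  expect_gt(thr_smooth, thr_white)

  thr_loose <- monte_carlo_cluster_threshold(mask, c(4, 4, 4),
                                             corrected_alpha = 0.20,
                                             n_iterations = 300, rng_seed = 2)
  thr_tight <- monte_carlo_cluster_threshold(mask, c(4, 4, 4),
                                             corrected_alpha = 0.01,
                                             n_iterations = 300, rng_seed = 2)
  expect_lte(thr_loose, thr_tight)

  # supra-threshold fraction per iteration is close to voxel_p for white noise
  set.seed(7)
  fracs <- replicate(50, {
    z <- rnorm(mask$n_voxels)
    z <- (z - mean(z)) / sd(z)
    mean(abs(z) > qnorm(1 - 0.05 / 2))
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.01)
})

test_that("the returned threshold controls FWER on fresh null maps", {
  # 20^3 mask, 2-voxel fwhm, 1000 threshold iterations, 500 fresh maps
  grid <- voxel_grid(c(20, 20, 20), c(2, 2, 2))
  mask <- full_mask(grid)
  fwhm <- c(4, 4, 4)  # 2 voxels at 2 mm
  thr <- monte_carlo_cluster_threshold(mask, fwhm, voxel_p = 0.05,
                                       corrected_alpha = 0.05,
                                       n_iterations = 1000, rng_seed = 19)
  sigma <- 4 / 2 / (2 * sqrt(2 * log(2)))
  set.seed(91)
  hits <- replicate(500, {
    f <- gaussian_smooth3d(array(rnorm(20^3), c(20, 20, 20)), sigma)
    v <- f[mask$linear]
    v <- (v - mean(v)) / sd(v)
    supra <- array(FALSE, grid$shape)
    supra[mask$linear] <- abs(v) > qnorm(1 - 0.05 / 2)
    fcvar:::max_component_size_cpp(as.vector(supra), grid$shape, 6L) >= thr
  })
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.09)
})
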