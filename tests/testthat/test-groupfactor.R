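test_that("two-group ANOVA F equals the squared post hoc t at every voxel", {
  set.seed(15)
  g <- factor(rep(c("deaf", "hearing"), c(16, 33)))
  fc <- matrix(rnorm(49 * 500), 49)
  des <- group_design(sprintf("s%02d", 1:49), g)
  gm <- group_mean_map(fc, des)
  expect_equal(gm$anova$statistic, gm$posthoc_t$deaf_vs_hearing$statistic^2,
               tolerance = 1e-9)
  # sign convention: first minus second group
  fc2 <- fc
  fc2[g == "deaf", 1] <- fc2[g == "deaf", 1] + 5
  gm2 <- group_mean_map(fc2, des)
  expect_gt(gm2$posthoc_t$deaf_vs_hearing$statistic[1], 0)
})

test_that("group F stays calibrated under group-separated nuisance covariates", {
  set.seed(71)
  g <- factor(rep(c("deaf", "hearing"), c(39, 33)))
  # accuracy-style covariate: group separation ~2.5 within-group SDs
  acc <- rnorm(72, ifelse(g == "deaf", 0.74, 0.89), 0.06)
  des <- group_design(sprintf("s%02d", 1:72), g, cbind(acc = acc))
  fc <- matrix(rnorm(72 * 4000), 72)  # null: no group effect
  gm <- group_mean_map(fc, des)
  rate <- mean(gm$anova$p < 0.05)
  expect_gt(rate, 0.035); expect_lt(rate, 0.065)
  # identical maps whether fc is raw or pre-residualized
  gm2 <- group_mean_map(residualize(fc, des), des)
  expect_equal(gm$anova$statistic, gm2$anova$statistic, tolerance = 1e-9)
  # F = t^2 holds in the covariate-adjusted model too
  expect_equal(gm$anova$statistic, gm$posthoc_t$deaf_vs_hearing$statistic^2,
               tolerance = 1e-9)
})

test_that("group mean differences are detected and nulls stay calibrated", {
  set.seed(23)
  g <- factor(rep(c("deaf", "hearing"), c(39, 33)))
  des <- group_design(sprintf("s%02d", 1:72), g)
  fc <- matrix(rnorm(72 * 2000, sd = 0.2), 72)
  fc[g == "deaf", 1:100] <- fc[g == "deaf", 1:100] + 0.3  # planted 0.5 vs 0.2
  gm <- group_mean_map(fc, des)
  expect_gt(mean(gm$anova$p[1:100] < 0.05), 0.9)
  expect_lt(mean(gm$anova$p[101:2000] < 0.05), 0.08)
})

test_that("planted reorganization is detected by cluster-vetted ANOVA maps", {
  # planted group means 0.5 vs 0.2 (deaf n = 39, hearing n = 33)
  grid <- voxel_grid(c(20, 20, 20), c(2, 2, 2))
  hits <- 0
  for (i in 1:10) {
    co <- simulate_fc_cohort(groups = c(deaf = 39, hearing = 33), grid = grid,
                             rng_seed = 3000 + i)
    # unconfounded design: power of the group contrast itself (covariates
    # group-separated as in the study trade power for bias control, tested
    # separately above)
    des <- group_design(co$cohort$subject, co$cohort$group)
    gm <- group_mean_map(co$fc, des, mask = co$mask)
    sm <- estimate_fwhm(fcvar:::center_by_group(co$fc, des$group_labels),
                        co$mask)
    thr <- monte_carlo_cluster_threshold(co$mask, sm, n_iterations = 300,
                                         rng_seed = 3100 + i)
    cl <- label_clusters(gm$anova, 0.05, thr)
    vet <- which(cl$labels > 0)
    truth <- co$truth$effect_masks[[1]]$linear  # the 0.5-vs-0.2 region
    if (length(vet) &&
        length(intersect(co$mask$linear[vet], truth)) / length(truth) > 0.3)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("factor correlation maps are calibrated and recover planted coupling", {
  set.seed(33)
  n <- 39
  fc <- matrix(rnorm(n * 4000), n)
  fac <- rnorm(n)
  sm <- factor_correlation_map(fc, fac)
  expect_gt(mean(sm$p), 0.47)
  expect_lt(mean(sm$p), 0.53)

  # factor equal to the planted subject effect: near-ceiling r at low noise
  z_s <- rnorm(n, 0.5, 0.3)
  fc2 <- outer(z_s, rep(1, 50)) + matrix(rnorm(n * 50, sd = 0.02), n)
  sm2 <- factor_correlation_map(fc2, z_s)
  expect_gt(mean(sm2$statistic), 0.9)

  # coupling chosen for rho = 0.5
  rho <- 0.5
  fac3 <- rho * scale(z_s)[, 1] + sqrt(1 - rho^2) * rnorm(n)
  fc3 <- outer(z_s, rep(1, 200)) + matrix(rnorm(n * 200, sd = 0.3), n)
  sm3 <- factor_correlation_map(fc3, fac3)
  expect_gt(mean(sm3$statistic), 0.35)
  expect_lt(mean(sm3$statistic), 0.62)

  expect_error(factor_correlation_map(fc, rep(1, n)), "constant")
  expect_error(factor_correlation_map(fc[1:4, ], fac[1:4]), "at least 5")
})

test_that("partialling covariates out of factor correlations removes confounds", {
  set.seed(40)
  n <- 60
  age <- rnorm(n)
  fc <- outer(age, rep(1, 300)) + matrix(rnorm(n * 300, sd = 0.5), n)
  fac <- age + rnorm(n, sd = 0.3)  # factor confounded with age
  naive <- factor_correlation_map(fc, fac)
  partial <- factor_correlation_map(fc, fac, covariates = cbind(age = age))
  expect_gt(mean(naive$statistic), 0.5)
  expect_lt(abs(mean(partial$statistic)), 0.1)
  expect_equal(unname(partial$df["df"]), n - 2 - 1)
})

test_that("ROI extraction preserves cluster geometry and is deterministic", {
  grid <- voxel_grid(c(12, 12, 12), c(2, 2, 2))
  mask <- full_mask(grid)
  p <- rep(1, mask$n_voxels)
  boxes <- list(box_mask(grid, c(1, 1, 1), c(2, 2, 2)),
                box_mask(grid, c(5, 5, 5), c(7, 7, 7)),
                box_mask(grid, c(10, 1, 1), c(12, 2, 2)),
                box_mask(grid, c(1, 10, 10), c(1, 12, 12)))
  for (b in boxes) p[match(b$linear, mask$linear)] <- 1e-4
  sm <- stat_map(rnorm(mask$n_voxels), p, c(1, 10), "F", mask = mask)
  cl <- label_clusters(sm, 0.05, 0)
  expect_equal(nrow(cl$clusters), 4)

  rois <- extract_rois(cl, min_size = 0)
  expect_length(rois$rois, 4)
  expect_setequal(vapply(rois$rois, function(r) r$mask$n_voxels, 0L),
                  vapply(boxes, function(b) b$n_voxels, 0L))
  rois2 <- extract_rois(cl, min_size = 0)
  expect_identical(vapply(rois$rois, `[[`, "", "label"),
                   vapply(rois2$rois, `[[`, "", "label"))
  expect_warning(empty <- extract_rois(cl, min_size = 1000), "no clusters")
  expect_length(empty$rois, 0)
})

test_that("single-voxel ROI correlations equal the voxel-wise map exactly", {
  set.seed(50)
  grid <- voxel_grid(c(6, 6, 6), c(2, 2, 2))
  mask <- full_mask(grid)
  n <- 30
  fc <- matrix(rnorm(n * mask$n_voxels), n)
  fac <- rnorm(n)
  p <- rep(1, mask$n_voxels); p[100] <- 1e-6
  sm <- stat_map(rep(1, mask$n_voxels), p, c(1, 10), "F", mask = mask)
  cl <- label_clusters(sm, 0.05, 0)
  rois <- extract_rois(cl)
  res <- roi_factor_correlation(fc, rois, mask, data.frame(fac = fac))
  vox_map <- factor_correlation_map(fc, fac)
  expect_equal(res$table$r[1], vox_map$statistic[100], tolerance = 1e-12)
  expect_equal(res$table$p[1], vox_map$p[100], tolerance = 1e-12)
})

test_that("BH q-values are monotone in p and planted ROI coupling is ranked", {
  set.seed(60)
  grid <- voxel_grid(c(8, 8, 8), c(2, 2, 2))
  mask <- full_mask(grid)
  roiA <- box_mask(grid, c(2, 2, 2), c(3, 3, 3))
  roiB <- box_mask(grid, c(6, 6, 6), c(7, 7, 7))
  rois <- structure(list(rois = list(list(label = "A", mask = roiA),
                                     list(label = "B", mask = roiB)),
                         source = "test"), class = "roi_set")
  hits <- 0
  n <- 30; rho <- 0.6
  for (rep_i in 1:15) {
    z_s <- rnorm(n)
    fac <- rho * z_s + sqrt(1 - rho^2) * rnorm(n)
    fc <- matrix(rnorm(n * mask$n_voxels, sd = 0.3), n)
    fc[, match(roiA$linear, mask$linear)] <-
      fc[, match(roiA$linear, mask$linear)] + z_s
    res <- roi_factor_correlation(fc, rois, mask, data.frame(f = fac))
    qa <- res$table$q[res$table$roi == "A"]
    qb <- res$table$q[res$table$roi == "B"]
    if (qa < 0.05 && qb >= 0.05) hits <- hits + 1
    expect_true(all(res$table$q >= res$table$p - 1e-12))
    ord <- order(res$table$p)
    expect_true(all(diff(res$table$q[ord]) >= -1e-12))
  }
  expect_gte(hits, 11)  # >= ~80% of cohorts

  # missing factor values are dropped listwise with n reported
  fac_na <- rnorm(n); fac_na[1:7] <- NA
  fc <- matrix(rnorm(n * mask$n_voxels), n)
  res2 <- roi_factor_correlation(fc, rois, mask, data.frame(f = fac_na))
  expect_true(all(res2$table$n == n - 7))

  # a constant ROI is reported as missing with a reason
  fc[, match(roiA$linear, mask$linear)] <- 1
  res3 <- roi_factor_correlation(fc, rois, mask, data.frame(f = rnorm(n)))
  expect_true(is.na(res3$table$r[res3$table$roi == "A"]))
  expect_match(res3$table$note[res3$table$roi == "A"], "constant")
})
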