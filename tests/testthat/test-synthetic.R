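test_that("expected_correlation matches its closed forms and a Monte-Carlo oracle", {
  expect_equal(expected_correlation(1, 1, 0), 1 / sqrt(2))
  expect_equal(expected_correlation(0, 1, 1, 10), 0)

  # Monte-Carlo oracle at 200k time points
  set.seed(2)
  n <- 200000; w <- 0.75; tn <- 1.2; sn <- 1.0; nv <- 30
  g <- rnorm(n)
  seed_mean <- g + rnorm(n, 0, sn / sqrt(nv))
  target <- w * g + rnorm(n, 0, tn)
  expect_lt(abs(cor(seed_mean, target) - expected_correlation(w, tn, sn, nv)),
            0.005)
})

test_that("coupling_for_correlation inverts expected_correlation", {
  for (r in c(-0.6, -0.1, 0.2, 0.46, 0.8)) {
    w <- coupling_for_correlation(r, 1.3, 0.9, 12)
    expect_equal(expected_correlation(w, 1.3, 0.9, 12), r, tolerance = 1e-12)
  }
  # the seed-mean noise caps attainable |r|
  expect_error(coupling_for_correlation(0.999, 1, 2, 1), "not attainable")
})

test_that("generate_cohort is reproducible and structurally correct", {
  cfg <- white_cohort_config(c(a = 3, b = 4), volumes = 40, n_runs = 2,
                             rng_seed = 42)
  coh <- generate_cohort(cfg)
  expect_length(coh$subjects, 7)
  expect_equal(nrow(coh$cohort), 7)
  expect_equal(as.character(coh$cohort$group), rep(c("a", "b"), c(3, 4)))
  expect_length(coh$subjects[[1]]$runs, 2)
  expect_equal(nrow(coh$subjects[[1]]$runs[[1]]$data), 40)
  expect_named(coh$subjects[[1]]$confounds[[1]],
               c("drift", "task", paste0("motion_", 1:6)))

  coh2 <- generate_cohort(cfg)
  expect_identical(coh$subjects[[2]]$runs[[1]]$data,
                   coh2$subjects[[2]]$runs[[1]]$data)
  expect_identical(coh$truth$z, coh2$truth$z)

  # different subjects use different substreams
  expect_false(identical(coh$subjects[[1]]$runs[[1]]$data,
                         coh$subjects[[2]]$runs[[1]]$data))
})

test_that("overlapping seed and effect masks are a config error", {
  grid <- voxel_grid(c(8, 8, 8), c(2, 2, 2))
  sm <- box_mask(grid, c(2, 2, 2), c(4, 4, 4))
  expect_error(
    cohort_config(groups = c(a = 3), grid = grid, seed_region = sm,
                  effect_regions = list(list(mask = box_mask(grid, c(4, 4, 4), c(6, 6, 6)),
                                             mu = c(a = 0.3), sigma = c(a = 0))),
                  spatial_fwhm = 0),
    "disjoint")
})

test_that("measured Fisher-z calibrates to the planted (mu, sigma)", {
  # planted mu = 0.5, sigma = 0.3, n = 40 subjects, long white-noise series
  cfg <- white_cohort_config(c(g = 40), mu = 0.5, volumes = 880, rng_seed = 7)
  cfg$effect_regions[[1]]$sigma[] <- 0.3
  coh <- generate_cohort(cfg)
  fc <- cohort_fc_matrix(coh$subjects, cfg$seed_region, cfg$analysis_mask,
                         band = c(0, 0.25))
  zhat <- rowMeans(fc[, effect_columns(cfg), drop = FALSE])
  se_z <- 1 / sqrt(880 - 3)
  se_mean <- sqrt(0.3^2 + se_z^2) / sqrt(40)
  expect_lt(abs(mean(zhat) - 0.5), 3 * se_mean)
  se_sd <- 0.3 / sqrt(2 * 39)
  expect_lt(abs(sd(zhat) - sqrt(0.3^2 + se_z^2)), 3 * se_sd)
})

test_that("confound mixing is recorded and removable", {
  # with drift and motion disabled, confound regression barely changes FC
  cfg <- white_cohort_config(c(g = 3), volumes = 1500, rng_seed = 3)
  cfg$drift_amplitude <- 0
  cfg$task_amplitude <- 0
  cfg$n_motion_regressors <- 0L
  coh <- generate_cohort(cfg)
  sub <- coh$subjects[[1]]
  raw <- seed_fc_map(sub$runs, cfg$seed_region, cfg$analysis_mask)
  basis <- build_projection(sub$confounds[[1]], 1500, 2, band = c(0, 0.25))
  den <- seed_fc_map(lapply(sub$runs, denoise_run, basis = basis),
                     cfg$seed_region, cfg$analysis_mask)
  expect_lt(max(abs(raw$values - den$values)), 0.01)

  # a strong drift biases naive FC; denoising restores the planted value
  cfg2 <- white_cohort_config(c(g = 8), mu = 0.5, volumes = 600, rng_seed = 9)
  cfg2$drift_amplitude <- 5
  cfg2$n_motion_regressors <- 2L
  coh2 <- generate_cohort(cfg2)
  eff <- effect_columns(cfg2)
  naive <- vapply(coh2$subjects, function(s)
    mean(seed_fc_map(s$runs, cfg2$seed_region, cfg2$analysis_mask)$values[eff]),
    0)
  fc <- cohort_fc_matrix(coh2$subjects, cfg2$seed_region, cfg2$analysis_mask,
                         band = c(0, 0.25))
  denoised <- rowMeans(fc[, eff, drop = FALSE])
  expect_gt(abs(mean(naive) - 0.5), 0.05)       # drift visibly corrupts
  expect_lt(abs(mean(denoised) - 0.5), 0.05)    # regression recovers
})

test_that("simulate_fc_cohort plants the group variance structure", {
  co <- simulate_fc_cohort(groups = c(deaf = 60, hearing = 60),
                           grid = voxel_grid(c(12, 12, 12), c(2, 2, 2)),
                           rng_seed = 21)
  er <- co$truth$effect_masks[[1]]
  cols <- match(er$linear, co$mask$linear)
  gl <- co$design$group_labels
  sd_deaf <- mean(apply(co$fc[gl == "deaf", cols], 2, sd))
  sd_hear <- mean(apply(co$fc[gl == "hearing", cols], 2, sd))
  # planted SDs are 0.4 and 0.2 plus measurement noise 0.04
  expect_equal(sd_deaf, sqrt(0.4^2 + 0.04^2), tolerance = 0.15)
  expect_equal(sd_hear, sqrt(0.2^2 + 0.04^2), tolerance = 0.15)

  co2 <- simulate_fc_cohort(groups = c(deaf = 60, hearing = 60),
                            grid = voxel_grid(c(12, 12, 12), c(2, 2, 2)),
                            rng_seed = 21)
  expect_identical(co$fc, co2$fc)
})

test_that("covariate coupling injects covariate-correlated variance", {
  spec <- list(list(name = "age", mean = c(deaf = 24, hearing = 21), sd = 1,
                    coupling = 2))
  co <- simulate_fc_cohort(groups = c(deaf = 40, hearing = 40),
                           grid = voxel_grid(c(10, 10, 10), c(2, 2, 2)),
                           covariate_spec = spec, rng_seed = 5)
  # covariates couple to the subject trait averaged over effect regions
  trait <- rowMeans(co$truth$z)
  zc <- trait - ave(trait, co$design$group_labels)
  agec <- co$cohort$age - ave(co$cohort$age, co$cohort$group)
  expect_gt(cor(zc, agec), 0.3)
})
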