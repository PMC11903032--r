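# Synthetic multi-subject cohorts with planted seed connectivity.
#
# Two generators share one ground-truth model on the Fisher-z scale:
#   * generate_cohort()    — full BOLD time series per subject and run, with
#     drift/motion/task confounds, for exercising the denoising and seed-FC
#     path end to end;
#   * simulate_fc_cohort() — per-subject Fisher-z FC maps drawn directly,
#     for exercising the variance-mapping and cluster-inference path at
#     cohort scale.
# In both, a subject s in group g carries a trait connectivity z_s ~
# Normal(mu_g, sigma_g^2) for each effect region; group differences in
# sigma_g are the planted signal the downstream variance tests recover.

#' Expected seed-target correlation for a coupled voxel
#'
#' Closed form for the Pearson correlation between a target voxel
#' `w * g(t) + noise` and the mean of `n_seed_voxels` seed voxels
#' `g(t) + noise`, where `g` is a unit-variance latent signal and the noise
#' terms are white with the given SDs.
#'
#' @param w coupling weight of the target voxel to the latent signal.
#' @param target_noise_sd,seed_noise_sd white-noise SDs at target and seed
#'   voxels.
#' @param n_seed_voxels number of seed voxels averaged.
#' @return The expected correlation `w / sqrt((1 + seed_noise_sd^2 /
#'   n_seed_voxels) * (w^2 + target_noise_sd^2))`.
#' @export
expected_correlation <- function(w, target_noise_sd, seed_noise_sd,
                                 n_seed_voxels = 1) {
  stopifnot(target_noise_sd >= 0, seed_noise_sd >= 0, n_seed_voxels >= 1,
            is.finite(w))
  w / sqrt((1 + seed_noise_sd^2 / n_seed_voxels) * (w^2 + target_noise_sd^2))
}

#' @rdname expected_correlation
#' @param r desired correlation (|r| below the attainable ceiling
#'   `1 / sqrt(1 + seed_noise_sd^2 / n_seed_voxels)`).
#' @export
coupling_for_correlation <- function(r, target_noise_sd, seed_noise_sd,
                                     n_seed_voxels = 1) {
  cfac <- 1 + seed_noise_sd^2 / n_seed_voxels
  coupling_general(r, target_noise_sd, cfac)
}

# general inverse: cfac = 1 + (variance of seed-mean noise relative to one
# voxel's signal variance); handles spatially correlated seed noise
coupling_general <- function(r, target_noise_sd, cfac) {
  if (any(r^2 * cfac >= 1))
    stop(sprintf("correlation %.4f is not attainable: seed-mean noise caps |r| at %.4f",
                 max(abs(r)), 1 / sqrt(cfac)), call. = FALSE)
  sign(r) * sqrt(r^2 * cfac * target_noise_sd^2 / (1 - r^2 * cfac))
}

#' Configuration for a synthetic BOLD cohort
#'
#' Defaults mirror the study design the package targets: three groups
#' (16 native-signing deaf, 23 delayed-signing deaf, 33 hearing), 10 runs of
#' 180 retained volumes at TR = 2 s, 2 mm voxels, spatially smooth noise at
#' 6 mm FWHM, and covariates (age, task accuracy, reaction time) whose group
#' means echo the cohort table of that design (hearing group younger and
#' more accurate).
#'
#' @param groups named integer vector of subjects per group.
#' @param n_runs,volumes_per_run,tr acquisition structure.
#' @param grid a [voxel_grid] (kept small by default; the generator is grid
#'   agnostic).
#' @param seed_region,effect_regions seed mask and a list of effect-region
#'   specs `list(mask =, mu =, sigma =)` with per-group Fisher-z mean and
#'   across-subject SD (named like `groups`).
#' @param analysis_mask gray-matter style mask defining which voxels carry
#'   data (defaults to the whole grid).
#' @param noise_sd white-noise SD relative to the unit-variance latent
#'   signal.
#' @param spatial_fwhm mm; noise fields are smoothed to this FWHM and
#'   rescaled so the marginal SD stays `noise_sd`.
#' @param drift_amplitude weight of the linear drift regressor mixed into
#'   every voxel.
#' @param n_motion_regressors number of motion-like (random-walk) nuisance
#'   series per run, mixed in with per-voxel weights.
#' @param task_amplitude weight of the block task regressor.
#' @param covariate_spec list of covariate specs
#'   `list(name =, mean = per-group named, sd =, coupling =)`; `coupling`
#'   is the linear coefficient from the subject's (centered) trait z to the
#'   covariate.
#' @param rng_seed integer seed; everything downstream is a pure function
#'   of the config and this seed.
#' @export
cohort_config <- function(groups = c(deaf_native = 16, deaf_delayed = 23, hearing = 33),
                          n_runs = 10, volumes_per_run = 180, tr = 2,
                          grid = voxel_grid(c(24, 24, 24), c(2, 2, 2)),
                          seed_region = box_mask(grid, c(4, 11, 11), c(6, 14, 14)),
                          effect_regions = default_effect_regions(grid, names(groups)),
                          analysis_mask = NULL,
                          noise_sd = 1, spatial_fwhm = 6,
                          drift_amplitude = 1, n_motion_regressors = 6,
                          task_amplitude = 0.5,
                          covariate_spec = default_covariates(names(groups)),
                          rng_seed = 1L) {
  stopifnot(length(groups) >= 1, all(groups >= 1), n_runs >= 1,
            volumes_per_run >= 1, tr > 0, noise_sd > 0, spatial_fwhm >= 0,
            n_motion_regressors >= 0)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  if (is.null(analysis_mask)) analysis_mask <- box_mask(grid, c(1, 1, 1), grid$shape)
  stop_if_grid_mismatch(seed_region$grid, grid, "seed mask")
  stop_if_grid_mismatch(analysis_mask$grid, grid, "analysis mask")
  for (er in effect_regions) {
    stop_if_grid_mismatch(er$mask$grid, grid, "effect mask")
    if (length(intersect(er$mask$linear, seed_region$linear)) > 0)
      stop("effect regions must be disjoint from the seed region", call. = FALSE)
    stopifnot(all(names(groups) %in% names(er$mu)),
              all(names(groups) %in% names(er$sigma)),
              all(er$sigma[names(groups)] >= 0))
  }
  structure(list(groups = groups, n_runs = n_runs,
                 volumes_per_run = volumes_per_run, tr = tr, grid = grid,
                 seed_region = seed_region, effect_regions = effect_regions,
                 analysis_mask = analysis_mask, noise_sd = noise_sd,
                 spatial_fwhm = spatial_fwhm,
                 drift_amplitude = drift_amplitude,
                 n_motion_regressors = n_motion_regressors,
                 task_amplitude = task_amplitude,
                 covariate_spec = covariate_spec, rng_seed = as.integer(rng_seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @param group_names group labels to key the per-group parameters by.
#' @export
default_effect_regions <- function(grid, group_names) {
  # two regions where the deaf group(s) carry both reorganized mean FC and
  # doubled across-subject spread ("variability over twice as large"), at a
  # typical Fisher-z scale; sizes mirror the multi-cluster structure of the
  # effects (one large temporal-like region, one smaller frontal-like one)
  hearing <- grepl("hearing", group_names)
  sigma <- stats::setNames(ifelse(hearing, 0.2, 0.4), group_names)
  mu1 <- stats::setNames(ifelse(hearing, 0.5, 0.2), group_names)
  mu2 <- stats::setNames(ifelse(hearing, 0.5, 0.65), group_names)
  lo1 <- pmax(1L, round(grid$shape * 0.55))
  hi1 <- pmin(grid$shape, lo1 + pmax(2L, round(grid$shape * 0.29)) - 1L)
  lo2 <- pmax(1L, round(grid$shape * 0.15))
  hi2 <- pmin(grid$shape, lo2 + pmax(2L, round(grid$shape * 0.25)) - 1L)
  list(list(mask = box_mask(grid, lo1, hi1), mu = mu1, sigma = sigma),
       list(mask = box_mask(grid, lo2, hi2), mu = mu2, sigma = sigma))
}

#' @rdname cohort_config
#' @export
default_covariates <- function(group_names) {
  gm <- function(deaf, hearing)
    stats::setNames(ifelse(grepl("hearing", group_names), hearing, deaf),
                    group_names)
  list(
    list(name = "age",      mean = gm(23.5, 21.0), sd = 2.5, coupling = 0),
    list(name = "accuracy", mean = gm(0.74, 0.89), sd = 0.06, coupling = 0),
    list(name = "rt",       mean = gm(1.083, 1.147), sd = 0.15, coupling = 0)
  )
}

group_vector <- function(groups) {
  factor(rep(names(groups), groups), levels = names(groups))
}

draw_covariates <- function(config, group_of, z_trait) {
  n <- length(group_of)
  out <- data.frame(subject = sprintf("sub-%03d", seq_len(n)),
                    group = as.character(group_of),
                    stringsAsFactors = FALSE)
  zc <- z_trait - ave(z_trait, group_of)  # centered within group
  for (cv in config$covariate_spec) {
    out[[cv$name]] <- cv$mean[as.character(group_of)] + cv$coupling * zc +
      rnorm(n, 0, cv$sd)
  }
  out
}

# Solve per-region coupling weights for a subject's trait z values,
# accounting for spatially correlated seed noise.
subject_couplings <- function(config, z_s, seed_cfac) {
  vapply(seq_along(z_s), function(i) {
    coupling_general(tanh(z_s[i]), config$noise_sd, seed_cfac)
  }, 0)
}

seed_noise_cfac <- function(config) {
  sigma_vox <- fwhm_to_sigma_vox(config$spatial_fwhm, config$grid$voxel_size)
  1 + config$noise_sd^2 *
    mask_mean_noise_factor(config$seed_region, sigma_vox)
}

#' Simulate one subject's runs
#'
#' Builds `n_runs` BOLD runs over the data mask (analysis mask plus seed):
#' seed voxels carry the unit-variance latent signal `g(t)` plus smoothed
#' noise, effect-region voxels carry `w * g(t)` plus noise with `w` solved
#' so the ideal-seed correlation equals `tanh(z_s)`, and every voxel gets a
#' recorded linear drift, block task regressor, and motion-like nuisance
#' series mixed in.
#'
#' @param config a [cohort_config].
#' @param z_s numeric, the subject's trait Fisher-z per effect region.
#' @param seed integer substream seed for this subject.
#' @return list with `runs` (list of `ts_matrix` over the data mask) and
#'   `confounds` (list of per-run data frames: drift, task, motion_*).
#' @export
simulate_subject <- function(config, z_s, seed) {
  with_seed(seed, {
    grid <- config$grid
    data_mask <- mask_union(config$analysis_mask, config$seed_region)
    sigma_vox <- fwhm_to_sigma_vox(config$spatial_fwhm, grid$voxel_size)
    w <- subject_couplings(config, z_s, seed_noise_cfac(config))
    seed_cols <- match(config$seed_region$linear, data_mask$linear)
    effect_cols <- lapply(config$effect_regions, function(er)
      match(er$mask$linear, data_mask$linear))
    nt <- config$volumes_per_run
    runs <- vector("list", config$n_runs)
    confounds <- vector("list", config$n_runs)
    task <- task_regressor(nt, config$tr)
    drift <- seq_len(nt) / nt - 0.5
    for (r in seq_len(config$n_runs)) {
      g <- rnorm(nt)
      noise <- matrix(0, nt, data_mask$n_voxels)
      for (t in seq_len(nt)) {
        field <- smooth_unit_noise(grid$shape, sigma_vox)
        noise[t, ] <- field[data_mask$linear]
      }
      dat <- config$noise_sd * noise
      dat[, seed_cols] <- dat[, seed_cols] + g
      for (i in seq_along(effect_cols))
        dat[, effect_cols[[i]]] <- dat[, effect_cols[[i]]] + w[i] * g
      conf <- data.frame(drift = drift, task = task)
      dat <- dat + config$drift_amplitude * drift +
        config$task_amplitude * task
      if (config$n_motion_regressors > 0) {
        for (m in seq_len(config$n_motion_regressors)) {
          mo <- cumsum(rnorm(nt))
          mo <- (mo - mean(mo)) / sd(mo)
          conf[[paste0("motion_", m)]] <- mo
          wts <- rnorm(data_mask$n_voxels, 0, 0.3)
          dat <- dat + outer(mo, wts)
        }
      }
      runs[[r]] <- ts_matrix(dat, data_mask, config$tr,
                             run_id = sprintf("run-%02d", r))
      confounds[[r]] <- conf
    }
    list(runs = runs, confounds = confounds)
  })
}

task_regressor <- function(nt, tr, block_s = 20) {
  per <- max(1L, round(block_s / tr))
  on <- ((seq_len(nt) - 1L) %/% per) %% 2L
  on - mean(on)
}

mask_union <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid, "mask")
  fc_mask(unique(rbind(a$coords, b$coords)), a$grid)
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject trait connectivity `z_s ~ Normal(mu_g, sigma_g^2)` for
#' each effect region, simulates every subject's runs and confound tables,
#' and returns (or writes) the cohort together with its ground truth.
#' Deterministic: identical `(config, rng_seed)` give bit-identical output.
#'
#' @param config a [cohort_config].
#' @param out_dir if non-NULL, write NIfTI runs, TSV confound/cohort tables
#'   and a JSON ground-truth file under this directory and return file
#'   paths instead of in-memory runs.
#' @return list with `subjects` (per subject: runs + confounds, or paths),
#'   `cohort` (data frame: subject, group, covariates), and `truth`
#'   (class `synthetic_truth`: per-subject z matrix, per-group mu/sigma,
#'   effect masks, covariate table).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  group_of <- group_vector(config$groups)
  n <- length(group_of)
  nreg <- length(config$effect_regions)
  z <- with_seed(derive_seed(config$rng_seed, 0, salt = 1), {
    zz <- matrix(0, n, nreg)
    for (i in seq_len(nreg)) {
      er <- config$effect_regions[[i]]
      zz[, i] <- rnorm(n, er$mu[as.character(group_of)],
                       er$sigma[as.character(group_of)])
    }
    zz
  })
  cohort <- with_seed(derive_seed(config$rng_seed, 0, salt = 2),
                      draw_covariates(config, group_of, rowMeans(z)))
  subjects <- vector("list", n)
  names(subjects) <- cohort$subject
  for (s in seq_len(n)) {
    sim <- simulate_subject(config, z[s, ],
                            seed = derive_seed(config$rng_seed, s, salt = 3))
    subjects[[s]] <- sim
  }
  truth <- structure(list(
    z = structure(z, dimnames = list(cohort$subject, NULL)),
    mu = lapply(config$effect_regions, `[[`, "mu"),
    sigma = lapply(config$effect_regions, `[[`, "sigma"),
    effect_masks = lapply(config$effect_regions, `[[`, "mask"),
    covariates = cohort), class = "synthetic_truth")
  res <- list(subjects = subjects, cohort = cohort, truth = truth)
  if (!is.null(out_dir)) res <- write_cohort(res, config, out_dir)
  res
}

write_cohort <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (s in names(res$subjects)) {
    sdir <- file.path(out_dir, s)
    dir.create(sdir, showWarnings = FALSE)
    runs <- res$subjects[[s]]$runs
    confs <- res$subjects[[s]]$confounds
    paths[[s]] <- lapply(seq_along(runs), function(r) {
      nii <- file.path(sdir, sprintf("%s_%s_bold.nii.gz", s, runs[[r]]$run_id))
      tsv <- file.path(sdir, sprintf("%s_%s_confounds.tsv", s, runs[[r]]$run_id))
      write_volume4d(runs[[r]], nii)
      write.table(confs[[r]], tsv, sep = "\t", row.names = FALSE,
                  quote = FALSE)
      list(bold = nii, confounds = tsv)
    })
  }
  write.table(res$cohort, file.path(out_dir, "cohort.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(z = res$truth$z, mu = res$truth$mu,
                            sigma = res$truth$sigma),
                       file.path(out_dir, "truth.json"), digits = NA)
  write_stat_map(rep(1, config$seed_region$n_voxels), config$seed_region,
                 file.path(out_dir, "seed.nii.gz"))
  write_stat_map(rep(1, config$analysis_mask$n_voxels), config$analysis_mask,
                 file.path(out_dir, "gm.nii.gz"))
  res$paths <- paths
  res$out_dir <- out_dir
  res
}

#' Simulate per-subject Fisher-z FC maps directly
#'
#' Map-level counterpart of [generate_cohort()]: each subject's seed-FC map
#' is a spatially smooth subject field (equal across-subject SD in every
#' group — the null background) plus, inside each effect region, the
#' subject's trait `z_s ~ Normal(mu_g, sigma_g^2)` and a small smooth
#' measurement-noise field. Group differences in `sigma_g` are the planted
#' variance signal.
#'
#' @param groups named integer vector of group sizes.
#' @param grid a [voxel_grid].
#' @param effect_regions list of `list(mask =, mu =, sigma =)` as in
#'   [cohort_config()].
#' @param background_sd across-subject SD of the null background field
#'   (Fisher-z units; equal across groups).
#' @param map_noise_sd SD of per-subject measurement noise (the residual
#'   FC estimation error at ~30 min of data).
#' @param fwhm_mm spatial smoothness of both fields.
#' @param covariate_spec as in [cohort_config()].
#' @param rng_seed integer seed.
#' @return list with `fc` (subject x voxel Fisher-z matrix), `mask`
#'   (whole-grid analysis mask), `design` (a [group_design]), `cohort`
#'   (covariate table) and `truth`.
#' @export
simulate_fc_cohort <- function(groups = c(deaf = 39, hearing = 33),
                               grid = voxel_grid(c(24, 24, 24), c(2, 2, 2)),
                               effect_regions = default_effect_regions(grid, names(groups)),
                               background_sd = 0.2, map_noise_sd = 0.04,
                               fwhm_mm = 6,
                               covariate_spec = default_covariates(names(groups)),
                               rng_seed = 1L) {
  stopifnot(all(groups >= 1), background_sd >= 0, map_noise_sd >= 0)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  group_of <- group_vector(groups)
  n <- length(group_of)
  mask <- box_mask(grid, c(1, 1, 1), grid$shape)
  sigma_vox <- fwhm_to_sigma_vox(fwhm_mm, grid$voxel_size)
  nreg <- length(effect_regions)
  z <- with_seed(derive_seed(rng_seed, 0, salt = 1), {
    zz <- matrix(0, n, nreg)
    for (i in seq_len(nreg)) {
      er <- effect_regions[[i]]
      zz[, i] <- rnorm(n, er$mu[as.character(group_of)],
                       er$sigma[as.character(group_of)])
    }
    zz
  })
  cfg <- list(covariate_spec = covariate_spec)
  cohort <- with_seed(derive_seed(rng_seed, 0, salt = 2),
                      draw_covariates(cfg, group_of,
                                      if (nreg) rowMeans(z) else rep(0, n)))
  fc <- matrix(0, n, mask$n_voxels)
  for (s in seq_len(n)) {
    fc[s, ] <- with_seed(derive_seed(rng_seed, s, salt = 3), {
      bg <- background_sd * smooth_unit_noise(grid$shape, sigma_vox)
      me <- map_noise_sd * smooth_unit_noise(grid$shape, sigma_vox)
      map <- bg
      for (i in seq_len(nreg)) {
        lin <- effect_regions[[i]]$mask$linear
        map[lin] <- z[s, i]
      }
      (map + me)[mask$linear]
    })
  }
  rownames(fc) <- cohort$subject
  covs <- as.matrix(cohort[, setdiff(names(cohort), c("subject", "group")),
                           drop = FALSE])
  design <- group_design(cohort$subject, group_of, covs)
  truth <- structure(list(
    z = z, mu = lapply(effect_regions, `[[`, "mu"),
    sigma = lapply(effect_regions, `[[`, "sigma"),
    effect_masks = lapply(effect_regions, `[[`, "mask"),
    covariates = cohort), class = "synthetic_truth")
  list(fc = fc, mask = mask, design = design, cohort = cohort, truth = truth)
}
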