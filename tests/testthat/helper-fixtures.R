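# Shared fixtures: tiny grids, masks and toy volumes built in code.

tiny_grid <- function(shape = c(6, 6, 6), voxel = c(2, 2, 2)) {
  voxel_grid(shape, voxel)
}

full_mask <- function(grid) box_mask(grid, c(1, 1, 1), grid$shape)

# write a 4-D array as NIfTI on `grid`, return the path
write_toy_4d <- function(arr, grid, path = tempfile(fileext = ".nii.gz")) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(grid$voxel_size, 1)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  path
}

write_toy_mask <- function(arr, grid, path = tempfile(fileext = ".nii.gz")) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  path
}

# a two-group white-noise cohort config on a small grid, no spatial
# smoothing (the regime where the coupling closed form is exact)
white_cohort_config <- function(n_per_group = c(g1 = 5, g2 = 5), mu = 0.5,
                                sigma = 0, volumes = 400, n_runs = 1,
                                rng_seed = 1) {
  grid <- voxel_grid(c(8, 8, 8), c(2, 2, 2))
  seed_m <- box_mask(grid, c(2, 3, 3), c(4, 5, 5))
  eff <- box_mask(grid, c(6, 6, 6), c(7, 7, 7))
  gn <- names(n_per_group)
  cohort_config(
    groups = n_per_group, n_runs = n_runs, volumes_per_run = volumes,
    grid = grid, seed_region = seed_m,
    effect_regions = list(list(mask = eff,
                               mu = stats::setNames(rep(mu, length(gn)), gn),
                               sigma = stats::setNames(rep(sigma, length(gn)), gn))),
    spatial_fwhm = 0, rng_seed = rng_seed)
}

effect_columns <- function(config) {
  match(config$effect_regions[[1]]$mask$linear, config$analysis_mask$linear)
}

dice_coefficient <- function(idx_a, idx_b) {
  2 * length(intersect(idx_a, idx_b)) / (length(idx_a) + length(idx_b))
}
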