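# Simulate the synthetic study data.
#
# Two artifacts: (a) a small full BOLD cohort (NIfTI runs + TSV confound
# tables) that exercises the file-level denoising path, and (b) the
# map-level study replica (per-subject Fisher-z seed-FC maps at the study's
# group sizes) that the variance and group analyses consume.

source("analysis/00_common.R")

## (a) time-series cohort written to disk ------------------------------------
ts_dir <- file.path(res_dir, "cohort_ts")
grid <- voxel_grid(c(10, 10, 10), c(2, 2, 2))
cfg <- cohort_config(
  groups = c(deaf = 6, hearing = 6), n_runs = 2, volumes_per_run = 150,
  grid = grid,
  seed_region = box_mask(grid, c(2, 4, 4), c(4, 6, 6)),
  effect_regions = list(list(mask = box_mask(grid, c(7, 7, 7), c(9, 9, 9)),
                             mu = c(deaf = 0.2, hearing = 0.5),
                             sigma = c(deaf = 0.4, hearing = 0.2))),
  spatial_fwhm = 6, rng_seed = study_seed)
coh <- generate_cohort(cfg, out_dir = ts_dir)
message(sprintf("wrote %d subjects x %d runs under %s",
                nrow(coh$cohort), cfg$n_runs, ts_dir))

## (b) map-level study replica ------------------------------------------------
co <- load_study_cohort()
fc_tab <- data.frame(subject = co$cohort$subject, co$fc, check.names = FALSE)
save_table(fc_tab, "fc_maps.tsv")
save_table(co$cohort, "cohort.tsv")
truth_z <- data.frame(subject = co$cohort$subject, co$truth$z)
save_table(truth_z, "truth_z.tsv")
message(sprintf("map replica: %d subjects, %d voxels, %d planted regions",
                nrow(co$fc), ncol(co$fc), length(co$truth$effect_masks)))
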