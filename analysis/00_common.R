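# Shared setup for the analysis scripts: output locations, the synthetic
# study configuration, and the global seed. Every script can be run on its
# own from the repository root (`Rscript analysis/03_variance_maps.R`);
# later scripts regenerate upstream results deterministically if the files
# they need are missing.

suppressPackageStartupMessages(library(fcvar))

res_dir <- "results"
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

study_seed <- 20240901L

# map-level study replica: three groups as in the cohort the package
# emulates (16 native-signing deaf, 23 delayed-signing deaf, 33 hearing),
# 24^3 grid of 2 mm voxels, 6 mm smoothness
study_grid <- voxel_grid(c(24, 24, 24), c(2, 2, 2))
study_groups <- c(deaf_native = 16, deaf_delayed = 23, hearing = 33)

load_study_cohort <- function() {
  simulate_fc_cohort(groups = study_groups, grid = study_grid,
                     rng_seed = study_seed)
}

# deaf (pooled native + delayed) vs hearing design with the study's
# nuisance covariates (age, task accuracy, reaction time)
pooled_design <- function(co) {
  pooled <- ifelse(grepl("hearing", co$cohort$group), "hearing", "deaf")
  covs <- as.matrix(co$cohort[, c("age", "accuracy", "rt")])
  group_design(co$cohort$subject, factor(pooled, c("deaf", "hearing")), covs)
}

save_table <- function(x, name) {
  path <- file.path(res_dir, name)
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", path)
  invisible(path)
}
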