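# Cluster-extent correction of the variance map and the variability-ratio
# map inside the surviving clusters.
#
# Smoothness is estimated from the group-median-centered FC residuals, the
# cluster-size threshold from 1000 Monte-Carlo smooth-noise simulations at
# voxel p < 0.05 (two-tailed) and corrected alpha 0.05, and the deaf /
# hearing SD ratio is reported for every vetted voxel.

source("analysis/00_common.R")
if (!file.exists(file.path(res_dir, "varmap_state.rds")))
  source("analysis/03_variance_maps.R")

co <- load_study_cohort()
st <- readRDS(file.path(res_dir, "varmap_state.rds"))

centered <- fcvar:::center_by_group(st$resid_fc, st$design$group_labels)
sm <- estimate_fwhm(centered, co$mask, source = "group-centered FC residuals")
message(sprintf("estimated smoothness: %.2f mm (per-axis %s)",
                sm$fwhm_iso, paste(round(sm$fwhm, 2), collapse = "/")))

thr <- monte_carlo_cluster_threshold(co$mask, sm, voxel_p = 0.05,
                                     corrected_alpha = 0.05,
                                     n_iterations = 1000,
                                     rng_seed = study_seed + 1L)
message(sprintf("Monte-Carlo cluster-extent threshold: %d voxels", thr))

cl <- label_clusters(st$bf, voxel_p = 0.05, size_threshold = thr,
                     corrected_alpha = 0.05)
save_table(cl$clusters, "bf_clusters.tsv")
write_stat_map(cl$labels, co$mask, file.path(res_dir, "bf_clusters.nii.gz"))

vet <- which(cl$labels > 0)
if (length(vet)) {
  rmap <- variability_ratio_map(st$resid_fc, st$design$group_labels,
                                "deaf", "hearing", restrict = vet)
  write_stat_map(ifelse(is.na(rmap$ratio), 0, rmap$ratio), co$mask,
                 file.path(res_dir, "variability_ratio.nii.gz"))
  message(sprintf("%d vetted voxels in %d cluster(s); median deaf/hearing SD ratio %.2f",
                  length(vet), nrow(cl$clusters),
                  median(rmap$ratio[vet], na.rm = TRUE)))
  qs <- quantile(rmap$ratio[vet], c(0.1, 0.5, 0.9), na.rm = TRUE)
  save_table(data.frame(quantile = names(qs), ratio = round(unname(qs), 3)),
             "variability_ratio_summary.tsv")
} else {
  message("no cluster survived the extent threshold")
}
saveRDS(list(smoothness = sm, threshold = thr, clusters = cl),
        file.path(res_dir, "cluster_state.rds"))
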