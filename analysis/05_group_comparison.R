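# Group-mean comparison of seed FC: covariate-adjusted ANOVA F map (deaf
# vs hearing) plus the post hoc t map giving the direction of
# reorganization, both cluster-vetted with the same extent machinery.

source("analysis/00_common.R")
if (!file.exists(file.path(res_dir, "cluster_state.rds")))
  source("analysis/04_cluster_ratio.R")

co <- load_study_cohort()
st <- readRDS(file.path(res_dir, "varmap_state.rds"))
cs <- readRDS(file.path(res_dir, "cluster_state.rds"))

gm <- group_mean_map(st$resid_fc, st$design, mask = co$mask)
write_stat_map(ifelse(is.na(gm$anova$statistic), 0, gm$anova$statistic),
               co$mask, file.path(res_dir, "anova_F.nii.gz"))
write_stat_map(ifelse(is.na(gm$posthoc_t$deaf_vs_hearing$statistic), 0,
                      gm$posthoc_t$deaf_vs_hearing$statistic),
               co$mask, file.path(res_dir, "posthoc_t_deaf_vs_hearing.nii.gz"))

cl <- label_clusters(gm$anova, voxel_p = 0.05,
                     size_threshold = cs$threshold, corrected_alpha = 0.05)
save_table(cl$clusters, "anova_clusters.tsv")
message(sprintf("covariate-adjusted ANOVA df (%d, %d); %d vetted cluster(s)",
                gm$anova$df[1], gm$anova$df[2], nrow(cl$clusters)))
tvet <- gm$posthoc_t$deaf_vs_hearing$statistic[cl$labels > 0]
if (length(tvet))
  message(sprintf("post hoc t in vetted voxels: median %.2f (negative = lower FC in deaf)",
                  median(tvet, na.rm = TRUE)))
saveRDS(gm, file.path(res_dir, "groupmap_state.rds"))
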