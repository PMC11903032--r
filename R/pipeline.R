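# Orchestrates the full study replica on a synthetic cohort: simulate ->
# fc -> varmap -> cluster -> ratio -> groupdiff -> spatialcorr -> roicorr,
# from one config (R list or YAML file), with per-stage digests, stage
# caching, and a machine-readable report.

#' Default pipeline configuration
#'
#' @param out_dir output directory (stage outputs + report.json).
#' @param rng_seed global integer seed; every stochastic stage derives its
#'   own substream from it, so toggling one stage never shifts another's
#'   randomness.
#' @param ... overrides for any default field.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, rng_seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir,
    rng_seed = as.integer(rng_seed),
    stages = c("simulate", "fc", "varmap", "cluster", "ratio", "groupdiff",
               "spatialcorr", "roicorr"),
    simulate = list(kind = "timeseries"),   # or "maps"
    grid_shape = c(16, 16, 16), voxel_size = c(2, 2, 2),
    groups = c(deaf = 12, hearing = 12),
    n_runs = 2, volumes_per_run = 90, tr = 2,
    band = c(0.01, 0.1),
    covariates = c("age", "accuracy", "rt"),
    contrast = c("deaf", "hearing"),
    voxel_p = 0.05, corrected_alpha = 0.05, connectivity = 6,
    mc_iterations = 500, perm_iterations = 1000,
    spatial_fwhm = 6)
  over <- list(...)
  cfg[names(over)] <- over
  # YAML-friendly: flatten list-valued scalar-vector fields
  for (f in c("stages", "grid_shape", "voxel_size", "groups", "band",
              "covariates", "contrast"))
    cfg[[f]] <- unlist(cfg[[f]])
  structure(cfg, class = "pipeline_config")
}

read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  args$out_dir <- raw$out_dir %||% dirname(path)
  do.call(pipeline_config, c(list(out_dir = args$out_dir,
                                  rng_seed = args$rng_seed %||% 1L),
                             raw[setdiff(names(raw), c("out_dir", "rng_seed"))]))
}

digest_bytes <- function(raw) {
  tf <- tempfile()
  writeBin(raw, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

file_digest <- function(path) unname(tools::md5sum(path))

cache_stage <- function(state, name, params, compute) {
  dir.create(state$cache_dir, recursive = TRUE, showWarnings = FALSE)
  # each key folds in the upstream stage's key, so a parameter change
  # upstream invalidates every dependent stage's cache
  key <- digest_bytes(serialize(list(name = name, params = params,
                                     upstream = state$chain), NULL,
                                version = 2))
  state$chain <- key
  rds <- file.path(state$cache_dir, paste0(name, ".rds"))
  keyf <- file.path(state$cache_dir, paste0(name, ".key"))
  if (file.exists(rds) && file.exists(keyf) &&
      identical(readLines(keyf, warn = FALSE), key)) {
    state$log(sprintf("stage %-11s cached (key %s)", name, substr(key, 1, 8)))
    return(readRDS(rds))
  }
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(compute(),
                    error = function(e) stop(sprintf("stage '%s' failed: %s",
                                                     name, conditionMessage(e)),
                                             call. = FALSE))
  saveRDS(value, rds, version = 2)
  writeLines(key, keyf)
  state$log(sprintf("stage %-11s done in %.1fs (key %s)", name,
                    proc.time()[["elapsed"]] - t0, substr(key, 1, 8)))
  value
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic cohort
#' and writes per-stage outputs plus `report.json` under the config's
#' `out_dir`. Identical config + seed produce identical outputs; stage
#' results are cached by a digest of their parameters and reused on rerun.
#'
#' @param config a `pipeline_config` (or a path to a YAML file with the
#'   same fields).
#' @param quiet suppress per-stage log lines.
#' @return The run report (list), invisibly written as
#'   `<out_dir>/report.json`: per-stage parameters and output digests plus
#'   headline numbers (cluster count and sizes, variability-ratio summary,
#'   spatial r and p).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "pipeline.log")
  state <- new.env()
  state$cache_dir <- file.path(config$out_dir, "cache")
  state$chain <- "root"
  state$log <- function(msg) {
    line <- sprintf("[%s] %s", "fcvar", msg)
    if (!quiet) message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  grid <- voxel_grid(config$grid_shape, config$voxel_size)
  report <- list(config = config[setdiff(names(config), "out_dir")],
                 stages = list(), headline = list())
  on <- function(s) s %in% config$stages

  sim <- NULL
  if (on("simulate")) {
    params <- config[c("simulate", "grid_shape", "voxel_size", "groups",
                       "n_runs", "volumes_per_run", "tr", "spatial_fwhm",
                       "rng_seed")]
    sim <- cache_stage(state, "simulate", params, function() {
      if (identical(config$simulate$kind, "maps")) {
        simulate_fc_cohort(groups = config$groups, grid = grid,
                           fwhm_mm = config$spatial_fwhm,
                           rng_seed = derive_seed(config$rng_seed, 1, salt = 11))
      } else {
        cc <- cohort_config(groups = config$groups, n_runs = config$n_runs,
                            volumes_per_run = config$volumes_per_run,
                            tr = config$tr, grid = grid,
                            spatial_fwhm = config$spatial_fwhm,
                            rng_seed = derive_seed(config$rng_seed, 1, salt = 11))
        out <- generate_cohort(cc)
        out$config <- cc
        out
      }
    })
    write.table(sim$cohort, file.path(config$out_dir, "cohort.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    report$stages$simulate <- list(n_subjects = nrow(sim$cohort),
                                   kind = config$simulate$kind)
  }
  if (!length(intersect(config$stages,
                        c("fc", "varmap", "cluster", "ratio", "groupdiff",
                          "spatialcorr", "roicorr")))) {
    report$headline$analysis_stages <- 0L
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  if (is.null(sim)) stop("analysis stages need the simulate stage (or data)",
                         call. = FALSE)

  # fc: subject x voxel Fisher-z matrix + analysis mask
  if (identical(config$simulate$kind, "maps")) {
    fc <- sim$fc
    mask <- sim$mask
  } else {
    fc <- cache_stage(state, "fc", list(config$band, config$rng_seed),
                      function() cohort_fc_matrix(sim$subjects,
                                                  sim$config$seed_region,
                                                  sim$config$analysis_mask,
                                                  band = config$band))
    mask <- sim$config$analysis_mask
  }
  covs <- as.matrix(sim$cohort[, intersect(config$covariates,
                                           names(sim$cohort)), drop = FALSE])
  design <- group_design(sim$cohort$subject, sim$cohort$group,
                         if (ncol(covs)) covs else NULL)

  bf <- resid_fc <- NULL
  if (on("varmap")) {
    varres <- cache_stage(state, "varmap", list(config$covariates), function() {
      resid_fc <- residualize(fc, design)
      bf <- brown_forsythe_map(resid_fc, design$group_labels, mask = mask)
      list(resid_fc = resid_fc, bf = bf)
    })
    resid_fc <- varres$resid_fc
    bf <- varres$bf
    write_stat_map(bf$statistic, mask, file.path(config$out_dir, "bf_F.nii.gz"))
    write_stat_map(bf$p, mask, file.path(config$out_dir, "bf_p.nii.gz"),
                   background = 1)
    report$stages$varmap <- list(df = bf$df, min_p = min(bf$p))
  }

  clusters <- NULL
  if (on("cluster")) {
    if (is.null(bf)) stop("cluster stage needs varmap", call. = FALSE)
    clus <- cache_stage(state, "cluster",
                        list(config$voxel_p, config$corrected_alpha,
                             config$connectivity, config$mc_iterations),
                        function() {
      centered <- center_by_group(resid_fc, design$group_labels)
      sm <- estimate_fwhm(centered, mask, source = "group-centered FC residuals")
      thr <- monte_carlo_cluster_threshold(mask, sm, config$voxel_p,
                                           config$corrected_alpha,
                                           config$mc_iterations,
                                           config$connectivity,
                                           rng_seed = derive_seed(config$rng_seed, 2, salt = 12))
      cl <- label_clusters(bf, config$voxel_p, thr, config$connectivity,
                           corrected_alpha = config$corrected_alpha)
      list(smoothness = sm, threshold = as.integer(thr), clusters = cl)
    })
    clusters <- clus$clusters
    write.table(clusters$clusters, file.path(config$out_dir, "bf_clusters.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    report$stages$cluster <- list(fwhm = clus$smoothness$fwhm,
                                  size_threshold = clus$threshold,
                                  n_clusters = nrow(clusters$clusters),
                                  sizes = clusters$clusters$size)
    report$headline$n_variability_clusters <- nrow(clusters$clusters)
    report$headline$cluster_sizes <- clusters$clusters$size
  }

  if (on("ratio")) {
    if (is.null(clusters)) stop("ratio stage needs cluster", call. = FALSE)
    vetted <- which(clusters$labels > 0)
    if (length(vetted)) {
      rm_ <- variability_ratio_map(resid_fc, design$group_labels,
                                   config$contrast[1], config$contrast[2],
                                   restrict = vetted)
      write_stat_map(ifelse(is.na(rm_$ratio), 0, rm_$ratio), mask,
                     file.path(config$out_dir, "variability_ratio.nii.gz"))
      med <- median(rm_$ratio[vetted], na.rm = TRUE)
      report$stages$ratio <- list(n_voxels = length(vetted), median = med)
      report$headline$median_variability_ratio <- med
    } else {
      report$stages$ratio <- list(n_voxels = 0L)
    }
  }

  gm <- NULL
  if (on("groupdiff")) {
    gm <- cache_stage(state, "groupdiff", list(config$covariates),
                      function() group_mean_map(resid_fc %||% residualize(fc, design),
                                                design, mask = mask))
    write_stat_map(gm$anova$statistic, mask,
                   file.path(config$out_dir, "anova_F.nii.gz"))
    report$stages$groupdiff <- list(df = gm$anova$df,
                                    pairs = names(gm$posthoc_t))
  }

  if (on("spatialcorr")) {
    if (is.null(bf) || is.null(gm))
      stop("spatialcorr needs varmap and groupdiff", call. = FALSE)
    pr <- cache_stage(state, "spatialcorr", list(config$perm_iterations),
                      function() {
      centered <- center_by_group(resid_fc, design$group_labels)
      sm <- estimate_fwhm(centered, mask, source = "group-centered FC residuals")
      spatial_permutation_test(bf$statistic, gm$anova$statistic, mask, sm,
                               n_iterations = config$perm_iterations,
                               rng_seed = derive_seed(config$rng_seed, 3, salt = 13))
    })
    res <- list(r = pr$r_observed, p_smoothed = pr$p_smoothed,
                p_unsmoothed = pr$p_unsmoothed,
                n_iterations = pr$n_iterations)
    jsonlite::write_json(res, file.path(config$out_dir, "spatial_corr.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$stages$spatialcorr <- res
    report$headline$spatial_r <- pr$r_observed
    report$headline$spatial_p <- pr$p_smoothed
  }

  if (on("roicorr")) {
    if (is.null(clusters)) stop("roicorr needs cluster", call. = FALSE)
    if (nrow(clusters$clusters)) {
      rois <- extract_rois(clusters)
      fac_names <- setdiff(names(sim$cohort), c("subject", "group",
                                                config$covariates))
      if (!length(fac_names)) fac_names <- intersect(config$covariates,
                                                     names(sim$cohort))
      tabres <- roi_factor_correlation(resid_fc, rois, mask,
                                       sim$cohort[, fac_names, drop = FALSE],
                                       covariates = NULL)
      write.table(tabres$table, file.path(config$out_dir, "roi_factor.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      report$stages$roicorr <- list(n_rois = length(rois$rois),
                                    n_tests = nrow(tabres$table),
                                    min_q = suppressWarnings(min(tabres$table$q,
                                                                 na.rm = TRUE)))
    } else {
      report$stages$roicorr <- list(n_rois = 0L)
    }
  }

  outs <- list.files(config$out_dir, pattern = "\\.(tsv|json|nii|nii\\.gz)$",
                     full.names = TRUE)
  outs <- setdiff(outs, file.path(config$out_dir, "report.json"))
  report$output_digests <- stats::setNames(lapply(outs, file_digest),
                                           basename(outs))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
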