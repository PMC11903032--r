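# Group mean comparison of FC maps (one-way ANOVA + post hoc t) and
# correlation of FC with continuous subject factors at the whole-brain and
# ROI level.

#' Voxel-wise group mean comparison
#'
#' Per voxel, the group effect is tested by the partial F for the group
#' factor in the joint model `fc ~ group + centered covariates`
#' (df (k - 1, N - k - q)); without covariates this is exactly the one-way
#' ANOVA F. Post hoc maps carry the model-based t for each group pair
#' (sign convention: first minus second group). Testing group jointly with
#' the covariates, rather than on pre-residualized values with unadjusted
#' df, keeps the null F calibrated when covariates are group-separated
#' (e.g. task accuracy differing between groups). Because residualized and
#' raw FC differ only within the covariate span, the maps are identical
#' for either input; with two groups, F equals t^2 at every voxel.
#'
#' @param fc subject x voxel matrix of Fisher-z FC (raw or residualized).
#' @param design a [group_design]; its covariates enter the model.
#' @param mask optional [fc_mask] attached to the maps.
#' @param welch use Welch (unpooled) t for the post hoc maps; only
#'   available without covariates.
#' @return list with `anova` (a [stat_map], kind "anova") and `posthoc_t`
#'   (named list of [stat_map]s, kind "t", one per group pair).
#' @export
group_mean_map <- function(fc, design, mask = NULL, welch = FALSE) {
  stopifnot(inherits(design, "group_design"))
  groups <- design$group_labels
  k <- nlevels(groups)
  n <- nrow(fc)
  C <- design$covariates
  if (!is.null(C)) C <- sweep(as.matrix(C), 2, colMeans(as.matrix(C)))
  q <- if (is.null(C)) 0L else ncol(C)
  if (welch && q > 0)
    stop("Welch post hoc t is only available without covariates", call. = FALSE)
  G <- stats::model.matrix(~ 0 + groups)
  Xf <- if (q) cbind(G, C) else G
  Xr <- if (q) cbind(rep(1, n), C) else matrix(1, n, 1)
  qf <- qr(Xf)
  sse_f <- colSums(qr.resid(qf, fc)^2)
  sse_r <- colSums(qr.resid(qr(Xr), fc)^2)
  df <- c(k - 1L, n - qf$rank)
  fstat <- ((sse_r - sse_f) / df[1]) / (sse_f / df[2])
  degen <- sse_f <= 0
  p <- pf(fstat, df[1], df[2], lower.tail = FALSE)
  fstat[degen] <- NA_real_
  p[degen] <- 1
  anova_map <- stat_map(fstat, p, df, "anova", mask = mask, degenerate = degen)
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  posthoc <- lapply(pairs, function(pr) {
    rows <- groups %in% pr
    pair_t_cols(fc[rows, , drop = FALSE],
                droplevels(groups[rows]) == pr[1],
                if (q) C[rows, , drop = FALSE] else NULL,
                welch = welch, mask = mask)
  })
  names(posthoc) <- vapply(pairs, paste, "", collapse = "_vs_")
  list(anova = anova_map, posthoc_t = posthoc)
}

# model-based two-group t (first minus second), optionally adjusting for
# covariates; reduces to the pooled two-sample t without them
pair_t_cols <- function(y, is_first, C, welch = FALSE, mask = NULL) {
  n <- nrow(y)
  if (welch) {
    x1 <- y[is_first, , drop = FALSE]; x2 <- y[!is_first, , drop = FALSE]
    n1 <- nrow(x1); n2 <- nrow(x2)
    v1 <- col_vars(x1); v2 <- col_vars(x2)
    se2 <- v1 / n1 + v2 / n2
    df_v <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tstat <- (colMeans(x1) - colMeans(x2)) / sqrt(se2)
    p <- 2 * pt(abs(tstat), df_v, lower.tail = FALSE)
    degen <- !is.finite(tstat)
    tstat[degen] <- NA_real_
    p[degen] <- 1
    return(stat_map(tstat, p, c(Welch = NA), "t", mask = mask,
                    degenerate = degen))
  }
  Xr <- if (is.null(C)) matrix(1, n, 1) else cbind(rep(1, n), C)
  qn <- qr(Xr)
  d_res <- qr.resid(qn, as.numeric(is_first))
  y_res <- qr.resid(qn, y)
  d2 <- sum(d_res^2)
  beta <- as.vector(crossprod(y_res, d_res)) / d2
  df2 <- n - qn$rank - 1L
  rss <- colSums(y_res^2) - beta^2 * d2
  s2 <- pmax(rss, 0) / df2
  tstat <- beta / sqrt(s2 / d2)
  p <- 2 * pt(abs(tstat), df2, lower.tail = FALSE)
  degen <- !is.finite(tstat)
  tstat[degen] <- NA_real_
  p[degen] <- 1
  stat_map(tstat, p, df2, "t", mask = mask, degenerate = degen)
}

#' Voxel-wise correlation of FC with a subject factor
#'
#' Pearson correlation per voxel between covariate-residualized FC and the
#' (covariate-residualized) factor, with p from the t transform at
#' df = n - 2 - q, where q is the number of covariates partialled out.
#' Subjects with a missing factor value are dropped listwise.
#'
#' @param fc subject x voxel matrix.
#' @param factor_values per-subject numeric (NAs dropped listwise).
#' @param covariates optional subject x covariate matrix to partial out of
#'   both sides.
#' @param mask optional [fc_mask].
#' @return A [stat_map] of kind "r" (statistic = correlation), with an
#'   `n_used` attribute-style field in `df`.
#' @export
factor_correlation_map <- function(fc, factor_values, covariates = NULL,
                                   mask = NULL) {
  keep <- !is.na(factor_values)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  n <- sum(keep)
  if (n < 5) stop("need at least 5 non-missing subjects", call. = FALSE)
  y <- fc[keep, , drop = FALSE]
  fv <- factor_values[keep]
  if (sd(fv) == 0) stop("constant factor", call. = FALSE)
  q <- 0L
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    C <- sweep(as.matrix(covariates)[keep, , drop = FALSE], 2,
               colMeans(as.matrix(covariates)[keep, , drop = FALSE]))
    qc <- qr(cbind(1, C))
    y <- qr.resid(qc, y)
    fv <- qr.resid(qc, fv)
    q <- qc$rank - 1L
  }
  fv_c <- fv - mean(fv)
  y_c <- sweep(y, 2, colMeans(y))
  r <- as.vector(crossprod(y_c, fv_c)) /
    (sqrt(colSums(y_c^2)) * sqrt(sum(fv_c^2)))
  degen <- !is.finite(r)
  r[degen] <- NA_real_
  df <- n - 2L - q
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[degen] <- 1
  stat_map(r, p, c(df = df, n = n), "r", mask = mask, degenerate = degen)
}

#' Extract ROIs from a vetted cluster set
#'
#' One ROI per retained cluster, labeled by peak coordinate and size.
#'
#' @param clusters a `cluster_set` from [label_clusters()].
#' @param min_size drop clusters smaller than this (voxels).
#' @return A `roi_set`: list of `rois` (each `list(label =, mask =)`)
#'   plus a provenance note.
#' @export
extract_rois <- function(clusters, min_size = 0) {
  stopifnot(inherits(clusters, "cluster_set"))
  tab <- clusters$clusters
  keep <- tab[tab$size >= min_size, , drop = FALSE]
  if (nrow(keep) == 0)
    warning("no clusters of at least ", min_size, " voxels")
  rois <- lapply(seq_len(nrow(keep)), function(i) {
    row <- keep[i, ]
    vox <- which(clusters$labels == row$id)
    list(label = sprintf("cluster_%02d_peak_%d_%d_%d_n%d", row$id,
                         row$peak_i, row$peak_j, row$peak_k, row$size),
         mask = fc_mask(clusters$mask$coords[vox, , drop = FALSE],
                        clusters$mask$grid))
  })
  structure(list(rois = rois,
                 source = sprintf("clusters vetted at extent >= %d (voxel p < %g)",
                                  clusters$size_threshold, clusters$voxel_p)),
            class = "roi_set")
}

#' ROI-level factor correlations with BH correction
#'
#' Per ROI, each subject's FC value is the mean over ROI voxels; the same
#' partial correlation as [factor_correlation_map()] is then computed for
#' every (ROI, factor) cell, with Benjamini-Hochberg q-values across the
#' whole ROI x factor family.
#'
#' @param fc subject x voxel matrix (on the analysis mask the ROIs were
#'   defined on).
#' @param rois a `roi_set` (masks must be subsets of `analysis_mask`).
#' @param analysis_mask the [fc_mask] the columns of `fc` live on.
#' @param factors data frame of per-subject factor values (NAs allowed;
#'   listwise per factor).
#' @param covariates optional subject x covariate matrix.
#' @return list with `table` (data frame: roi, factor, n, r, p, q, note)
#'   and `subject_values` (subject x ROI means for scatter plots).
#' @export
roi_factor_correlation <- function(fc, rois, analysis_mask, factors,
                                   covariates = NULL) {
  stopifnot(inherits(rois, "roi_set"), length(rois$rois) >= 1)
  roi_vals <- vapply(rois$rois, function(roi) {
    cols <- match(roi$mask$linear, analysis_mask$linear)
    if (anyNA(cols)) stop("ROI '", roi$label,
                          "' has voxels outside the analysis mask",
                          call. = FALSE)
    rowMeans(fc[, cols, drop = FALSE])
  }, numeric(nrow(fc)))
  colnames(roi_vals) <- vapply(rois$rois, `[[`, "", "label")
  rows <- list()
  for (roi in colnames(roi_vals)) {
    for (fac in names(factors)) {
      fv <- factors[[fac]]
      keep <- !is.na(fv)
      if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
      y <- roi_vals[keep, roi]
      x <- fv[keep]
      note <- ""
      r <- p <- NA_real_
      n <- sum(keep)
      if (n < 5) {
        note <- "fewer than 5 non-missing subjects"
      } else if (sd(y) == 0 || sd(x) == 0) {
        note <- "constant values; correlation undefined"
      } else {
        covs_k <- if (is.null(covariates)) NULL
                  else as.matrix(covariates)[keep, , drop = FALSE]
        sm <- factor_correlation_map(matrix(y, ncol = 1), x,
                                     covariates = covs_k)
        r <- sm$statistic[1]
        p <- sm$p[1]
        n <- unname(sm$df["n"])
      }
      rows[[length(rows) + 1L]] <-
        data.frame(roi = roi, factor = fac, n = n, r = r, p = p, note = note,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$q <- NA_real_
  ok <- !is.na(tab$p)
  tab$q[ok] <- p.adjust(tab$p[ok], method = "BH")
  list(table = tab[, c("roi", "factor", "n", "r", "p", "q", "note")],
       subject_values = roi_vals)
}
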