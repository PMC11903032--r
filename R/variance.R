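# Voxel-wise homogeneity-of-variance testing between groups and
# variability-ratio maps, after nuisance-covariate residualization.

#' Group design with nuisance covariates
#'
#' @param subject_ids character labels, aligned with the rows of the FC
#'   matrix.
#' @param group_labels factor (or coercible) with k >= 2 levels, each with
#'   at least 3 subjects.
#' @param covariates optional subject x covariate numeric matrix (e.g. age,
#'   task accuracy, reaction time); columns are mean-centered at fit time.
#' @return A `group_design`.
#' @export
group_design <- function(subject_ids, group_labels, covariates = NULL) {
  group_labels <- droplevels(as.factor(group_labels))
  n <- length(subject_ids)
  stopifnot(length(group_labels) == n, nlevels(group_labels) >= 2)
  if (any(table(group_labels) < 3))
    stop("every group needs at least 3 subjects", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (!all(is.finite(covariates)))
      stop("covariates must be finite", call. = FALSE)
    csd <- apply(covariates, 2, sd)
    if (any(csd == 0))
      stop("constant covariate column(s): ",
           paste(colnames(covariates)[csd == 0], collapse = ", "),
           call. = FALSE)
  }
  structure(list(subject_ids = as.character(subject_ids),
                 group_labels = group_labels, covariates = covariates),
            class = "group_design")
}

#' Remove nuisance-covariate effects from FC values
#'
#' Per voxel, fits `y ~ group intercepts + centered covariates` jointly by
#' least squares and subtracts only the covariate component, so group
#' means are retained while covariate-driven variance (e.g. an age
#' difference confounded with group) is removed. Fitting covariates jointly
#' with group intercepts prevents group differences from aliasing into the
#' covariate betas.
#'
#' @param fc subject x voxel matrix, rows aligned with
#'   `design$subject_ids`.
#' @param design a [group_design].
#' @return subject x voxel matrix of partially residualized values.
#' @export
residualize <- function(fc, design) {
  stopifnot(inherits(design, "group_design"), nrow(fc) == length(design$subject_ids))
  C <- design$covariates
  if (is.null(C) || ncol(C) == 0) return(fc)
  C <- sweep(C, 2, colMeans(C))
  G <- stats::model.matrix(~ 0 + design$group_labels)
  X <- cbind(G, C)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), sort(qrx$pivot[seq_len(qrx$rank)]))
    nm <- c(paste0("group:", levels(design$group_labels)),
            colnames(C) %||% paste0("covariate_", seq_len(ncol(C))))
    stop("rank-deficient design; collinear columns: ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, fc)
  cov_rows <- ncol(G) + seq_len(ncol(C))
  fc - C %*% beta[cov_rows, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-voxel statistic map container
#'
#' @param statistic,p per-voxel statistic and p-value vectors.
#' @param df degrees-of-freedom descriptor.
#' @param kind label ("brown-forsythe", "anova", "t", "r", ...).
#' @param mask optional [fc_mask] giving the voxels' spatial layout.
#' @param degenerate optional logical flags for voxels where the statistic
#'   is undefined (p is set to 1 there).
#' @export
stat_map <- function(statistic, p, df, kind, mask = NULL, degenerate = NULL) {
  stopifnot(length(statistic) == length(p))
  if (is.null(degenerate)) degenerate <- rep(FALSE, length(p))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  structure(list(statistic = statistic, p = p, df = df, kind = kind,
                 mask = mask, degenerate = degenerate),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s: %d voxels, df = (%s), min p = %.3g\n",
              x$kind, length(x$statistic), paste(x$df, collapse = ", "),
              suppressWarnings(min(x$p, na.rm = TRUE))))
  invisible(x)
}

#' Brown-Forsythe test (single voxel)
#'
#' Homogeneity-of-variance test: a one-way ANOVA on absolute deviations
#' from the group medians. Median-centering (rather than Levene's
#' mean-centering) keeps the test's false-positive rate near nominal under
#' skewed data.
#'
#' @param values numeric vector.
#' @param groups factor of the same length, k >= 2 levels.
#' @param center "median" (Brown-Forsythe, default) or "mean" (Levene).
#' @return list with `statistic` (F), `p`, `df = c(k - 1, N - k)`.
#' @export
brown_forsythe_test <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- length(values)
  stopifnot(k >= 2, length(groups) == n)
  ctr <- if (center == "median") tapply(values, groups, median)
         else tapply(values, groups, mean)
  d <- abs(values - ctr[groups])
  df <- c(k - 1L, n - k)
  if (all(d == 0))
    return(list(statistic = NA_real_, p = 1, df = df, degenerate = TRUE))
  fit <- stats::oneway.test(d ~ groups, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p = unname(fit$p.value), df = df,
       degenerate = FALSE)
}

#' Voxel-wise Brown-Forsythe map
#'
#' Vectorized over voxels: per voxel, absolute deviations from group
#' medians are submitted to a one-way ANOVA F with df (k - 1, N - k).
#' Voxels where every deviation is zero are flagged degenerate (p = 1).
#'
#' @param residuals subject x voxel matrix (typically
#'   covariate-[residualize()]d Fisher-z FC).
#' @param groups factor of group labels per subject.
#' @param mask optional [fc_mask] to attach to the result.
#' @param center "median" (default) or "mean" (Levene variant).
#' @return A [stat_map] of kind "brown-forsythe".
#' @export
brown_forsythe_map <- function(residuals, groups, mask = NULL,
                               center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- nrow(residuals)
  stopifnot(k >= 2, length(groups) == n)
  if (any(table(groups) < 3))
    stop("every group needs at least 3 subjects", call. = FALSE)
  d <- abs(center_by_group(residuals, groups, center))
  f <- anova_f_cols(d, groups)
  df <- c(k - 1L, n - k)
  degen <- f$ss_between == 0 & f$ss_within == 0
  stat <- f$f
  p <- pf(stat, df[1], df[2], lower.tail = FALSE)
  stat[degen] <- NA_real_
  p[degen] <- 1
  # nonzero between-group signal with exactly zero within-group spread
  p[!degen & !is.finite(f$f)] <- 0
  stat_map(stat, p, df, "brown-forsythe", mask = mask, degenerate = degen)
}

center_by_group <- function(x, groups, center = "median") {
  out <- x
  for (g in levels(groups)) {
    rows <- which(groups == g)
    ctr <- if (center == "median") col_medians(x[rows, , drop = FALSE])
           else colMeans(x[rows, , drop = FALSE])
    out[rows, ] <- sweep(x[rows, , drop = FALSE], 2, ctr)
  }
  out
}

# columnwise one-way ANOVA decomposition
anova_f_cols <- function(x, groups) {
  n <- nrow(x)
  k <- nlevels(groups)
  grand <- colMeans(x)
  ss_total <- colSums(sweep(x, 2, grand)^2)
  ss_between <- 0
  for (g in levels(groups)) {
    rows <- which(groups == g)
    mg <- colMeans(x[rows, , drop = FALSE])
    ss_between <- ss_between + length(rows) * (mg - grand)^2
  }
  ss_within <- pmax(ss_total - ss_between, 0)
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(f = f, ss_between = ss_between, ss_within = ss_within)
}

#' Group variability-ratio map
#'
#' Ratio of across-subject spread (SD by default, variance via
#' `spread = "var"`) between two groups at each voxel of a restriction
#' (typically the voxels with a significant Brown-Forsythe effect).
#'
#' @param residuals subject x voxel matrix of residualized FC.
#' @param groups factor; exactly the two groups named below are used.
#' @param numerator_group,denominator_group group labels forming the
#'   ratio numerator / denominator.
#' @param restrict logical per-voxel flags (or integer indices) selecting
#'   the voxels to report; must select at least one voxel.
#' @param spread "sd" or "var".
#' @return A `ratio_map`: list with `ratio` (NA outside the restriction or
#'   where the denominator spread is zero), `voxels` (restricted indices),
#'   `flagged` (indices excluded for zero denominator), `spread_kind`.
#' @export
variability_ratio_map <- function(residuals, groups, numerator_group,
                                  denominator_group, restrict,
                                  spread = c("sd", "var")) {
  spread <- match.arg(spread)
  groups <- as.factor(groups)
  stopifnot(numerator_group %in% levels(groups),
            denominator_group %in% levels(groups))
  if (is.logical(restrict)) restrict <- which(restrict)
  if (length(restrict) < 1) stop("restriction is empty", call. = FALSE)
  num <- residuals[groups == numerator_group, restrict, drop = FALSE]
  den <- residuals[groups == denominator_group, restrict, drop = FALSE]
  vn <- col_vars(num)
  vd <- col_vars(den)
  ratio_r <- vn / vd
  if (spread == "sd") ratio_r <- sqrt(ratio_r)
  bad <- vd == 0
  ratio_r[bad] <- NA_real_
  ratio <- rep(NA_real_, ncol(residuals))
  ratio[restrict] <- ratio_r
  structure(list(ratio = ratio, voxels = restrict,
                 flagged = restrict[bad], spread_kind = spread,
                 numerator = numerator_group, denominator = denominator_group),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  ok <- x$ratio[x$voxels]
  cat(sprintf("<ratio_map> %s(%s)/%s(%s): %d voxels, median %.3f\n",
              x$spread_kind, x$numerator, x$spread_kind, x$denominator,
              length(x$voxels), median(ok, na.rm = TRUE)))
  invisible(x)
}
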