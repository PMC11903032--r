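# Confound regression with simultaneous band-pass filtering, and seed-based
# Fisher-z connectivity maps.
#
# Band-pass filtering is realized as regression: the projection basis holds
# the confound columns together with a discrete-cosine basis spanning all
# frequencies *outside* the pass band, so one least-squares projection
# removes confounds and out-of-band fluctuations simultaneously. This
# avoids the artifact of sequential filter-then-regress, where regression
# of unfiltered confounds reintroduces out-of-band variance.

#' Build a confound + band-pass projection basis
#'
#' @param confounds data frame or matrix of per-volume confound regressors
#'   (may be NULL or zero-column for none).
#' @param n_volumes number of volumes the basis applies to.
#' @param tr repetition time in seconds.
#' @param band numeric(2), pass band in Hz: `0 <= low < high <= Nyquist`
#'   (Nyquist = `1 / (2 * tr)`). Frequencies outside `(low, high)` are
#'   represented by discrete-cosine columns and hence removed.
#' @return A `projection_basis`: list with `regressors` (time x column,
#'   full column rank; intercept first), `n_volumes`, `tr`, `band`, plus a
#'   precomputed QR factorization.
#' @export
build_projection <- function(confounds, n_volumes, tr, band = c(0.01, 0.1)) {
  nyq <- 1 / (2 * tr)
  if (!(length(band) == 2 && band[1] >= 0 && band[1] < band[2] && band[2] <= nyq + 1e-12))
    stop(sprintf("band must satisfy 0 <= low < high <= Nyquist (%.4g Hz)", nyq),
         call. = FALSE)
  X <- matrix(1, n_volumes, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(confounds) && NCOL(confounds) > 0) {
    cm <- as.matrix(confounds)
    if (nrow(cm) != n_volumes)
      stop(sprintf("confounds have %d rows but n_volumes = %d", nrow(cm),
                   n_volumes), call. = FALSE)
    if (is.null(colnames(cm))) colnames(cm) <- paste0("confound_", seq_len(ncol(cm)))
    X <- cbind(X, cm)
  }
  # DCT-II columns at f_k = k / (2 * n * tr), k = 1..n-1; keep out-of-band
  k <- seq_len(n_volumes - 1)
  freq <- k / (2 * n_volumes * tr)
  out_band <- freq <= band[1] | freq >= band[2]
  if (any(out_band)) {
    t_idx <- seq_len(n_volumes) - 0.5
    dct <- vapply(k[out_band], function(kk) cos(pi * kk * t_idx / n_volumes),
                  numeric(n_volumes))
    colnames(dct) <- sprintf("dct_%04d", k[out_band])
    X <- cbind(X, dct)
  }
  X <- drop_dependent_columns(X)
  structure(list(regressors = X, n_volumes = n_volumes, tr = tr, band = band,
                 qr = qr(X)),
            class = "projection_basis")
}

# keep the earliest maximal independent subset of columns (later
# duplicates dropped), deterministically
drop_dependent_columns <- function(X, tol = 1e-9) {
  qrx <- qr(X, tol = tol)
  if (qrx$rank == ncol(X)) return(X)
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  X[, keep, drop = FALSE]
}

#' Regress confounds and out-of-band frequencies out of a run
#'
#' Replaces each voxel series by its least-squares residual against the
#' projection basis. This is an orthogonal projection, so it is idempotent
#' and can only shrink per-voxel variance.
#'
#' @param run a `ts_matrix`.
#' @param basis a `projection_basis` built for the same number of volumes.
#' @return A denoised `ts_matrix`.
#' @export
denoise_run <- function(run, basis) {
  stopifnot(inherits(run, "ts_matrix"), inherits(basis, "projection_basis"))
  if (nrow(run$data) != basis$n_volumes)
    stop(sprintf("run has %d volumes but basis expects %d", nrow(run$data),
                 basis$n_volumes), call. = FALSE)
  res <- qr.resid(basis$qr, run$data)
  out <- run
  out$data <- res
  out
}

#' Seed-based Fisher-z connectivity map
#'
#' For each run, the seed time course is the mean of the z-scored seed-voxel
#' series; all series are standardized per run, concatenated across runs,
#' and the per-voxel Pearson correlation with the seed course is Fisher
#' transformed (`atanh`) after clamping `|r|` at `1 - 1e-7`.
#'
#' @param runs list of (denoised) `ts_matrix`, all on one data mask.
#' @param seed a [fc_mask]; must be contained in the runs' data mask.
#' @param analysis_mask a [fc_mask] of voxels to map (e.g. gray matter);
#'   must be contained in the runs' data mask.
#' @param subject_id label carried on the result.
#' @return An `fc_map`: list with `values` (Fisher z per analysis-mask
#'   voxel), `mask`, `seed`, `subject_id`, `n_volumes`, and
#'   `n_degenerate` (voxels with zero variance, mapped to z = 0).
#' @export
seed_fc_map <- function(runs, seed, analysis_mask, subject_id = "subject") {
  if (inherits(runs, "ts_matrix")) runs <- list(runs)
  stopifnot(length(runs) >= 1)
  data_mask <- runs[[1]]$mask
  for (r in runs)
    if (!identical(r$mask$linear, data_mask$linear))
      stop("all runs must share one data mask", call. = FALSE)
  seed_cols <- match(seed$linear, data_mask$linear)
  if (anyNA(seed_cols))
    stop("seed mask is not contained in the runs' data mask", call. = FALSE)
  out_cols <- match(analysis_mask$linear, data_mask$linear)
  if (anyNA(out_cols))
    stop("analysis mask is not contained in the runs' data mask", call. = FALSE)
  seed_all <- c()
  vox_all <- NULL
  n_degenerate <- 0L
  for (r in runs) {
    zs <- scale_cols(r$data[, seed_cols, drop = FALSE])
    if (any(attr(zs, "zero_var")))
      stop("zero-variance seed voxel series", call. = FALSE)
    seed_series <- rowMeans(zs)
    ssd <- sd(seed_series)
    if (!is.finite(ssd) || ssd == 0)
      stop("zero-variance seed series", call. = FALSE)
    vox <- scale_cols(r$data[, out_cols, drop = FALSE])
    n_degenerate <- n_degenerate + sum(attr(vox, "zero_var"))
    seed_all <- c(seed_all, (seed_series - mean(seed_series)) / ssd)
    vox_all <- rbind(vox_all, vox)
  }
  tt <- length(seed_all)
  sa <- seed_all - mean(seed_all)
  va <- sweep(vox_all, 2, colMeans(vox_all))
  denom <- sqrt(sum(sa^2)) * sqrt(colSums(va^2))
  r_vec <- as.vector(crossprod(va, sa)) / denom
  r_vec[!is.finite(r_vec)] <- 0
  if (n_degenerate > 0)
    warning(sprintf("%d zero-variance voxel series set to z = 0", n_degenerate))
  z <- atanh(clamp_r(r_vec))
  structure(list(values = z, mask = analysis_mask, seed = seed,
                 subject_id = subject_id, n_volumes = tt,
                 n_degenerate = n_degenerate),
            class = "fc_map")
}

# z-score columns; zero-variance columns become 0 and are flagged
scale_cols <- function(x) {
  mu <- colMeans(x)
  s <- sqrt(col_vars(x))
  zero <- !is.finite(s) | s == 0
  s[zero] <- 1
  out <- sweep(sweep(x, 2, mu), 2, s, "/")
  out[, zero] <- 0
  attr(out, "zero_var") <- zero
  out
}

#' @export
print.fc_map <- function(x, ...) {
  cat(sprintf("<fc_map> %s: %d voxels, %d volumes, mean z %.3f\n",
              x$subject_id, length(x$values), x$n_volumes, mean(x$values)))
  invisible(x)
}

#' Per-subject FC maps for a whole cohort
#'
#' Convenience driver: builds one projection basis per run from its
#' confound table, denoises, and maps seed connectivity, returning the
#' subject x voxel Fisher-z matrix the group analyses consume.
#'
#' @param subjects list as returned by [generate_cohort()] (`$subjects`):
#'   per subject a list with `runs` and `confounds`.
#' @param seed,analysis_mask masks as in [seed_fc_map()].
#' @param band pass band in Hz (see [build_projection()]).
#' @return subject x voxel matrix of Fisher-z values (rows named by
#'   subject).
#' @export
cohort_fc_matrix <- function(subjects, seed, analysis_mask,
                             band = c(0.01, 0.1)) {
  fc <- matrix(0, length(subjects), analysis_mask$n_voxels,
               dimnames = list(names(subjects), NULL))
  for (s in seq_along(subjects)) {
    runs <- subjects[[s]]$runs
    confs <- subjects[[s]]$confounds
    den <- lapply(seq_along(runs), function(r) {
      basis <- build_projection(confs[[r]], nrow(runs[[r]]$data),
                                runs[[r]]$tr, band)
      denoise_run(runs[[r]], basis)
    })
    fc[s, ] <- seed_fc_map(den, seed, analysis_mask,
                           subject_id = names(subjects)[s])$values
  }
  fc
}
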