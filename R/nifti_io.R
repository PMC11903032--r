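#' @useDynLib fcvar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median var cor pf pt pnorm qnorm
#'   p.adjust complete.cases
#' @importFrom utils write.table read.delim
NULL

grid_from_nifti <- function(img) {
  d <- dim(img)
  vox <- RNifti::pixdim(img)
  aff <- structure(as.matrix(RNifti::xform(img)), dim = c(4L, 4L))
  voxel_grid(d[1:3], vox[1:3], aff)
}

nifti_from_grid <- function(arr, grid, tr = 1) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- if (nd == 4) c(grid$voxel_size, tr) else grid$voxel_size
  aff <- structure(grid$affine, code = 2L)
  RNifti::`sform<-`(img, aff)
}

#' Load a 4-D BOLD run as a time x voxel matrix
#'
#' Reads a 4-D NIfTI-1 volume, drops the initial volumes acquired before
#' signal equilibrium, and restricts it to the in-mask voxels, producing the
#' masked time x voxel representation used throughout the package. The image
#' grid must match the mask grid exactly; the package never resamples.
#'
#' @param path path to a 4-D NIfTI-1 file (.nii or .nii.gz).
#' @param mask a [fc_mask] defining the voxels (and column order) to keep.
#' @param tr repetition time in seconds (> 0).
#' @param discard_initial number of leading volumes to drop (default 0;
#'   dummy scans at the start of each run).
#' @param run_id label carried on the returned object.
#' @return A `ts_matrix`: list with `data` (time x voxel matrix, columns in
#'   mask order), `grid`, `mask`, `tr`, `run_id`.
#' @export
load_volume4d <- function(path, mask, tr, discard_initial = 0, run_id = basename(path)) {
  stopifnot(tr > 0, discard_initial >= 0)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4-D NIfTI image: ", path, call. = FALSE)
  stop_if_grid_mismatch(grid_from_nifti(img), mask$grid, what = path)
  if (discard_initial >= d[4])
    stop(sprintf("discard_initial (%d) must be < number of volumes (%d)",
                 discard_initial, d[4]), call. = FALSE)
  nvol <- d[4]
  flat <- matrix(as.numeric(img), prod(d[1:3]), nvol)
  dat <- t(flat[mask$linear, (discard_initial + 1):nvol, drop = FALSE])
  if (!all(is.finite(dat)))
    stop("non-finite voxel values inside mask in ", path, call. = FALSE)
  ts_matrix(dat, mask, tr, run_id)
}

#' @rdname load_volume4d
#' @param data time x voxel numeric matrix (columns in mask order).
#' @export
ts_matrix <- function(data, mask, tr, run_id = "run") {
  data <- as.matrix(data)
  if (ncol(data) != mask$n_voxels)
    stop("data column count must equal mask n_voxels", call. = FALSE)
  stopifnot(tr > 0)
  structure(list(data = data, grid = mask$grid, mask = mask, tr = tr,
                 run_id = run_id),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> %s: %d volumes x %d voxels, TR %.3g s\n",
              x$run_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Load a binary mask image
#'
#' Nonzero voxels become mask members; ordering is deterministic
#' (lexicographic by coordinate). Grid mismatches are an error — no silent
#' resampling.
#'
#' @param path path to a 3-D NIfTI-1 image.
#' @param reference a [voxel_grid] the mask must live on.
#' @return A [fc_mask].
#' @export
load_mask <- function(path, reference) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("expected a 3-D mask image: ", path, call. = FALSE)
  stop_if_grid_mismatch(grid_from_nifti(img), reference, what = path)
  arr <- array(as.numeric(img), dim(img))
  arr[!is.finite(arr)] <- 0
  mask_from_array(arr, reference)
}

#' Write a per-voxel statistic map as NIfTI
#'
#' In-mask voxels carry `values`; out-of-mask voxels carry `background`
#' (0 by default; pass `background = 1` for p-value maps so thresholding
#' tools never pick up out-of-mask voxels). Data are stored as float32.
#'
#' @param values numeric of length `mask$n_voxels`.
#' @param mask a [fc_mask].
#' @param path output path (.nii or .nii.gz).
#' @param background out-of-mask fill value.
#' @export
write_stat_map <- function(values, mask, path, background = 0) {
  arr <- unmask(values, mask, background = background)
  RNifti::writeNifti(nifti_from_grid(arr, mask$grid), path, datatype = "float")
  invisible(path)
}

#' @rdname write_stat_map
#' @export
read_stat_map <- function(path, mask) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("expected a 3-D image: ", path, call. = FALSE)
  stop_if_grid_mismatch(grid_from_nifti(img), mask$grid, what = path)
  arr <- array(as.numeric(img), dim(img))
  arr[mask$linear]
}

#' @rdname load_volume4d
#' @param runs list of `ts_matrix` (one per run) to write as 4-D volumes.
#' @export
write_volume4d <- function(runs, path) {
  run <- if (inherits(runs, "ts_matrix")) runs else stop("expected a ts_matrix")
  nvol <- nrow(run$data)
  arr <- array(0, c(run$grid$shape, nvol))
  flat <- matrix(arr, prod(run$grid$shape), nvol)
  flat[run$mask$linear, ] <- t(run$data)
  arr <- array(flat, c(run$grid$shape, nvol))
  RNifti::writeNifti(nifti_from_grid(arr, run$grid, tr = run$tr), path,
                     datatype = "float")
  invisible(path)
}
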