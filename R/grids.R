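#' Voxel grid geometry
#'
#' A `voxel_grid` ties an image array to scanner space: the array shape, the
#' voxel size in mm along each axis, and a 4x4 voxel-to-world affine. All
#' images and masks entering an analysis must share one grid; the package
#' never resamples.
#'
#' @param shape integer(3), voxels per axis (each >= 1).
#' @param voxel_size numeric(3), voxel edge lengths in mm (each > 0).
#' @param affine 4x4 voxel-to-world transform; defaults to a diagonal
#'   scaling by `voxel_size` (origin at the first voxel).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size = c(2, 2, 2), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("voxel_grid affine must be invertible")
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

#' @rdname voxel_grid
#' @param a,b grids to compare.
#' @param tol numeric tolerance on voxel size and affine entries.
#' @export
grids_compatible <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) <= tol) &&
    all(abs(a$affine - b$affine) <= tol)
}

describe_grid <- function(g) {
  sprintf("[shape %s, voxel %s mm]",
          paste(g$shape, collapse = "x"),
          paste(format(g$voxel_size, digits = 4), collapse = "x"))
}

stop_if_grid_mismatch <- function(a, b, what = "image") {
  if (!grids_compatible(a, b))
    stop(sprintf("incompatible grids: %s grid %s does not match reference %s",
                 what, describe_grid(a), describe_grid(b)), call. = FALSE)
  invisible(TRUE)
}

#' Binary mask on a voxel grid
#'
#' A `fc_mask` holds the in-mask voxel coordinates of a binary image in a
#' deterministic order (lexicographic by coordinate), so that every
#' downstream time x voxel or subject x voxel matrix has a stable, platform
#' independent column order.
#'
#' @param coords integer matrix (n x 3) of 1-based voxel coordinates.
#' @param grid a [voxel_grid].
#' @return An object of class `fc_mask` with fields `grid`, `coords`
#'   (ordered n x 3 matrix), `n_voxels` and `linear` (column-major linear
#'   indices into the grid array).
#' @export
fc_mask <- function(coords, grid) {
  coords <- matrix(as.integer(coords), ncol = 3)
  if (nrow(coords) < 1L) stop("mask is empty", call. = FALSE)
  if (any(coords < 1L) || any(coords > matrix(grid$shape, nrow(coords), 3, byrow = TRUE)))
    stop("mask coordinates outside grid bounds", call. = FALSE)
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  coords <- coords[ord, , drop = FALSE]
  if (anyDuplicated(coords)) stop("mask coordinates must be unique", call. = FALSE)
  lin <- coords[, 1] + (coords[, 2] - 1L) * grid$shape[1] +
    (coords[, 3] - 1L) * grid$shape[1] * grid$shape[2]
  structure(list(grid = grid, coords = coords, n_voxels = nrow(coords),
                 linear = as.integer(lin)),
            class = "fc_mask")
}

#' @rdname fc_mask
#' @param arr 3-D array; nonzero entries become mask voxels.
#' @export
mask_from_array <- function(arr, grid) {
  stopifnot(identical(dim(arr), as.integer(grid$shape)))
  nz <- which(arr != 0)
  if (length(nz) == 0L) stop("mask is empty", call. = FALSE)
  fc_mask(arrayInd(nz, grid$shape), grid)
}

#' @export
print.fc_mask <- function(x, ...) {
  cat(sprintf("<fc_mask> %d voxels on %s grid\n", x$n_voxels,
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Embed per-voxel values into a full 3-D array
#'
#' @param values numeric of length `mask$n_voxels`.
#' @param mask a [fc_mask].
#' @param background value for out-of-mask voxels (0 for statistic maps;
#'   use 1 for p-value maps so out-of-mask voxels can never look
#'   significant).
#' @return 3-D array of the mask grid shape.
#' @export
unmask <- function(values, mask, background = 0) {
  if (length(values) != mask$n_voxels)
    stop(sprintf("expected %d values, got %d", mask$n_voxels, length(values)),
         call. = FALSE)
  arr <- array(background, mask$grid$shape)
  arr[mask$linear] <- values
  arr
}

#' Cuboid sub-mask helper
#'
#' Convenience constructor for rectangular masks (used by the synthetic
#' cohort generator and in tests).
#'
#' @param grid a [voxel_grid].
#' @param from,to integer(3) corners (inclusive, 1-based).
#' @export
box_mask <- function(grid, from, to) {
  from <- as.integer(from); to <- as.integer(to)
  stopifnot(all(from >= 1), all(to <= grid$shape), all(from <= to))
  coords <- as.matrix(expand.grid(i = from[1]:to[1], j = from[2]:to[2],
                                  k = from[3]:to[3]))
  fc_mask(coords, grid)
}
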