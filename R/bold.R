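#' BOLD run container
#'
#' A `bold_run` holds one subject/run 4D BOLD acquisition: the masked voxel
#' time series, the 3D brain mask, the voxel-index to millimetre affine, and
#' the repetition time. Internally the signal is stored as a `V x T` matrix
#' over masked voxels (column-major mask order); [bold_array()] materialises
#' the full 4D array, e.g. for NIfTI export.
#'
#' @param data either a 4D numeric array (`X x Y x Z x T`) or a `V x T`
#'   matrix of masked voxel series (rows in column-major mask order).
#' @param mask 3D logical array; at least two `TRUE` voxels.
#' @param affine invertible 4x4 matrix mapping 1-based voxel indices
#'   `(i, j, k, 1)` to mm coordinates.
#' @param tr repetition time in seconds.
#' @return An object of class `bold_run` with elements `series`, `mask`,
#'   `affine`, `tr`.
#' @export
bold_run <- function(data, mask, affine, tr) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  n_vox <- sum(mask)
  if (n_vox < 2L) stop("mask must contain at least 2 voxels")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be an invertible 4x4 matrix")
  }
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("tr must be a positive scalar")

  if (length(dim(data)) == 4L) {
    if (!all(dim(data)[1:3] == dim(mask))) stop("data and mask dimensions disagree")
    nt <- dim(data)[4L]
    series <- matrix(data[rep(mask, nt)], nrow = n_vox, ncol = nt)
  } else if (is.matrix(data)) {
    if (nrow(data) != n_vox) stop("series matrix must have one row per masked voxel")
    series <- data
  } else {
    stop("data must be a 4D array or a V x T matrix")
  }
  if (ncol(series) < 2L) stop("need at least T = 2 volumes")
  if (!all(is.finite(series))) stop("masked BOLD values must be finite")

  structure(
    list(series = series, mask = mask, affine = affine, tr = tr),
    class = "bold_run"
  )
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf(
    "<bold_run> %s grid, %d masked voxels, %d volumes, TR %.3g s\n",
    paste(dim(x$mask), collapse = "x"), nrow(x$series), ncol(x$series), x$tr
  ))
  invisible(x)
}

#' @rdname bold_run
#' @param bold a `bold_run`.
#' @export
n_volumes <- function(bold) ncol(bold$series)

#' Voxel coordinates of a mask
#'
#' Returns the 1-based array indices of masked voxels in column-major order —
#' the row order used throughout for masked series and feature maps.
#'
#' @param mask 3D logical array.
#' @return integer `V x 3` matrix.
#' @export
voxel_coords <- function(mask) {
  which(mask, arr.ind = TRUE)[, 1:3, drop = FALSE]
}

#' Millimetre coordinates of masked voxels
#'
#' @param bold a `bold_run`, or anything with `mask` + `affine` elements.
#' @return numeric `V x 3` matrix of mm coordinates (affine applied to
#'   1-based voxel indices).
#' @export
voxel_coords_mm <- function(bold) {
  ijk <- voxel_coords(bold$mask)
  xyz1 <- cbind(ijk, 1) %*% t(bold$affine)
  xyz1[, 1:3, drop = FALSE]
}

#' Materialise a 4D array from a bold_run
#'
#' Unmasked voxels are filled with `fill` (default 0).
#'
#' @param bold a `bold_run`.
#' @param fill value for voxels outside the mask.
#' @return 4D numeric array `X x Y x Z x T`.
#' @export
bold_array <- function(bold, fill = 0) {
  d <- c(dim(bold$mask), ncol(bold$series))
  out <- array(fill, dim = d)
  out[rep(bold$mask, d[4L])] <- as.vector(bold$series)
  out
}

#' Place a masked per-voxel vector into a 3D volume
#'
#' @param values numeric vector, one value per masked voxel.
#' @param mask 3D logical array with `sum(mask) == length(values)`.
#' @param fill value outside the mask.
#' @return 3D numeric array.
#' @export
unmask <- function(values, mask, fill = 0) {
  stopifnot(sum(mask) == length(values))
  vol <- array(fill, dim = dim(mask))
  vol[mask] <- values
  vol
}
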