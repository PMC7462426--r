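# Spatial containers: the voxel grid, 4D masked time-series volumes, and
# integer parcellations. Volumes store only in-mask voxel series (rows in the
# column-major order of which(mask)); out-of-mask voxels carry no data.

#' Define a 3D voxel grid
#'
#' @param dims Integer triple `(nx, ny, nz)`, all >= 1.
#' @param voxel_size Voxel edge lengths in mm (scalar recycled to 3).
#' @param origin mm coordinate of the centre of voxel `(1, 1, 1)`.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(dims, voxel_size = 2, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(voxel_size > 0))
  origin <- rep_len(as.numeric(origin), 3)
  structure(list(dims = dims, voxel_size = voxel_size, origin = origin),
            class = "volume_grid")
}

#' mm coordinates of voxel indices
#'
#' @param grid A `volume_grid`.
#' @param idx Integer matrix (n x 3) of voxel indices, or missing for every
#'   voxel of the grid in column-major (array) order.
#' @return An n x 3 numeric matrix of mm coordinates of voxel centres.
#' @export
voxel_coords <- function(grid, idx) {
  stopifnot(inherits(grid, "volume_grid"))
  if (missing(idx)) {
    idx <- arrayInd(seq_len(prod(grid$dims)), grid$dims)
  }
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, grid$voxel_size, "*"), 2, grid$origin, "+")
}

#' Construct a masked 4D volume
#'
#' @param grid A `volume_grid`.
#' @param mask Logical array over the grid marking in-brain voxels.
#' @param series Numeric matrix, one row per in-mask voxel in the column-major
#'   order of `which(mask)`, one column per time point (T >= 2).
#' @param tr Repetition time in seconds.
#' @return A `brain_volume4d` object.
#' @export
brain_volume4d <- function(grid, mask, series, tr = 2) {
  stopifnot(inherits(grid, "volume_grid"))
  mask <- array(as.logical(mask), dim = grid$dims)
  if (anyNA(mask)) stop("mask must not contain NA")
  series <- as.matrix(series)
  if (nrow(series) != sum(mask))
    stop("series must have one row per in-mask voxel (", sum(mask),
         "), got ", nrow(series))
  if (ncol(series) < 2) stop("series must have T >= 2 time points")
  stopifnot(is.numeric(tr), tr > 0)
  structure(list(grid = grid, mask = mask, series = series, tr = tr),
            class = "brain_volume4d")
}

#' @export
print.brain_volume4d <- function(x, ...) {
  cat("<brain_volume4d> grid", paste(x$grid$dims, collapse = "x"),
      "voxels of", paste(signif(x$grid$voxel_size, 3), collapse = "x"), "mm;",
      sum(x$mask), "in mask;", ncol(x$series), "time points; TR",
      x$tr, "s\n")
  invisible(x)
}

#' @keywords internal
#' @noRd
n_timepoints <- function(volume) ncol(volume$series)

#' Expand a volume's series to a full 4D array
#'
#' Out-of-mask voxels are filled with `fill`.
#' @param volume A `brain_volume4d`.
#' @param fill Value for out-of-mask voxels.
#' @return A 4D numeric array `(nx, ny, nz, T)`.
#' @export
volume_as_array <- function(volume, fill = 0) {
  stopifnot(inherits(volume, "brain_volume4d"))
  tt <- n_timepoints(volume)
  a <- array(fill, dim = c(volume$grid$dims, tt))
  flat <- matrix(a, ncol = tt)
  flat[which(volume$mask), ] <- volume$series
  array(flat, dim = c(volume$grid$dims, tt))
}

#' Build a volume from a full 4D array and a mask
#'
#' @param arr 4D numeric array `(nx, ny, nz, T)`.
#' @param grid A `volume_grid` matching the first three dims.
#' @param mask Logical array; defaults to all voxels in mask.
#' @param tr Repetition time in seconds.
#' @return A `brain_volume4d`.
#' @export
volume_from_array <- function(arr, grid, mask = NULL, tr = 2) {
  stopifnot(length(dim(arr)) == 4)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(arr)[1:3])
  stopifnot(all(dim(arr)[1:3] == grid$dims))
  flat <- matrix(arr, ncol = dim(arr)[4])
  brain_volume4d(grid, mask, flat[which(array(mask, grid$dims)), , drop = FALSE], tr)
}
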