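# ROI bookkeeping: integer-labelled parcellations, ROI mean time series,
# mm-space centroids and centroid distances, and fixed-size (7-voxel) ROIs.

#' Construct a parcellation
#'
#' @param grid A `volume_grid`.
#' @param labels Integer array over the grid; 0 = background, 1..R = ROIs.
#'   ROIs are nonoverlapping by construction (one label per voxel) and every
#'   ROI id up to `max(labels)` must own at least one voxel.
#' @param names Optional character vector of R ROI names.
#' @param system Optional character vector of R system labels (e.g. "DMN").
#' @return A `parcellation` object.
#' @export
parcellation <- function(grid, labels, names = NULL, system = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  labels <- array(as.integer(labels), dim = grid$dims)
  if (anyNA(labels) || any(labels < 0)) stop("labels must be nonnegative integers")
  r <- max(labels)
  if (r < 1) stop("parcellation must contain at least one ROI")
  present <- tabulate(labels[labels > 0], nbins = r)
  if (any(present == 0))
    stop("ROI id(s) with no voxels: ", paste(which(present == 0), collapse = ", "))
  if (!is.null(names)) stopifnot(length(names) == r)
  if (!is.null(system)) stopifnot(length(system) == r)
  structure(list(grid = grid, labels = labels, n_rois = r,
                 names = names, system = system),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation>", x$n_rois, "ROIs on a",
      paste(x$grid$dims, collapse = "x"), "grid (",
      sum(x$labels > 0), "labelled voxels )\n")
  invisible(x)
}

#' Average voxel time series within ROIs
#'
#' Row r of the result is the unweighted mean, per time point, of the series
#' of the in-mask voxels labelled r.
#'
#' @param volume A `brain_volume4d`.
#' @param parc A `parcellation` on the same grid.
#' @return An R x T numeric matrix of ROI mean series.
#' @export
roi_time_series <- function(volume, parc) {
  stopifnot(inherits(volume, "brain_volume4d"), inherits(parc, "parcellation"))
  if (!identical(volume$grid$dims, parc$grid$dims))
    stop("volume grid (", paste(volume$grid$dims, collapse = "x"),
         ") and parcellation grid (", paste(parc$grid$dims, collapse = "x"),
         ") differ")
  row_of <- rep(NA_integer_, prod(volume$grid$dims))
  row_of[which(volume$mask)] <- seq_len(sum(volume$mask))
  out <- matrix(NA_real_, parc$n_rois, n_timepoints(volume))
  for (r in seq_len(parc$n_rois)) {
    rows <- row_of[which(parc$labels == r)]
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0)
      stop("ROI ", r, " has no in-mask voxels")
    out[r, ] <- colMeans(volume$series[rows, , drop = FALSE])
  }
  rownames(out) <- if (!is.null(parc$names)) parc$names else paste0("roi", seq_len(parc$n_rois))
  out
}

#' ROI centroids in mm space
#'
#' The centroid of an ROI is the unweighted mean of its member voxels' mm
#' centre coordinates.
#'
#' @param parc A `parcellation`.
#' @return An R x 3 numeric matrix of mm coordinates.
#' @export
roi_centroids <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  out <- matrix(NA_real_, parc$n_rois, 3)
  for (r in seq_len(parc$n_rois)) {
    idx <- arrayInd(which(parc$labels == r), parc$grid$dims)
    out[r, ] <- colMeans(voxel_coords(parc$grid, idx))
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Pairwise Euclidean distances between ROI centroids
#'
#' @param centroids An R x 3 mm coordinate matrix from [roi_centroids()].
#' @return A symmetric R x R mm distance matrix with zero diagonal.
#' @export
link_lengths <- function(centroids) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 3, all(is.finite(centroids)))
  as.matrix(stats::dist(centroids))
}

#' Replace ROIs by fixed-size 7-voxel spheres at their centroids
#'
#' Each new ROI is the voxel containing the ROI centroid plus its six
#' face-adjacent voxels (the only 7-voxel digital sphere). The centroid voxel
#' is found by rounding the mm centroid to the nearest voxel centre, ties
#' broken toward the lower index. A sphere clipped by the grid edge or
#' overlapping another sphere is an error, keeping the fixed-size contract
#' honest.
#'
#' @param parc A `parcellation`.
#' @return A new `parcellation` with 7 voxels per ROI.
#' @export
make_fixed_size_rois <- function(parc) {
  cen <- roi_centroids(parc)
  g <- parc$grid
  # nearest voxel index; exact .5 rounds down (toward the lower index)
  vox <- ceiling(sweep(sweep(cen, 2, g$origin, "-"), 2, g$voxel_size, "/") + 1 - 0.5)
  offsets <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  labels <- array(0L, g$dims)
  owner <- array(0L, g$dims)
  overlaps <- NULL
  for (r in seq_len(parc$n_rois)) {
    if (any(vox[r, ] < 1 | vox[r, ] > g$dims))
      stop("centroid of ROI ", r, " falls outside the grid")
    member <- sweep(offsets, 2, vox[r, ], "+")
    if (any(member < 1) || any(sweep(member, 2, g$dims, ">")))
      stop("7-voxel sphere of ROI ", r, " is clipped by the grid edge")
    lin <- member[, 1] + (member[, 2] - 1) * g$dims[1] +
      (member[, 3] - 1) * prod(g$dims[1:2])
    taken <- owner[lin]
    if (any(taken > 0))
      overlaps <- rbind(overlaps, cbind(unique(taken[taken > 0]), r))
    owner[lin] <- r
    labels[lin] <- r
  }
  if (!is.null(overlaps))
    stop("fixed-size spheres overlap for ROI pair(s): ",
         paste(apply(overlaps, 1, paste, collapse = "-"), collapse = ", "))
  parcellation(g, labels, names = parc$names, system = parc$system)
}
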