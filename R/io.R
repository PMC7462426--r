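# Readers and writers for the standard formats the pipeline touches:
# NIfTI-1 volumes (4D time series, 3D masks, integer parcellations),
# TSV matrix stacks with a subject manifest, and the sweep output tables.

#' Write and read masked 4D volumes as NIfTI-1
#'
#' The volume's series is written as a 4D NIfTI (out-of-mask voxels 0) with
#' voxel size and TR in `pixdim` and the grid origin in the qform offset; the
#' mask is written alongside as a 3D integer NIfTI. Round trips preserve
#' data, grid, voxel size and TR within 1e-6.
#'
#' @param volume A `brain_volume4d`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param mask_path Where to write the mask (default: `path` with `_mask`
#'   inserted); `NULL` skips the mask file.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, mask_path = default_mask_path(path)) {
  stopifnot(inherits(volume, "brain_volume4d"))
  img <- RNifti::asNifti(volume_as_array(volume, fill = 0))
  RNifti::pixdim(img) <- c(volume$grid$voxel_size, volume$tr)
  RNifti::qform(img) <- grid_xform(volume$grid)
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    mimg <- RNifti::asNifti(array(as.integer(volume$mask), volume$grid$dims))
    RNifti::pixdim(mimg) <- volume$grid$voxel_size
    RNifti::qform(mimg) <- grid_xform(volume$grid)
    RNifti::writeNifti(mimg, mask_path)
  }
  invisible(path)
}

#' @rdname write_volume
#' @param tr Fallback TR in seconds when the header carries none.
#' @export
read_volume <- function(path, mask_path = default_mask_path(path), tr = NULL) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4) stop("expected a 4D NIfTI, got dims ",
                            paste(dm, collapse = "x"))
  pd <- RNifti::pixdim(img)
  hdr_tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else NULL
  tr <- if (!is.null(tr)) tr else if (!is.null(hdr_tr)) hdr_tr else 2
  grid <- volume_grid(dm[1:3], voxel_size = pd[1:3], origin = nifti_origin(img))
  mask <- if (!is.null(mask_path) && file.exists(mask_path)) {
    mimg <- RNifti::readNifti(mask_path)
    if (!all(dim(mimg)[1:3] == dm[1:3]))
      stop("mask dims (", paste(dim(mimg), collapse = "x"),
           ") do not match volume dims (", paste(dm[1:3], collapse = "x"), ")")
    array(mimg != 0, dm[1:3])
  } else array(TRUE, dm[1:3])
  volume_from_array(array(as.numeric(img), dim = dm), grid, mask = mask,
                    tr = tr)
}

#' @keywords internal
#' @noRd
default_mask_path <- function(path) {
  sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
}

#' @keywords internal
#' @noRd
grid_xform <- function(grid) {
  m <- rbind(cbind(diag(grid$voxel_size), grid$origin), c(0, 0, 0, 1))
  structure(m, code = 2L)
}

#' @keywords internal
#' @noRd
nifti_origin <- function(img) {
  h <- RNifti::niftiHeader(img)
  as.numeric(c(h$qoffset_x, h$qoffset_y, h$qoffset_z))
}

#' Write and read a parcellation as an integer NIfTI plus optional ROI table
#'
#' @param parc A `parcellation`.
#' @param path Output NIfTI path.
#' @param table_path Optional TSV (`roi_id name system`) with ROI metadata.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path, table_path = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  img <- RNifti::asNifti(array(as.integer(parc$labels), parc$grid$dims))
  RNifti::pixdim(img) <- parc$grid$voxel_size
  RNifti::qform(img) <- grid_xform(parc$grid)
  RNifti::writeNifti(img, path)
  if (!is.null(table_path)) {
    tab <- data.frame(roi_id = seq_len(parc$n_rois),
                      name = if (is.null(parc$names))
                        paste0("roi", seq_len(parc$n_rois)) else parc$names,
                      system = if (is.null(parc$system)) NA else parc$system)
    utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path, table_path = NULL) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3) stop("expected a 3D NIfTI parcellation")
  pd <- RNifti::pixdim(img)
  grid <- volume_grid(dm, voxel_size = pd[1:3], origin = nifti_origin(img))
  nm <- sys <- NULL
  if (!is.null(table_path) && file.exists(table_path)) {
    tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
    nm <- tab$name
    if (!all(is.na(tab$system))) sys <- tab$system
  }
  parcellation(grid, round(unclass(img)), names = nm, system = sys)
}

#' Write and read a matrix stack as per-subject TSVs plus a manifest
#'
#' Each subject's symmetric matrix goes to `<id>.tsv` (square, ROI ids as
#' header and first column, 12 significant digits); the manifest
#' `manifest.tsv` carries the subject table plus the file name. Reading
#' validates symmetry to 1e-8 and errors on manifest entries whose matrix
#' file is missing.
#'
#' @param stack A `matrix_stack`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_matrix_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "matrix_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roi_ids <- paste0("roi", seq_len(stack$n_rois))
  files <- paste0(stack$subjects$id, ".tsv")
  for (s in seq_along(stack$matrices)) {
    m <- format(stack$matrices[[s]], digits = 12, trim = TRUE,
                scientific = FALSE)
    dimnames(m) <- list(roi_ids, roi_ids)
    utils::write.table(m, file.path(dir, files[s]), sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  manifest <- cbind(stack$subjects, file = files)
  manifest$nuisance_shift <- NULL
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' @rdname write_matrix_stack
#' @param space,fwhm Stack metadata to attach on read (see [matrix_stack()]).
#' @export
read_matrix_stack <- function(dir, space = "r", fwhm = NA_real_) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("no manifest.tsv in ", dir)
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  mats <- lapply(seq_len(nrow(manifest)), function(s) {
    f <- file.path(dir, manifest$file[s])
    if (!file.exists(f))
      stop("matrix file missing for subject ", manifest$id[s], ": ", f)
    m <- as.matrix(utils::read.delim(f, row.names = 1, check.names = FALSE))
    check_square_symmetric(m, tol = 1e-8,
                           what = paste0("matrix of subject ", manifest$id[s]))
    dimnames(m) <- NULL
    m
  })
  manifest$file <- NULL
  matrix_stack(manifest, mats, space = space, fwhm = fwhm)
}

#' Write a cohort to disk
#'
#' Volumes (and their masks) as 4D NIfTI, the parcellation as integer NIfTI,
#' the subject table as `subjects.tsv` (`id group site mean_fd gender`), and
#' the ground-truth planted links as `ground_truth.tsv`
#' (`roi_a roi_b delta_achieved`).
#'
#' @param cohort A volume-mode `cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"), cohort$mode == "volumes")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_len(nrow(cohort$subjects)))
    write_volume(cohort$data[[s]],
                 file.path(dir, paste0(cohort$subjects$id[s], ".nii.gz")))
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.nii.gz"))
  subj <- cohort$subjects[c("id", "group", "site", "mean_fd", "gender")]
  utils::write.table(subj, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- cohort$ground_truth
  utils::write.table(
    data.frame(roi_a = gt$planted_links[, 1], roi_b = gt$planted_links[, 2],
               delta_achieved = gt$delta_achieved),
    file.path(dir, "ground_truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Write the tables of a kernel sweep result
#'
#' Emits `subnetwork_fwhm<k>.tsv` edge lists (`roi_a roi_b f_value`),
#' `hamming.tsv`, `d_grid.tsv`, `rho_by_kernel.tsv`, `persistence.tsv` and a
#' `run_log.txt` echoing seed and configuration.
#'
#' @param result A `kernel_sweep_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sweep_result <- function(result, dir) {
  stopifnot(inherits(result, "kernel_sweep_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f, ...) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, ...)
  for (ki in seq_along(result$fwhms)) {
    sub <- result$subnetworks[[ki]]
    edges <- if (is.null(sub)) {
      data.frame(roi_a = integer(0), roi_b = integer(0), f_value = numeric(0))
    } else {
      data.frame(roi_a = sub$links[, 1], roi_b = sub$links[, 2],
                 f_value = result$f_matrices[[ki]][sub$links])
    }
    wt(edges, sprintf("subnetwork_fwhm%g.tsv", result$fwhms[ki]),
       row.names = FALSE)
  }
  wt(result$hamming, "hamming.tsv", col.names = NA)
  wt(result$d_grid, "d_grid.tsv", col.names = NA)
  wt(data.frame(fwhm = result$fwhms, rho = result$rho,
                n_links = result$n_links),
     "rho_by_kernel.tsv", row.names = FALSE)
  wt(result$persistence$table, "persistence.tsv", row.names = FALSE)
  writeLines(c(paste("seed:", result$seed),
               paste("suprathreshold:", result$config$suprathreshold),
               paste("n_perm:", result$config$n_perm),
               paste("alpha:", result$config$alpha),
               paste("confounds:", paste(result$config$confounds, collapse = ",")),
               paste("fwhms:", paste(result$fwhms, collapse = ","))),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
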