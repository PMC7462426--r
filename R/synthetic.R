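# Synthetic two-group cohorts with a planted group-difference subnetwork.
#
# The generator emulates the data a smoothing-sweep study starts from after
# preprocessing: band-limited (default 0.01-0.08 Hz at TR = 2 s) ROI-level
# signals with a prescribed correlation structure, laid onto a toy block
# parcellation, with within-ROI voxel noise carrying nonzero intrinsic
# spatial smoothness, plus site- and motion-linked nuisance shifts injected
# at the Fisher-z link level (the level at which they are regressed out).
# Ground truth (planted links, achieved contrast, nuisance bookkeeping) is
# kept alongside so downstream detections can be scored.

#' Specify a synthetic cohort
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param n_rois Number of ROIs R.
#' @param roi_edge Voxels per ROI block edge (ROIs are cubic blocks of
#'   `roi_edge^3` voxels tiled with `gap`-voxel gaps).
#' @param gap Background voxels between neighbouring ROI blocks (>= 1).
#' @param n_timepoints Samples per series T.
#' @param tr Repetition time in seconds.
#' @param voxel_size Voxel edge in mm.
#' @param base_corr Background correlation r0 shared by all ROI pairs.
#' @param planted_links Two-column matrix of ROI pairs (i < j) forming a
#'   connected set; these links gain `delta` in the patient group.
#' @param delta Correlation increment on planted links (|r0| + |delta| < 1).
#' @param band Passband in Hz, `c(f_lo, f_hi)`.
#' @param voxel_noise_sd Standard deviation of within-ROI voxel noise.
#' @param intrinsic_fwhm FWHM (mm) of the spatial smoothness of the voxel
#'   noise field; 0 = independent noise.
#' @param n_sites Number of acquisition sites (assigned round-robin within
#'   each group).
#' @param site_effect_sd SD of the per-site additive Fisher-z offset.
#' @param fd_effect_slope Fisher-z shift per mm of mean framewise
#'   displacement.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10, n_rois = 12, roi_edge = 2, gap = 2,
                        n_timepoints = 128, tr = 2, voxel_size = 3,
                        base_corr = 0.1,
                        planted_links = default_planted_links(),
                        delta = 0.3, band = c(0.01, 0.08),
                        voxel_noise_sd = 0.5, intrinsic_fwhm = 3,
                        n_sites = 2, site_effect_sd = 0.1,
                        fd_effect_slope = 0.5, seed = 1L) {
  stopifnot(n_per_group >= 2, n_rois >= 2, roi_edge >= 1, gap >= 1,
            n_timepoints >= 8, tr > 0, voxel_size > 0,
            abs(base_corr) < 1, voxel_noise_sd >= 0, intrinsic_fwhm >= 0,
            n_sites >= 1, site_effect_sd >= 0)
  if (abs(base_corr) + abs(delta) >= 1)
    stop("|base_corr| + |delta| must be < 1 for a valid correlation matrix")
  planted_links <- as.matrix(planted_links)
  stopifnot(ncol(planted_links) == 2)
  if (any(planted_links[, 1] >= planted_links[, 2]))
    stop("planted links must be pairs (i, j) with i < j")
  if (any(planted_links > n_rois) || any(planted_links < 1))
    stop("planted links reference ROIs outside 1..n_rois")
  if (!links_connected(planted_links))
    stop("planted links must form a connected set on their incident nodes")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_rois = as.integer(n_rois), roi_edge = as.integer(roi_edge),
                 gap = as.integer(gap), n_timepoints = as.integer(n_timepoints),
                 tr = tr, voxel_size = voxel_size, base_corr = base_corr,
                 planted_links = planted_links, delta = delta, band = band,
                 voxel_noise_sd = voxel_noise_sd,
                 intrinsic_fwhm = intrinsic_fwhm, n_sites = as.integer(n_sites),
                 site_effect_sd = site_effect_sd,
                 fd_effect_slope = fd_effect_slope, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default planted subnetwork: a 5-link chain over ROIs 1-6
#' @return A two-column matrix of ROI pairs.
#' @export
default_planted_links <- function() cbind(1:5, 2:6)

#' @keywords internal
#' @noRd
links_connected <- function(links) {
  nodes <- sort(unique(as.vector(links)))
  if (length(nodes) == 0) return(FALSE)
  reached <- nodes[1]
  repeat {
    touch <- links[, 1] %in% reached | links[, 2] %in% reached
    new <- setdiff(unique(as.vector(links[touch, , drop = FALSE])), reached)
    if (length(new) == 0) break
    reached <- c(reached, new)
  }
  length(reached) == length(nodes)
}

#' Build the toy block parcellation of a cohort spec
#'
#' ROIs are axis-aligned cubic blocks of `roi_edge^3` voxels tiled on a near
#' cubic layout with `gap` background voxels between blocks (and at the grid
#' border), so spatial smoothing mixes neighbouring ROIs realistically.
#'
#' @param spec A `cohort_spec`.
#' @return A `parcellation`.
#' @export
block_parcellation <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  r <- spec$n_rois
  la <- ceiling(r^(1 / 3))
  lb <- ceiling(sqrt(r / la))
  lc <- ceiling(r / (la * lb))
  layout <- sort(c(la, lb, lc), decreasing = TRUE)
  pitch <- spec$roi_edge + spec$gap
  dims <- layout * pitch + spec$gap
  grid <- volume_grid(dims, voxel_size = spec$voxel_size)
  labels <- array(0L, dims)
  id <- 0L
  for (cz in seq_len(layout[3])) for (cy in seq_len(layout[2]))
    for (cx in seq_len(layout[1])) {
      if (id >= r) break
      id <- id + 1L
      x0 <- spec$gap + (cx - 1L) * pitch
      y0 <- spec$gap + (cy - 1L) * pitch
      z0 <- spec$gap + (cz - 1L) * pitch
      labels[x0 + seq_len(spec$roi_edge), y0 + seq_len(spec$roi_edge),
             z0 + seq_len(spec$roi_edge)] <- id
    }
  parcellation(grid, labels)
}

#' Group correlation matrices with a planted contrast
#'
#' The control matrix carries `base_corr` on every off-diagonal entry; the
#' patient matrix is identical except that planted links carry
#' `base_corr + delta`. Both are repaired to the nearest positive
#' semidefinite correlation matrix (eigenvalue clipping at zero, then
#' rescaling to unit diagonal); the achieved planted contrast after repair -
#' not the requested one - is recorded as ground truth.
#'
#' @param spec A `cohort_spec`.
#' @return A list with `control`, `patient` (R x R correlation matrices) and
#'   `ground_truth` (planted links, per-link `delta_achieved`, mean achieved
#'   contrast).
#' @export
make_group_covariances <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  r <- spec$n_rois
  control <- matrix(spec$base_corr, r, r)
  diag(control) <- 1
  patient <- control
  patient[spec$planted_links] <- spec$base_corr + spec$delta
  patient[spec$planted_links[, c(2, 1), drop = FALSE]] <-
    spec$base_corr + spec$delta
  control <- nearest_psd_correlation(control)
  patient <- nearest_psd_correlation(patient)
  achieved <- patient[spec$planted_links] - control[spec$planted_links]
  list(control = control, patient = patient,
       ground_truth = list(planted_links = spec$planted_links,
                           delta_requested = spec$delta,
                           delta_achieved = achieved,
                           mean_delta_achieved = mean(achieved),
                           cov_control = control, cov_patient = patient))
}

#' @keywords internal
#' @noRd
nearest_psd_correlation <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values >= 0)) return(m)
  v <- pmax(e$values, 0)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / outer(d, d)
  diag(m2) <- 1
  (m2 + t(m2)) / 2
}

#' Generate band-limited correlated ROI time series
#'
#' Draws R independent Gaussian series, band-limits each by frequency-domain
#' masking (bins outside `[f_lo, f_hi]` zeroed), standardises them, and mixes
#' with the symmetric square root of the target correlation matrix, so the
#' rows are zero-mean, unit-variance, band-limited, and their correlation
#' converges to `cov` as T grows.
#'
#' @param cov R x R positive semidefinite correlation matrix.
#' @param n_timepoints Series length T (>= 8).
#' @param tr Sampling interval in seconds.
#' @param band Passband `c(f_lo, f_hi)` in Hz; `f_hi` at most the Nyquist
#'   frequency `1 / (2 tr)`. A band covering the whole spectrum disables
#'   filtering.
#' @param seed Integer seed or NULL.
#' @return An R x T matrix.
#' @export
generate_roi_series <- function(cov, n_timepoints, tr = 2,
                                band = c(0.01, 0.08), seed = NULL) {
  check_square_symmetric(cov, what = "covariance")
  stopifnot(n_timepoints >= 8, tr > 0, length(band) == 2)
  nyquist <- 1 / (2 * tr)
  if (band[1] < 0 || band[1] >= band[2]) stop("need 0 <= f_lo < f_hi")
  if (band[2] > nyquist + 1e-12)
    stop("f_hi = ", band[2], " Hz exceeds the Nyquist frequency ",
         nyquist, " Hz")
  r <- nrow(cov)
  tt <- n_timepoints
  with_seed(seed, {
    z <- matrix(stats::rnorm(r * tt), r, tt)
    freqs <- (seq_len(tt) - 1) / (tt * tr)
    freqs <- pmin(freqs, 1 / tr - freqs) # fold to [0, Nyquist]
    keep <- freqs >= band[1] & freqs <= band[2]
    if (!all(keep)) {
      if (!any(keep)) stop("passband contains no frequency bins at this T")
      z <- t(apply(z, 1, function(row) {
        s <- stats::fft(row)
        s[!keep] <- 0
        Re(stats::fft(s, inverse = TRUE)) / tt
      }))
    }
    z <- z - rowMeans(z)
    z <- z / apply(z, 1, stats::sd)
    e <- eigen(cov, symmetric = TRUE)
    a <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    x <- a %*% z
    x - rowMeans(x)
  })
}

#' Render ROI series as a masked voxel volume
#'
#' Every voxel of ROI r carries `roi_series[r, ]` plus voxel noise of SD
#' `voxel_noise_sd`. With `intrinsic_fwhm > 0` the noise field is generated
#' on the full grid, smoothed to that FWHM, and rescaled back to the target
#' SD before masking, giving the volume a nonzero intrinsic smoothness. The
#' mask is the union of ROI voxels.
#'
#' @param parc A `parcellation` with R ROIs.
#' @param roi_series R x T matrix of latent ROI signals.
#' @param spec A `cohort_spec` (noise and TR parameters).
#' @param seed Integer seed or NULL.
#' @return A `brain_volume4d`.
#' @export
generate_subject_volume <- function(parc, roi_series, spec, seed = NULL) {
  stopifnot(inherits(parc, "parcellation"), inherits(spec, "cohort_spec"))
  roi_series <- as.matrix(roi_series)
  if (nrow(roi_series) != parc$n_rois)
    stop("roi_series rows (", nrow(roi_series), ") must match ROI count (",
         parc$n_rois, ")")
  mask <- parc$labels > 0
  idx <- which(mask)
  tt <- ncol(roi_series)
  series <- roi_series[parc$labels[idx], , drop = FALSE]
  if (spec$voxel_noise_sd > 0) {
    noise <- with_seed(seed, {
      if (spec$intrinsic_fwhm > 0) {
        full <- brain_volume4d(parc$grid, array(TRUE, parc$grid$dims),
                               matrix(stats::rnorm(prod(parc$grid$dims) * tt),
                                      ncol = tt), tr = spec$tr)
        sm <- gaussian_smooth(full, spec$intrinsic_fwhm)
        sm$series[idx, , drop = FALSE] / stats::sd(sm$series)
      } else {
        matrix(stats::rnorm(length(idx) * tt), ncol = tt)
      }
    })
    series <- series + spec$voxel_noise_sd * noise
  }
  brain_volume4d(parc$grid, mask, series, tr = spec$tr)
}

#' Generate a full synthetic cohort
#'
#' Produces `n_per_group` subjects per group (patients and controls). Sites
#' are assigned round-robin within each group; mean framewise displacement is
#' drawn from a log-normal (meanlog = ln 0.15, sdlog = 0.5) truncated at
#' 0.5 mm; gender alternates. Each subject receives band-limited ROI series
#' drawn from the group correlation matrix, rendered as a voxel volume (or
#' kept as ROI series in `mode = "series"`). Per-subject nuisance shifts
#' (site offset ~ N(0, site_effect_sd) shared within site, plus
#' fd_effect_slope * mean_fd) are stored in the subject table and injected
#' additively into Fisher-z link weights by [cohort_stack()].
#'
#' @param spec A `cohort_spec`.
#' @param mode `"volumes"` (full voxel rendering) or `"series"` (ROI series
#'   only; faster, for studies that start from connectivity).
#' @return A `cohort`: subject table, parcellation, per-subject data, and
#'   ground truth.
#' @export
generate_cohort <- function(spec, mode = c("volumes", "series")) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  if (spec$n_per_group < 2) stop("n_per_group must be >= 2 (F undefined)")
  parc <- block_parcellation(spec)
  covs <- make_group_covariances(spec)
  n <- spec$n_per_group
  with_seed(spec$seed, {
    site_offsets <- stats::rnorm(spec$n_sites, 0, spec$site_effect_sd)
    names(site_offsets) <- paste0("site", seq_len(spec$n_sites))
    groups <- rep(c("patient", "control"), each = n)
    ids <- sprintf("sub%03d", seq_len(2 * n))
    site <- paste0("site", rep_len(seq_len(spec$n_sites), n))
    site <- c(site, site) # round-robin within each group
    mean_fd <- vapply(seq_len(2 * n), function(s) {
      fd <- Inf
      while (fd > 0.5) fd <- stats::rlnorm(1, meanlog = log(0.15), sdlog = 0.5)
      fd
    }, 0)
    gender <- rep_len(c("M", "F"), 2 * n)
    subjects <- data.frame(id = ids, group = groups, site = site,
                           mean_fd = mean_fd, gender = gender,
                           stringsAsFactors = FALSE)
    subjects$nuisance_shift <- site_offsets[subjects$site] +
      spec$fd_effect_slope * subjects$mean_fd
    data <- vector("list", 2 * n)
    for (s in seq_len(2 * n)) {
      cv <- if (groups[s] == "patient") covs$patient else covs$control
      series_seed <- derive_seed(spec$seed, 1000 + s)
      roi_series <- generate_roi_series(cv, spec$n_timepoints, spec$tr,
                                        spec$band, seed = series_seed)
      data[[s]] <- if (mode == "volumes") {
        generate_subject_volume(parc, roi_series, spec,
                                seed = derive_seed(spec$seed, 2000 + s))
      } else roi_series
    }
    gt <- covs$ground_truth
    gt$site_offsets <- site_offsets
    structure(list(spec = spec, parcellation = parc, subjects = subjects,
                   data = data, mode = mode, ground_truth = gt),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$subjects), "subjects (", x$spec$n_per_group,
      "per group ),", x$spec$n_rois, "ROIs, T =", x$spec$n_timepoints,
      ", mode", x$mode, "\n")
  invisible(x)
}

#' Build the cleaned connectivity stack of a cohort
#'
#' The network-extraction pipeline: (optional) Gaussian smoothing of each
#' subject's volume at `fwhm`, ROI series extraction, Pearson correlation,
#' Fisher z, additive injection of the stored per-subject nuisance shift,
#' link-wise confound regression, inverse Fisher transform.
#'
#' @param cohort A `cohort`.
#' @param fwhm Smoothing kernel FWHM in mm (ignored for series-mode cohorts).
#' @param confounds Covariates to regress out (`NULL` to skip regression).
#' @param inject_nuisance Add the generator's per-subject nuisance shifts to
#'   the z-weights (TRUE by default; set FALSE for idealised pipelines).
#' @return A cleaned `matrix_stack` in r space tagged with `fwhm`.
#' @export
cohort_stack <- function(cohort, fwhm = 0, confounds = c("site", "mean_fd"),
                         inject_nuisance = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  series <- if (cohort$mode == "volumes") {
    lapply(cohort$data, function(vol)
      roi_time_series(gaussian_smooth(vol, fwhm), cohort$parcellation))
  } else cohort$data
  mats <- lapply(series, pearson_matrix)
  stack <- matrix_stack(cohort$subjects, mats, space = "r", fwhm = fwhm)
  stack <- fisher_z_stack(stack)
  if (inject_nuisance && !is.null(cohort$subjects$nuisance_shift)) {
    stack$matrices <- lapply(seq_along(stack$matrices), function(s) {
      m <- stack$matrices[[s]] + cohort$subjects$nuisance_shift[s]
      diag(m) <- 0
      m
    })
  }
  if (!is.null(confounds) && length(confounds) > 0)
    stack <- regress_confounds(stack, model = confounds)
  fisher_inverse_stack(stack)
}
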