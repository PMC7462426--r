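# Kernel-sweep orchestration and the sweep-level comparison quantities:
# per-kernel subnetworks, signed Cohen's d per link per kernel, link
# persistence across kernels, Hamming distances between subnetwork masks,
# link-length distributions and the Spearman correlation between link length
# and F statistic.

#' Cohen's d from a two-group F statistic
#'
#' With one numerator degree of freedom F = t^2, so
#' `|d| = sqrt(F * (1/n1 + 1/n2))`; the sign is taken from the group mean
#' difference of the link weight.
#'
#' @param f F statistic (>= 0), vectorised.
#' @param n1,n2 Group sizes (>= 2).
#' @param sign_source Sign carrier: the (patient - control) mean difference;
#'   only its sign is used. Default 1 (positive).
#' @return Signed Cohen's d.
#' @export
cohens_d_from_f <- function(f, n1, n2, sign_source = 1) {
  stopifnot(all(f >= 0), n1 >= 2, n2 >= 2)
  sqrt(f * (1 / n1 + 1 / n2)) * ifelse(sign_source >= 0, 1, -1)
}

#' Hamming distance between two subnetwork masks
#'
#' The number of upper-triangle link positions at which the two binary masks
#' differ; 0 iff the subnetworks are identical. An absent subnetwork
#' (`NULL`) counts as the empty mask.
#'
#' @param a,b `subnetwork` objects, binary symmetric R x R masks, or `NULL`.
#' @param n_rois ROI count, required only when both arguments are `NULL`.
#' @return Integer distance.
#' @export
hamming_distance <- function(a, b, n_rois = NULL) {
  ma <- subnetwork_mask(a, n_rois)
  mb <- subnetwork_mask(b, n_rois)
  if (is.null(ma) && is.null(mb)) return(0L)
  if (is.null(ma)) ma <- matrix(0L, nrow(mb), ncol(mb))
  if (is.null(mb)) mb <- matrix(0L, nrow(ma), ncol(ma))
  if (!all(dim(ma) == dim(mb)))
    stop("subnetwork masks have different ROI counts: ",
         nrow(ma), " vs ", nrow(mb))
  sum(links_of(ma) != links_of(mb))
}

#' @keywords internal
#' @noRd
subnetwork_mask <- function(x, n_rois = NULL) {
  if (is.null(x)) {
    if (is.null(n_rois)) return(NULL)
    return(matrix(0L, n_rois, n_rois))
  }
  m <- if (inherits(x, "subnetwork")) x$link_mask else x
  check_square_symmetric(m, what = "subnetwork mask")
  if (!all(m %in% c(0, 1))) stop("subnetwork mask must be binary")
  m
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (ties get average ranks).
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for constant input")
  stats::cor(x, y, method = "spearman")
}

#' Link persistence across the kernel sweep
#'
#' For every link significant at at least one kernel: the set of kernels at
#' which it is significant, the smallest such kernel, and the count of
#' kernels. Links are ordered by (smallest detecting kernel asc, count desc,
#' node pair). The summary reports how many links are significant at every
#' kernel and at >= 75% of the kernels.
#'
#' @param subnetworks List of `subnetwork` objects (or `NULL`), one per
#'   kernel.
#' @param fwhms Kernel FWHMs, aligned with `subnetworks`.
#' @param n_rois ROI count.
#' @return A list with `table` (data frame: roi_a, roi_b, first_fwhm,
#'   n_kernels, kernels) and `summary` (n_links_any, n_links_all,
#'   n_links_75pct).
#' @export
link_persistence <- function(subnetworks, fwhms, n_rois) {
  stopifnot(length(subnetworks) == length(fwhms))
  k <- length(fwhms)
  masks <- lapply(subnetworks, function(s) {
    m <- subnetwork_mask(s, n_rois)
    if (nrow(m) != n_rois) stop("subnetwork ROI count differs from n_rois")
    links_of(m)
  })
  hits <- do.call(cbind, masks) # links x kernels
  ever <- which(rowSums(hits) > 0)
  pairs <- link_pairs(n_rois)
  if (length(ever) == 0) {
    tab <- data.frame(roi_a = integer(0), roi_b = integer(0),
                      first_fwhm = numeric(0), n_kernels = integer(0),
                      kernels = character(0))
  } else {
    first <- apply(hits[ever, , drop = FALSE], 1, function(h) fwhms[which(h > 0)[1]])
    count <- rowSums(hits[ever, , drop = FALSE])
    tab <- data.frame(roi_a = pairs[ever, 1], roi_b = pairs[ever, 2],
                      first_fwhm = first, n_kernels = as.integer(count),
                      kernels = vapply(ever, function(l)
                        paste(fwhms[hits[l, ] > 0], collapse = ","), ""))
    tab <- tab[order(tab$first_fwhm, -tab$n_kernels, tab$roi_a, tab$roi_b), ]
    rownames(tab) <- NULL
  }
  list(table = tab,
       summary = list(n_links_any = length(ever),
                      n_links_all = sum(tab$n_kernels == k),
                      n_links_75pct = sum(tab$n_kernels >= ceiling(0.75 * k))))
}

#' Run the full smoothing sweep on a cohort
#'
#' For each kernel of the sweep, smooths every subject's original volume,
#' extracts ROI series, builds cleaned connectivity matrices, runs NBS with
#' a kernel-specific sub-seed derived from the master seed, and selects the
#' primary subnetwork. It then assembles the sweep-level comparisons: the
#' signed Cohen's d grid over the links significant at >= 1 kernel (d
#' computed at every kernel for those links), the Hamming distance matrix
#' over kernel pairs, the per-kernel Spearman correlation between link
#' length and F over ALL links, the detected-link length distributions, and
#' the link persistence table.
#'
#' @param cohort A volume-mode `cohort`.
#' @param fwhms Kernel sweep (strictly increasing, mm).
#' @param suprathreshold,n_perm,alpha NBS parameters, see [nbs_config()].
#' @param confounds Covariates regressed out of each link, see
#'   [cohort_stack()].
#' @param seed Master seed; kernel k uses `derive_seed(seed, k)`.
#' @return A `kernel_sweep_result`.
#' @export
run_sweep <- function(cohort, fwhms = c(0, 4, 8, 12), suprathreshold = 12.25,
                      n_perm = 1000, alpha = 0.05,
                      confounds = c("site", "mean_fd"), seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  check_sweep(fwhms)
  if (cohort$mode != "volumes")
    stop("run_sweep needs a volume-mode cohort (smoothing acts on voxels)")
  r <- cohort$spec$n_rois
  k <- length(fwhms)
  lengths_mm <- link_lengths(roi_centroids(cohort$parcellation))
  len_links <- links_of(lengths_mm)
  subnetworks <- vector("list", k)
  nbs_results <- vector("list", k)
  rho <- numeric(k)
  n_links <- integer(k)
  length_distributions <- vector("list", k)
  for (ki in seq_len(k)) {
    stage <- sprintf("fwhm=%g mm", fwhms[ki])
    stack <- tryCatch(
      cohort_stack(cohort, fwhm = fwhms[ki], confounds = confounds),
      error = function(e) stop("network extraction failed at ", stage, ": ",
                               conditionMessage(e), call. = FALSE))
    cfg <- nbs_config(suprathreshold = suprathreshold, n_perm = n_perm,
                      alpha = alpha, seed = derive_seed(seed, ki))
    res <- tryCatch(nbs_test(stack, cfg),
                    error = function(e) stop("NBS failed at ", stage, ": ",
                                             conditionMessage(e), call. = FALSE))
    nbs_results[[ki]] <- res
    sub <- select_primary_subnetwork(res)
    subnetworks[ki] <- list(sub) # [[<- would drop NULL elements
    n_links[ki] <- if (is.null(sub)) 0L else sub$n_links
    f_links <- links_of(res$f_matrix)
    finite <- is.finite(f_links)
    rho[ki] <- spearman_rho(len_links[finite], f_links[finite])
    length_distributions[[ki]] <- if (is.null(sub)) numeric(0)
    else lengths_mm[sub$links]
  }
  # signed d grid over the ever-significant links, at every kernel
  ever_masks <- vapply(subnetworks, function(s)
    links_of(subnetwork_mask(s, r)), numeric(r * (r - 1) / 2))
  ever <- which(rowSums(ever_masks) > 0)
  pairs <- link_pairs(r)
  n1 <- nbs_results[[1]]$group_sizes[1]
  n2 <- nbs_results[[1]]$group_sizes[2]
  d_grid <- matrix(NA_real_, length(ever), k)
  dimnames(d_grid) <- list(if (length(ever)) paste0(pairs[ever, 1], "-",
                                                    pairs[ever, 2]),
                           paste0("fwhm", fwhms))
  # group_levels are sorted, so level 1 is "control": flip the stored
  # difference to report patient - control
  for (ki in seq_len(k)) {
    res <- nbs_results[[ki]]
    dsign <- links_of(res$diff_matrix)[ever]
    if (identical(res$group_levels[1], "control")) dsign <- -dsign
    d_grid[, ki] <- cohens_d_from_f(links_of(res$f_matrix)[ever], n1, n2,
                                    sign_source = dsign)
  }
  hamming <- matrix(0L, k, k, dimnames = list(fwhms, fwhms))
  for (a in seq_len(k)) for (b in seq_len(k))
    hamming[a, b] <- hamming_distance(subnetworks[[a]], subnetworks[[b]],
                                      n_rois = r)
  structure(list(fwhms = fwhms, subnetworks = subnetworks,
                 n_links = n_links, d_grid = d_grid,
                 persistence = link_persistence(subnetworks, fwhms, r),
                 hamming = hamming, rho = rho,
                 length_distributions = length_distributions,
                 f_matrices = lapply(nbs_results, `[[`, "f_matrix"),
                 link_lengths = lengths_mm,
                 group_sizes = c(n1, n2), seed = seed,
                 config = list(suprathreshold = suprathreshold,
                               n_perm = n_perm, alpha = alpha,
                               confounds = confounds)),
            class = "kernel_sweep_result")
}

#' @export
print.kernel_sweep_result <- function(x, ...) {
  cat("<kernel_sweep_result>", length(x$fwhms), "kernels:",
      paste(x$fwhms, collapse = ", "), "mm\n")
  cat("  subnetwork links per kernel:", paste(x$n_links, collapse = ", "), "\n")
  cat("  links significant at >= 1 kernel:",
      x$persistence$summary$n_links_any, "\n")
  cat("  Spearman rho(length, F):",
      paste(signif(x$rho, 3), collapse = ", "), "\n")
  invisible(x)
}
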