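# Gaussian spatial smoothing of masked 4D volumes, global smoothness
# estimation, and iterative blur-to-target smoothing.
#
# Each in-mask voxel's series is replaced by the kernel-weighted average of
# the in-mask voxels around it, with the normalising denominator restricted
# to the mask, so signal never bleeds in from outside the brain. The kernel
# is truncated per axis at 4*sigma (box support); the per-axis truncation
# makes 3D smoothing on a full cuboid mask exactly equal to sequential 1D
# smoothing along each axis, which the implementation exploits.

FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2)) # 2.354820045...

#' Convert between FWHM and Gaussian sigma
#'
#' FWHM = 2 sqrt(2 ln 2) sigma, both in mm.
#'
#' @param fwhm,sigma Kernel width in mm (nonnegative).
#' @return The converted width in mm.
#' @export
fwhm_to_sigma <- function(fwhm) {
  stopifnot(is.numeric(fwhm))
  if (any(fwhm < 0)) stop("fwhm must be nonnegative")
  fwhm / FWHM_PER_SIGMA
}

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) {
  stopifnot(is.numeric(sigma))
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  sigma * FWHM_PER_SIGMA
}

#' Describe a Gaussian smoothing kernel
#'
#' @param fwhm Full width at half maximum in mm.
#' @return A `smoothing_kernel` with fields `fwhm`, `sigma` and the per-axis
#'   `truncation_radius` (4 sigma) beyond which weights are dropped.
#' @export
smoothing_kernel <- function(fwhm) {
  sigma <- fwhm_to_sigma(fwhm)
  structure(list(fwhm = fwhm, sigma = sigma, truncation_radius = 4 * sigma),
            class = "smoothing_kernel")
}

#' The default kernel sweep
#'
#' Sixteen kernels: no smoothing (0 mm) then 4 mm to 32 mm in 2 mm steps.
#' @return Numeric vector of FWHM values in mm.
#' @export
default_kernel_sweep <- function() c(0, seq(4, 32, by = 2))

#' @keywords internal
#' @noRd
check_sweep <- function(fwhms) {
  stopifnot(is.numeric(fwhms), length(fwhms) >= 1)
  if (any(fwhms < 0)) stop("sweep FWHMs must be nonnegative")
  if (is.unsorted(fwhms, strictly = TRUE))
    stop("sweep FWHMs must be strictly increasing")
  fwhms
}

# --- smoothing paths ---------------------------------------------------------

# 1D row-normalised operator along one axis (n voxels of size v mm).
gauss_op_1d <- function(n, v, sigma, radius) {
  d <- outer(seq_len(n), seq_len(n), "-") * v
  w <- exp(-d^2 / (2 * sigma^2))
  w[abs(d) > radius] <- 0
  w / rowSums(w)
}

# Full-cuboid-mask path: sequential normalised 1D smoothing per axis.
smooth_separable <- function(volume, sigma, radius) {
  d <- volume$grid$dims
  vs <- volume$grid$voxel_size
  tt <- n_timepoints(volume)
  a <- array(volume$series, dim = c(d, tt))
  perms <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(3, 2, 1, 4))
  for (ax in 1:3) {
    if (d[ax] == 1) next
    w <- gauss_op_1d(d[ax], vs[ax], sigma, radius)
    a <- aperm(a, perms[[ax]])
    dm <- dim(a)
    a <- array(w %*% matrix(a, nrow = d[ax]), dim = dm)
    a <- aperm(a, perms[[ax]])
  }
  out <- volume
  out$series <- matrix(a, ncol = tt)
  out
}

# Small-mask path: explicit dense row-normalised operator over in-mask voxels.
smooth_operator <- function(volume, sigma, radius) {
  idx <- which(volume$mask)
  co <- voxel_coords(volume$grid, arrayInd(idx, volume$grid$dims))
  w <- matrix(1, length(idx), length(idx))
  for (ax in 1:3) {
    da <- outer(co[, ax], co[, ax], "-")
    wa <- exp(-da^2 / (2 * sigma^2))
    wa[abs(da) > radius] <- 0
    w <- w * wa
  }
  w <- w / rowSums(w)
  out <- volume
  out$series <- w %*% volume$series
  out
}

# General path: accumulate shifted copies over the kernel's offset box.
smooth_shift <- function(volume, sigma, radius) {
  d <- volume$grid$dims
  vs <- volume$grid$voxel_size
  tt <- n_timepoints(volume)
  noff <- pmin(floor(radius / vs), d - 1)
  m <- array(0, d)
  m[which(volume$mask)] <- 1
  a <- volume_as_array(volume, fill = 0)
  num <- array(0, c(d, tt))
  den <- array(0, d)
  for (dx in -noff[1]:noff[1]) {
    wx <- exp(-(dx * vs[1])^2 / (2 * sigma^2))
    xt <- max(1, 1 + dx):min(d[1], d[1] + dx); xs <- xt - dx
    for (dy in -noff[2]:noff[2]) {
      wy <- exp(-(dy * vs[2])^2 / (2 * sigma^2))
      yt <- max(1, 1 + dy):min(d[2], d[2] + dy); ys <- yt - dy
      for (dz in -noff[3]:noff[3]) {
        wz <- exp(-(dz * vs[3])^2 / (2 * sigma^2))
        zt <- max(1, 1 + dz):min(d[3], d[3] + dz); zs <- zt - dz
        w <- wx * wy * wz
        den[xt, yt, zt] <- den[xt, yt, zt] + w * m[xs, ys, zs]
        num[xt, yt, zt, ] <- num[xt, yt, zt, , drop = FALSE] +
          w * a[xs, ys, zs, , drop = FALSE]
      }
    }
  }
  keep <- which(volume$mask)
  out <- volume
  out$series <- matrix(num, ncol = tt)[keep, , drop = FALSE] /
    as.vector(den)[keep]
  out
}

#' Mask-aware Gaussian spatial smoothing
#'
#' Replaces each in-mask voxel series by the Gaussian-weighted average of the
#' in-mask voxel series around it; the normalisation runs over in-mask voxels
#' only, so the weighted average of a constant field is that constant and no
#' signal is drawn from outside the mask. `fwhm = 0` returns the input
#' unchanged. Grid, mask and TR are untouched.
#'
#' @param volume A `brain_volume4d` with at least one in-mask voxel.
#' @param fwhm Kernel FWHM in mm, or a `smoothing_kernel`.
#' @param method Smoothing path: `"auto"` picks separable 1D passes on a full
#'   cuboid mask, a dense voxel-pair operator for small masks, and a
#'   shift-and-accumulate convolution otherwise. All paths compute the same
#'   quantity.
#' @return A smoothed `brain_volume4d`.
#' @export
gaussian_smooth <- function(volume, fwhm,
                            method = c("auto", "separable", "operator", "shift")) {
  stopifnot(inherits(volume, "brain_volume4d"))
  if (inherits(fwhm, "smoothing_kernel")) fwhm <- fwhm$fwhm
  stopifnot(is.numeric(fwhm), length(fwhm) == 1, fwhm >= 0)
  if (sum(volume$mask) < 1) stop("volume has no in-mask voxels")
  method <- match.arg(method)
  if (fwhm == 0) return(volume)
  sigma <- fwhm_to_sigma(fwhm)
  radius <- 4 * sigma
  if (method == "auto") {
    method <- if (all(volume$mask)) "separable"
    else if (sum(volume$mask) <= 2500) "operator"
    else "shift"
  }
  switch(method,
         separable = {
           if (!all(volume$mask))
             stop("separable smoothing requires a full cuboid mask")
           smooth_separable(volume, sigma, radius)
         },
         operator = smooth_operator(volume, sigma, radius),
         shift = smooth_shift(volume, sigma, radius))
}

#' Smooth one volume with every kernel of a sweep
#'
#' Each kernel is applied to the original volume independently (never
#' cumulatively); output order matches the sweep order.
#'
#' @param volume A `brain_volume4d`.
#' @param fwhms Strictly increasing nonnegative FWHMs in mm
#'   (default [default_kernel_sweep()]).
#' @return A list of smoothed volumes, one per FWHM.
#' @export
kernel_sweep_smooth <- function(volume, fwhms = default_kernel_sweep()) {
  check_sweep(fwhms)
  lapply(fwhms, function(f) gaussian_smooth(volume, f))
}

# --- smoothness estimation ---------------------------------------------------

#' Estimate the global spatial smoothness of a volume
#'
#' Variance-of-first-differences estimator: along each axis `a`,
#' `FWHM_a = delta_a * sqrt(-2 ln 2 / ln(1 - v_a / (2 v)))` where `v` is the
#' spatial variance of the field, `v_a` the variance of first differences
#' between in-mask neighbours along `a` (both averaged over time points) and
#' `delta_a` the voxel size. This recovers the FWHM of the Gaussian kernel
#' that, applied to white noise, would produce the observed autocorrelation.
#' An axis rougher than white noise (`v_a >= 2 v`) contributes the voxel size
#' as a floor. The three axis estimates are combined by geometric mean.
#'
#' @param volume A `brain_volume4d`, non-constant, with at least two in-mask
#'   voxels along each axis.
#' @return Estimated FWHM in mm.
#' @export
estimate_smoothness <- function(volume) {
  stopifnot(inherits(volume, "brain_volume4d"))
  tt <- n_timepoints(volume)
  a <- volume_as_array(volume, fill = NA)
  v <- mean(apply(volume$series, 2, stats::var))
  if (!is.finite(v) || v <= 0) stop("smoothness undefined for a constant field")
  d <- volume$grid$dims
  vs <- volume$grid$voxel_size
  fwhm_axis <- numeric(3)
  for (ax in 1:3) {
    if (d[ax] < 2) stop("need >= 2 in-mask voxels along axis ", ax)
    hi <- lapply(seq_along(d), function(k) if (k == ax) 2:d[k] else seq_len(d[k]))
    lo <- lapply(seq_along(d), function(k) if (k == ax) 1:(d[k] - 1) else seq_len(d[k]))
    va_t <- numeric(tt)
    for (t in seq_len(tt)) {
      frame <- a[, , , t, drop = FALSE]
      dif <- do.call(`[`, c(list(frame), hi, list(1))) -
        do.call(`[`, c(list(frame), lo, list(1)))
      dif <- dif[!is.na(dif)]
      if (length(dif) < 2) stop("axis ", ax, " has no in-mask neighbour pairs")
      va_t[t] <- stats::var(dif)
    }
    ratio <- mean(va_t) / (2 * v)
    fwhm_axis[ax] <- if (ratio >= 1) vs[ax]
    else vs[ax] * sqrt(-2 * log(2) / log(1 - ratio))
  }
  exp(mean(log(fwhm_axis)))
}

#' Smooth a volume until it reaches a target global smoothness
#'
#' Applies global Gaussian steps, re-estimating smoothness after each, until
#' the estimate is within `tol * target` of the target or `max_iter` steps
#' have run. Smoothness compounds approximately in quadrature, so each step
#' uses the full quadrature gap `sqrt(max(target^2 - current^2, 0))`,
#' floored at 0.5 mm; kernels much smaller than a voxel are unresolvable on
#' the grid, so fractional-gap steps would stall short of the target. The
#' loop also stops once the estimate reaches the target, since smoothing
#' cannot be undone. A volume that is already smoother than the target is
#' returned unchanged with `blur_already_smoother = TRUE` and a warning.
#'
#' @param volume A `brain_volume4d`.
#' @param target Target FWHM in mm (> 0).
#' @param max_iter Maximum smoothing steps.
#' @param tol Relative tolerance on the achieved smoothness.
#' @return The smoothed volume, with attributes `blur_fwhm_estimate`,
#'   `blur_steps`, `blur_converged` and `blur_already_smoother`.
#' @export
blur_to_fwhm <- function(volume, target, max_iter = 25, tol = 0.05) {
  stopifnot(is.numeric(target), length(target) == 1, target > 0)
  cur <- estimate_smoothness(volume)
  if (cur > target * (1 + tol)) {
    warning("volume is already smoother (", signif(cur, 4),
            " mm) than the target (", target, " mm); returning input unchanged")
    attr(volume, "blur_fwhm_estimate") <- cur
    attr(volume, "blur_steps") <- 0L
    attr(volume, "blur_converged") <- FALSE
    attr(volume, "blur_already_smoother") <- TRUE
    return(volume)
  }
  steps <- 0L
  while (abs(cur - target) > tol * target && steps < max_iter) {
    step <- max(sqrt(max(target^2 - cur^2, 0)), 0.5)
    volume <- gaussian_smooth(volume, step)
    new <- estimate_smoothness(volume)
    cur <- max(new, cur) # estimated smoothness is monotone over iterations
    steps <- steps + 1L
    if (cur >= target) break # cannot unsmooth past the target
  }
  attr(volume, "blur_fwhm_estimate") <- cur
  attr(volume, "blur_steps") <- steps
  attr(volume, "blur_converged") <- abs(cur - target) <= tol * target
  attr(volume, "blur_already_smoother") <- FALSE
  volume
}
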