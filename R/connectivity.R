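# Per-subject connectivity matrices: Pearson correlation of ROI series,
# Fisher z transform, link-wise nuisance regression across subjects, inverse
# transform, and density thresholding. A matrix stack bundles one matrix per
# subject with the subject table; all group statistics act on stacks.

#' Pearson connectivity matrix of ROI series
#'
#' @param series R x T matrix of ROI time series (T >= 3, rows non-constant).
#' @return Symmetric R x R Pearson correlation matrix, diagonal fixed to 0
#'   (self-links never enter group statistics).
#' @export
pearson_matrix <- function(series) {
  series <- as.matrix(series)
  if (ncol(series) < 3) stop("need T >= 3 time points")
  sds <- apply(series, 1, stats::sd)
  if (any(sds == 0))
    stop("constant ROI series: ", paste(which(sds == 0), collapse = ", "))
  m <- stats::cor(t(series))
  diag(m) <- 0
  dimnames(m) <- NULL
  m
}

#' Fisher z transform and its inverse
#'
#' `fisher_z` applies `artanh` elementwise off-diagonal, clipping |w| = 1 to
#' 1 - 1e-7 to avoid divergence; `fisher_inverse` applies `tanh`. The diagonal
#' (zero by convention) maps to itself.
#'
#' @param w Correlation matrix or vector with |w| <= 1.
#' @param z z-scored matrix or vector.
#' @return Transformed object of the same shape.
#' @export
fisher_z <- function(w) {
  if (any(abs(w) > 1)) stop("|w| must be <= 1 for the Fisher transform")
  clip <- 1 - 1e-7
  atanh(pmin(pmax(w, -clip), clip))
}

#' @rdname fisher_z
#' @export
fisher_inverse <- function(z) tanh(z)

#' Bundle per-subject connectivity matrices with the subject table
#'
#' @param subjects Data frame with at least columns `id` and `group` (two
#'   levels); typically also `site`, `mean_fd`, `gender`.
#' @param matrices List of symmetric R x R matrices, one per subject row.
#' @param space `"r"` (correlation) or `"z"` (Fisher-transformed).
#' @param fwhm Smoothing provenance tag in mm (NA if unknown).
#' @return A `matrix_stack`.
#' @export
matrix_stack <- function(subjects, matrices, space = c("r", "z"), fwhm = NA_real_) {
  space <- match.arg(space)
  subjects <- as.data.frame(subjects)
  stopifnot(all(c("id", "group") %in% names(subjects)),
            length(matrices) == nrow(subjects))
  groups <- unique(as.character(subjects$group))
  if (length(groups) != 2) stop("stack must contain exactly two groups")
  r <- nrow(matrices[[1]])
  for (m in matrices) {
    check_square_symmetric(m, what = "connectivity matrix")
    if (nrow(m) != r) stop("all matrices must share the same ROI count")
  }
  structure(list(subjects = subjects, matrices = matrices, n_rois = r,
                 space = space, fwhm = fwhm),
            class = "matrix_stack")
}

#' @export
print.matrix_stack <- function(x, ...) {
  cat("<matrix_stack>", length(x$matrices), "subjects x", x$n_rois,
      "ROIs; space", x$space, "; fwhm", x$fwhm, "mm\n")
  print(table(x$subjects$group))
  invisible(x)
}

#' @keywords internal
#' @noRd
stack_link_matrix <- function(stack) {
  t(vapply(stack$matrices, links_of,
           numeric(stack$n_rois * (stack$n_rois - 1) / 2)))
}

#' @keywords internal
#' @noRd
stack_from_link_matrix <- function(stack, w) {
  stack$matrices <- lapply(seq_len(nrow(w)), function(s)
    mat_from_links(w[s, ], stack$n_rois))
  stack
}

#' Apply the Fisher transform (or its inverse) to every matrix of a stack
#'
#' @param stack A `matrix_stack`.
#' @return The transformed stack with `space` updated.
#' @export
fisher_z_stack <- function(stack) {
  stopifnot(inherits(stack, "matrix_stack"))
  if (stack$space == "z") stop("stack is already in z space")
  stack$matrices <- lapply(stack$matrices, function(m) {
    z <- fisher_z(m); diag(z) <- 0; z
  })
  stack$space <- "z"
  stack
}

#' @rdname fisher_z_stack
#' @export
fisher_inverse_stack <- function(stack) {
  stopifnot(inherits(stack, "matrix_stack"))
  if (stack$space == "r") stop("stack is already in r space")
  stack$matrices <- lapply(stack$matrices, fisher_inverse)
  stack$space <- "r"
  stack
}

#' Remove nuisance covariates from every link by linear regression
#'
#' Fits, for each link independently across subjects, an ordinary
#' least-squares model of the Fisher-z weight on an intercept plus the named
#' covariates (categorical covariates dummy-coded against the alphabetically
#' first level), and replaces the weight by residual + fitted intercept: the
#' mean level is retained, the nuisance-explained variation removed. Group
#' membership is never part of the model, so group signal survives.
#'
#' @param stack A `matrix_stack` in z space.
#' @param model Character vector of subject-table column names (default
#'   `c("site", "mean_fd")`).
#' @return The cleaned stack, still in z space.
#' @export
regress_confounds <- function(stack, model = c("site", "mean_fd")) {
  stopifnot(inherits(stack, "matrix_stack"))
  if (stack$space != "z")
    stop("confound regression operates on Fisher-z matrices; call fisher_z_stack() first")
  if ("group" %in% model) stop("group membership must not be regressed out")
  missing_cols <- setdiff(model, names(stack$subjects))
  if (length(missing_cols))
    stop("covariate(s) not in subject table: ", paste(missing_cols, collapse = ", "))
  dat <- stack$subjects[model]
  for (k in seq_along(dat)) {
    if (is.character(dat[[k]]))
      dat[[k]] <- factor(dat[[k]], levels = sort(unique(dat[[k]])))
  }
  # constant covariates are absorbed by the intercept: nothing to remove
  constant <- vapply(dat, function(col) length(unique(col)) < 2, TRUE)
  dat <- dat[!constant]
  if (length(dat) == 0) return(stack)
  x <- stats::model.matrix(~ ., data = dat)
  if (nrow(x) < ncol(x) + 2)
    stop("need at least ", ncol(x) + 2, " subjects for ", ncol(x), " design columns")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  w <- stack_link_matrix(stack)
  coefs <- qr.coef(qx, w)
  cleaned <- w - x %*% coefs
  cleaned <- sweep(cleaned, 2, coefs[1, ], "+") # keep the fitted intercept
  stack_from_link_matrix(stack, cleaned)
}

#' Threshold a connectivity matrix to a fixed link density
#'
#' Keeps the `k = round(density * R(R-1)/2)` largest off-diagonal weights and
#' zeroes the rest, so every subject's graph carries the same number of
#' links. Ranking is by signed value by default (`mode = "signed"`); ties at
#' the cutoff are broken deterministically toward the lower (row, col) index.
#'
#' @param m Symmetric R x R weight matrix, zero diagonal.
#' @param density Fraction of links to keep, in (0, 1].
#' @param binarize If `TRUE`, surviving links are set to 1.
#' @param mode Rank links by `"signed"` value or by `"absolute"` value.
#' @return The thresholded matrix.
#' @export
threshold_density <- function(m, density = 0.07, binarize = FALSE,
                              mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  check_square_symmetric(m, what = "connectivity matrix")
  stopifnot(density > 0, density <= 1)
  r <- nrow(m)
  n_links <- r * (r - 1) / 2
  k <- round(density * n_links)
  if (k == 0) stop("density ", density, " keeps zero links for R = ", r)
  v <- links_of(m)
  key <- if (mode == "signed") v else abs(v)
  pairs <- link_pairs(r)
  ord <- order(-key, pairs[, 1], pairs[, 2])
  keep <- logical(n_links)
  keep[ord[seq_len(k)]] <- TRUE
  out <- if (binarize) as.numeric(keep) else v * keep
  mat_from_links(out, r)
}

#' Threshold every matrix of a stack
#'
#' @inheritParams threshold_density
#' @param stack A `matrix_stack` in r space.
#' @return The thresholded stack.
#' @export
threshold_stack <- function(stack, density = 0.07, binarize = FALSE,
                            mode = c("signed", "absolute")) {
  stopifnot(inherits(stack, "matrix_stack"))
  mode <- match.arg(mode)
  stack$matrices <- lapply(stack$matrices, threshold_density,
                           density = density, binarize = binarize, mode = mode)
  stack
}
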