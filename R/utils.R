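# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded operations never perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Counter scheme used to give each stage of a sweep its own independent but
#' reproducible RNG stream: `(master + 104729 * index) mod (2^31 - 1)`.
#'
#' @param master Integer master seed.
#' @param index Nonnegative integer counter (e.g. kernel position).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index))
  as.integer((as.numeric(master) + 104729 * as.numeric(index)) %% 2147483647)
}

# Upper-triangle link bookkeeping. Links of an R-node network are the pairs
# (i, j), i < j, enumerated in the column-major order of upper.tri(), so that
# mat[upper.tri(mat)] and these pairs stay aligned everywhere.

#' Enumerate the links (node pairs) of an R-node network
#'
#' @param n_nodes Number of nodes R.
#' @return A two-column integer matrix with one row per link (i < j), in the
#'   column-major order of `upper.tri`.
#' @export
link_pairs <- function(n_nodes) {
  stopifnot(n_nodes >= 1)
  idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)))
  cbind(i = as.integer((idx - 1) %% n_nodes + 1),
        j = as.integer((idx - 1) %/% n_nodes + 1))
}

#' @keywords internal
#' @noRd
links_of <- function(m) m[upper.tri(m)]

#' @keywords internal
#' @noRd
mat_from_links <- function(v, n_nodes, diag_value = 0) {
  m <- matrix(diag_value, n_nodes, n_nodes)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}

#' @keywords internal
#' @noRd
check_square_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(what, " must be symmetric (max asymmetry > ", tol, ")", call. = FALSE)
  invisible(m)
}
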