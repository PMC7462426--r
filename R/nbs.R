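# The network-based statistic (NBS): link-wise two-group F statistics,
# breadth-first search for connected components of suprathreshold links, and
# a permutation null of the maximal component size (in links). Component
# extent is the only statistic used for family-wise control; no directional
# (under/over-connectivity) assumption is made.

#' NBS configuration
#'
#' @param suprathreshold Primary F cutoff; links with F strictly greater
#'   enter the component search (default 12.25, i.e. |t| = 3.5).
#' @param n_perm Number of group-label permutations M.
#' @param alpha Significance level for component p-values.
#' @param seed Integer seed for the permutation stream (NULL = current RNG).
#' @return An `nbs_config`.
#' @export
nbs_config <- function(suprathreshold = 12.25, n_perm = 5000, alpha = 0.05,
                       seed = NULL) {
  stopifnot(suprathreshold > 0, n_perm >= 1, alpha > 0, alpha < 1)
  structure(list(suprathreshold = suprathreshold, n_perm = as.integer(n_perm),
                 alpha = alpha, seed = seed),
            class = "nbs_config")
}

#' Two-group one-way ANOVA F statistic for a single link
#'
#' With two groups the F statistic on (1, n1 + n2 - 2) degrees of freedom
#' equals the square of the pooled-variance two-sample t statistic. Zero
#' within-group variance gives F = 0 when the means agree and F = Inf (above
#' any threshold) when they differ.
#'
#' @param a,b Numeric link weights for the two groups (each length >= 2).
#' @return The F value.
#' @export
link_f_statistic <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 subjects")
  drop(group_f_statistics(rbind(matrix(a, ncol = 1), matrix(b, ncol = 1)),
                          rep(c(TRUE, FALSE), c(length(a), length(b)))))
}

# Vectorised F over the columns of w (subjects x links); g1 flags group 1.
group_f_statistics <- function(w, g1) {
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(w[g1, , drop = FALSE])
  m2 <- colMeans(w[!g1, , drop = FALSE])
  ss1 <- colSums(sweep(w[g1, , drop = FALSE], 2, m1)^2)
  ss2 <- colSums(sweep(w[!g1, , drop = FALSE], 2, m2)^2)
  ssb <- n1 * n2 / (n1 + n2) * (m1 - m2)^2
  msw <- (ss1 + ss2) / (n1 + n2 - 2)
  f <- ssb / msw
  f[msw == 0 & ssb == 0] <- 0
  f[msw == 0 & ssb > 0] <- Inf
  f
}

#' Connected components of suprathreshold links
#'
#' Thresholds a symmetric link-statistic matrix at `threshold` (strict
#' inequality) and finds the connected components of the surviving links by
#' breadth-first search. Component size is measured in links.
#'
#' @param f_matrix Symmetric R x R statistic matrix; diagonal ignored.
#' @param threshold Primary cutoff.
#' @return A list of components ordered by (link count desc, smallest
#'   incident node asc); each has `nodes`, `links` (two-column matrix of node
#'   pairs) and `n_links`.
#' @export
suprathreshold_components <- function(f_matrix, threshold) {
  check_square_symmetric(f_matrix, what = "statistic matrix")
  r <- nrow(f_matrix)
  adj <- f_matrix > threshold
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  comps <- list()
  visited <- logical(r)
  for (start in which(deg > 0)) {
    if (visited[start]) next
    # breadth-first search from `start`
    queue <- start
    visited[start] <- TRUE
    nodes <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nodes <- c(nodes, v)
      nb <- which(adj[v, ] & !visited)
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    nodes <- sort(nodes)
    sub <- adj[nodes, nodes, drop = FALSE]
    pr <- which(upper.tri(sub) & sub, arr.ind = TRUE)
    links <- cbind(nodes[pr[, 1]], nodes[pr[, 2]])
    links <- links[order(links[, 1], links[, 2]), , drop = FALSE]
    comps[[length(comps) + 1]] <- list(nodes = nodes, links = links,
                                       n_links = nrow(links))
  }
  if (length(comps) == 0) return(comps)
  sizes <- vapply(comps, `[[`, 0, "n_links")
  mins <- vapply(comps, function(cc) min(cc$nodes), 0)
  comps[order(-sizes, mins)]
}

# Maximal component link count of a thresholded statistic vector (links of
# the upper triangle). Fast path for the permutation loop.
max_component_size <- function(f_links, pairs, n_nodes, threshold) {
  sup <- which(f_links > threshold)
  if (length(sup) == 0) return(0L)
  if (length(sup) == 1) return(1L)
  e <- pairs[sup, , drop = FALSE]
  # union-find over the incident nodes
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(e))) {
    ra <- find(e[k, 1]); rb <- find(e[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(e[, 1], find, 0L)
  max(tabulate(roots, nbins = n_nodes))
}

#' Run the network-based statistic on a matrix stack
#'
#' The six steps: (1) a two-group F statistic per link, (2) thresholding at
#' `suprathreshold`, (3) breadth-first search for connected components of the
#' surviving links, (4-5) M group-label permutations (group sizes preserved)
#' each recording the maximal component link count, (6) the p-value of each
#' observed component as `(1 + #\{perm max >= size\}) / (M + 1)`. Subjects are
#' canonicalised by (group, id) before permuting, so p-values do not depend
#' on input order.
#'
#' @param stack A `matrix_stack` (two groups, each >= 2 subjects), normally
#'   in r space (the cleaned, inverse-Fisher matrices).
#' @param config An [nbs_config()].
#' @return An `nbs_result` with the F matrix, the group mean-difference
#'   matrix (first group level minus second), observed components with
#'   p-values, the null maximal sizes, and the significant components.
#' @export
nbs_test <- function(stack, config = nbs_config()) {
  stopifnot(inherits(stack, "matrix_stack"), inherits(config, "nbs_config"))
  ord <- order(as.character(stack$subjects$group), as.character(stack$subjects$id))
  subjects <- stack$subjects[ord, , drop = FALSE]
  w <- stack_link_matrix(stack)[ord, , drop = FALSE]
  glev <- sort(unique(as.character(subjects$group)))
  g1 <- as.character(subjects$group) == glev[1]
  if (sum(g1) < 2 || sum(!g1) < 2) stop("each group needs >= 2 subjects")
  r <- stack$n_rois
  pairs <- link_pairs(r)
  f_links <- group_f_statistics(w, g1)
  f_matrix <- mat_from_links(f_links, r)
  m1 <- colMeans(w[g1, , drop = FALSE])
  m2 <- colMeans(w[!g1, , drop = FALSE])
  diff_matrix <- mat_from_links(m1 - m2, r)
  comps <- suprathreshold_components(f_matrix, config$suprathreshold)
  n <- nrow(w)
  null_max <- with_seed(config$seed, {
    vapply(seq_len(config$n_perm), function(b) {
      perm <- logical(n)
      perm[sample.int(n, sum(g1))] <- TRUE
      max_component_size(group_f_statistics(w, perm), pairs, r,
                         config$suprathreshold)
    }, 0L)
  })
  for (k in seq_along(comps)) {
    comps[[k]]$p_value <- (1 + sum(null_max >= comps[[k]]$n_links)) /
      (config$n_perm + 1)
  }
  significant <- Filter(function(cc) cc$p_value < config$alpha, comps)
  structure(list(f_matrix = f_matrix, diff_matrix = diff_matrix,
                 components = comps, null_max_sizes = null_max,
                 significant = significant, config = config,
                 group_levels = glev,
                 group_sizes = c(sum(g1), sum(!g1))),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("<nbs_result>", length(x$components), "suprathreshold component(s) at F >",
      x$config$suprathreshold, "with", x$config$n_perm, "permutations\n")
  for (cc in x$components)
    cat("  component:", cc$n_links, "links, p =", signif(cc$p_value, 3), "\n")
  invisible(x)
}

#' Select the primary subnetwork from an NBS result
#'
#' Among significant components, returns the largest by link count, ties
#' broken by the smallest incident node index; `NULL` when nothing is
#' significant.
#'
#' @param res An `nbs_result`.
#' @param n_rois ROI count (taken from the result's F matrix).
#' @return A `subnetwork` (binary symmetric `link_mask`, `n_links`,
#'   `p_value`, `links`) or `NULL`.
#' @export
select_primary_subnetwork <- function(res) {
  stopifnot(inherits(res, "nbs_result"))
  if (length(res$significant) == 0) return(NULL)
  cc <- res$significant[[1]] # components are pre-ordered by (size, min node)
  r <- nrow(res$f_matrix)
  mask <- matrix(0L, r, r)
  mask[cc$links] <- 1L
  mask[cc$links[, c(2, 1), drop = FALSE]] <- 1L
  structure(list(link_mask = mask, n_links = cc$n_links,
                 p_value = cc$p_value, links = cc$links, nodes = cc$nodes),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("<subnetwork>", x$n_links, "links over", length(x$nodes),
      "nodes, p =", signif(x$p_value, 3), "\n")
  invisible(x)
}
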