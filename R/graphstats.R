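# Thresholded-network analysis: five graph measures per subject, two-sided
# nonparametric permutation tests on group mean differences (with exhaustive
# enumeration when the relabeling space is small), and Benjamini-Hochberg
# FDR control across nodes or links.

#' Five graph measures of a binary undirected network
#'
#' Degree (neighbour count), clustering coefficient (density of links among
#' a node's neighbours; 0 for degree < 2), local efficiency (global
#' efficiency of the subgraph induced on the node's neighbours; 0 for degree
#' < 2), betweenness centrality (fraction of all-pairs shortest paths through
#' the node, fractional counting over ties, normalised by (R-1)(R-2)/2), and
#' global efficiency (mean inverse shortest-path length over node pairs,
#' disconnected pairs contributing 0).
#'
#' @param adj Symmetric binary R x R adjacency matrix, zero diagonal.
#' @return A list with per-node vectors `degree`, `clustering`,
#'   `local_efficiency`, `betweenness`, and scalars `global_efficiency` and
#'   `mean_clustering`.
#' @export
node_metrics <- function(adj) {
  check_square_symmetric(adj, what = "adjacency matrix")
  if (!all(adj %in% c(0, 1))) stop("adjacency matrix must be binary")
  if (any(diag(adj) != 0)) stop("adjacency matrix must have zero diagonal")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  r <- nrow(adj)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  btw <- if (r > 2) igraph::betweenness(g, normalized = TRUE) else rep(0, r)
  # strict induced-subgraph local efficiency: paths may not leave the
  # neighbour subgraph (igraph's local_efficiency allows detours through the
  # rest of the graph, a different convention)
  leff <- vapply(seq_len(r), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- igraph::graph_from_adjacency_matrix(adj[nb, nb, drop = FALSE],
                                               mode = "undirected")
    igraph::global_efficiency(sub)
  }, 0)
  leff[is.nan(leff)] <- 0 # edgeless neighbour subgraphs
  geff <- igraph::global_efficiency(g)
  list(degree = as.numeric(igraph::degree(g)),
       clustering = as.numeric(cl),
       local_efficiency = leff,
       betweenness = as.numeric(btw),
       global_efficiency = if (is.nan(geff)) 0 else as.numeric(geff),
       mean_clustering = mean(cl))
}

# Shared permutation engine: columns of v are variables, rows subjects.
# Two-sided statistic |mean(A) - mean(B)|. Exhaustive enumeration over all
# choose(n, n1) relabelings when that is <= 10 * n_perm (p = tail fraction,
# identity included); otherwise Monte Carlo with the +1 estimator.
perm_group_pvalues <- function(v, g1, n_perm = 10000, seed = NULL,
                               exhaustive = c("auto", "never", "always")) {
  exhaustive <- match.arg(exhaustive)
  v <- as.matrix(v)
  n <- nrow(v)
  n1 <- sum(g1)
  stopifnot(n1 >= 1, n - n1 >= 1, n_perm >= 1)
  stat_for <- function(sel) {
    abs(colMeans(v[sel, , drop = FALSE]) - colMeans(v[!sel, , drop = FALSE]))
  }
  obs <- stat_for(g1)
  n_total <- choose(n, n1)
  use_ex <- switch(exhaustive,
                   always = TRUE, never = FALSE,
                   auto = n_total <= 10 * n_perm)
  eps <- 1e-12 # permutation stats tying the observed count as >=
  if (use_ex) {
    combos <- utils::combn(n, n1)
    count <- integer(ncol(v))
    for (k in seq_len(ncol(combos))) {
      sel <- logical(n); sel[combos[, k]] <- TRUE
      count <- count + (stat_for(sel) >= obs - eps)
    }
    list(statistic = obs, p = count / ncol(combos),
         method = "exhaustive", n_perm = ncol(combos))
  } else {
    count <- with_seed(seed, {
      cnt <- integer(ncol(v))
      for (b in seq_len(n_perm)) {
        sel <- logical(n); sel[sample.int(n, n1)] <- TRUE
        cnt <- cnt + (stat_for(sel) >= obs - eps)
      }
      cnt
    })
    list(statistic = obs, p = (1 + count) / (n_perm + 1),
         method = "monte-carlo", n_perm = n_perm)
  }
}

#' Two-sided permutation test on a group mean difference
#'
#' Statistic |mean(x) - mean(y)|; the null is built by permuting group
#' labels. When the number of distinct relabelings is at most `10 * n_perm`
#' the test enumerates all of them (exact p = tail fraction); otherwise it
#' Monte-Carlo samples with p = `(1 + #\{perm >= obs\}) / (n_perm + 1)`.
#'
#' @param x,y Numeric samples for the two groups (nonempty).
#' @param n_perm Number of Monte-Carlo permutations.
#' @param seed Integer seed for the Monte-Carlo stream.
#' @param exhaustive `"auto"` (default), `"never"` or `"always"`.
#' @return A list with `statistic`, `p`, `method`, `n_perm`.
#' @export
permutation_test <- function(x, y, n_perm = 10000, seed = NULL,
                             exhaustive = c("auto", "never", "always")) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  res <- perm_group_pvalues(matrix(c(x, y), ncol = 1),
                            rep(c(TRUE, FALSE), c(length(x), length(y))),
                            n_perm = n_perm, seed = seed,
                            exhaustive = match.arg(exhaustive))
  list(statistic = unname(res$statistic), p = unname(res$p),
       method = res$method, n_perm = res$n_perm)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Standard step-up procedure at level `alpha`: reject the hypotheses whose
#' BH-adjusted p-value is at most `alpha`.
#'
#' @param p Vector of p-values in (0, 1].
#' @param alpha FDR level.
#' @return Logical rejection mask aligned with `p`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  stopifnot(all(p > 0), all(p <= 1), alpha > 0, alpha < 1)
  stats::p.adjust(p, method = "BH") <= alpha
}

#' Group comparison of graph measures on density-thresholded networks
#'
#' Thresholds every subject's matrix to the given density, binarizes,
#' computes the five graph measures, then runs a two-sided permutation test
#' per node for each node-level measure (degree, clustering, local
#' efficiency, betweenness) with BH-FDR across nodes, and a single
#' permutation test for each global measure (global efficiency, mean
#' clustering).
#'
#' @param stack A `matrix_stack` in r space.
#' @param density Link density retained (default 0.07).
#' @param n_perm Permutations per measure (default 10000).
#' @param seed Master seed; each measure gets a derived sub-seed.
#' @param alpha FDR level for node-level rejections.
#' @param mode Threshold ranking mode, see [threshold_density()].
#' @return A list with `node_tables` (one data frame per measure: node, stat,
#'   p, q_reject) and `global_table` (measure, stat, p).
#' @export
groupwise_metric_tests <- function(stack, density = 0.07, n_perm = 10000,
                                   seed = NULL, alpha = 0.05,
                                   mode = c("signed", "absolute")) {
  stopifnot(inherits(stack, "matrix_stack"))
  mode <- match.arg(mode)
  bin <- threshold_stack(stack, density = density, binarize = TRUE, mode = mode)
  mets <- lapply(bin$matrices, node_metrics)
  g1 <- as.character(stack$subjects$group) ==
    sort(unique(as.character(stack$subjects$group)))[1]
  node_measures <- c("degree", "clustering", "local_efficiency", "betweenness")
  node_tables <- list()
  for (k in seq_along(node_measures)) {
    v <- t(vapply(mets, `[[`, numeric(stack$n_rois), node_measures[k]))
    res <- perm_group_pvalues(v, g1, n_perm = n_perm,
                              seed = if (is.null(seed)) NULL else derive_seed(seed, k))
    node_tables[[node_measures[k]]] <-
      data.frame(node = seq_len(stack$n_rois), stat = res$statistic,
                 p = res$p, q_reject = bh_fdr(res$p, alpha))
  }
  global_measures <- c("global_efficiency", "mean_clustering")
  gstat <- gp <- numeric(length(global_measures))
  for (k in seq_along(global_measures)) {
    v <- matrix(vapply(mets, `[[`, 0, global_measures[k]), ncol = 1)
    res <- perm_group_pvalues(v, g1, n_perm = n_perm,
                              seed = if (is.null(seed)) NULL else derive_seed(seed, 10 + k))
    gstat[k] <- res$statistic; gp[k] <- res$p
  }
  list(node_tables = node_tables,
       global_table = data.frame(measure = global_measures, stat = gstat, p = gp))
}

#' Link-wise permutation tests on thresholded weighted matrices
#'
#' Thresholds every subject's matrix to the given density (weights kept, not
#' binarized; zeroed links participate as values), runs a two-sided
#' permutation test per link, and controls the FDR across all links by
#' Benjamini-Hochberg.
#'
#' @inheritParams groupwise_metric_tests
#' @return A list with symmetric matrices `p_matrix`, `stat_matrix` and the
#'   logical `reject` mask (diagonal of `p_matrix` set to 1).
#' @export
linkwise_permutation_tests <- function(stack, density = 0.07, n_perm = 10000,
                                       seed = NULL, alpha = 0.05,
                                       mode = c("signed", "absolute")) {
  stopifnot(inherits(stack, "matrix_stack"))
  mode <- match.arg(mode)
  thr <- threshold_stack(stack, density = density, binarize = FALSE, mode = mode)
  w <- stack_link_matrix(thr)
  g1 <- as.character(stack$subjects$group) ==
    sort(unique(as.character(stack$subjects$group)))[1]
  res <- perm_group_pvalues(w, g1, n_perm = n_perm, seed = seed)
  rej <- bh_fdr(res$p, alpha)
  p_matrix <- mat_from_links(res$p, stack$n_rois, diag_value = 1)
  diag(p_matrix) <- 1
  list(p_matrix = p_matrix,
       stat_matrix = mat_from_links(res$statistic, stack$n_rois),
       reject = mat_from_links(as.numeric(rej), stack$n_rois) > 0)
}
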