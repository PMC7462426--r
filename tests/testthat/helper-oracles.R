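# Independent brute-force oracles and small fixture builders used across the
# suite. Every oracle is written from the definition, sharing no code with
# the implementation it checks.

# Brute-force mask-aware Gaussian smoothing: per-voxel double loop over the
# weighted-average definition, per-axis support of 4 sigma.
bf_gaussian_smooth <- function(volume, fwhm) {
  if (fwhm == 0) return(volume$series)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  rad <- 4 * sigma
  co <- voxel_coords(volume$grid, arrayInd(which(volume$mask), volume$grid$dims))
  out <- volume$series
  for (i in seq_len(nrow(co))) {
    d <- sweep(co, 2, co[i, ])
    w <- exp(-rowSums(d^2) / (2 * sigma^2))
    w[abs(d[, 1]) > rad | abs(d[, 2]) > rad | abs(d[, 3]) > rad] <- 0
    out[i, ] <- colSums(w * volume$series) / sum(w)
  }
  out
}

# Union-find connected components of links with statistic > threshold;
# returns sorted link counts (descending).
uf_component_sizes <- function(f_matrix, threshold) {
  r <- nrow(f_matrix)
  parent <- seq_len(r)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  links <- which(upper.tri(f_matrix) & f_matrix > threshold, arr.ind = TRUE)
  if (nrow(links) == 0) return(integer(0))
  for (k in seq_len(nrow(links))) {
    a <- find(links[k, 1]); b <- find(links[k, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(links[, 1], find, 0L)
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# All-pairs BFS distances and shortest-path counts of a binary graph.
bf_bfs_all <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  npaths <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sig <- rep(0, n)
    d[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] > 0)) {
        if (!is.finite(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
        if (d[w] == d[v] + 1) sig[w] <- sig[w] + sig[v]
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d; npaths[s, ] <- sig
  }
  list(dist = dist, npaths = npaths)
}

# The five graph measures from their definitions.
bf_node_metrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  bfs <- bf_bfs_all(adj)
  d <- bfs$dist; sig <- bfs$npaths
  clustering <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    t2 <- sum(adj[nb, nb]) / 2
    2 * t2 / (length(nb) * (length(nb) - 1))
  }, 0)
  geff <- function(a) {
    m <- nrow(a)
    if (m < 2) return(0)
    dd <- bf_bfs_all(a)$dist
    inv <- 1 / dd; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
    sum(inv) / (m * (m - 1))
  }
  local_eff <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    geff(adj[nb, nb, drop = FALSE])
  }, 0)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
    }
  }
  btw <- if (n > 2) btw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  list(degree = deg, clustering = clustering, local_efficiency = local_eff,
       betweenness = btw, global_efficiency = geff(adj),
       mean_clustering = mean(clustering))
}

# Literal Benjamini-Hochberg step-up: sort ascending, find the largest k
# with p_(k) <= k * alpha / m, reject hypotheses 1..k.
bf_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(ok)) reject[ord[seq_len(max(ok))]] <- TRUE
  reject
}

# Random symmetric statistic matrix with zero diagonal.
rand_sym <- function(n, fn = stats::runif) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- fn(n * (n - 1) / 2)
  m + t(m)
}

# Random Erdos-Renyi binary adjacency matrix.
rand_adj <- function(n, p = 0.3) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  m + t(m)
}

# A stack of null connectivity matrices: every subject's matrix is the
# Pearson matrix of independent series, so the groups are exchangeable.
make_null_stack <- function(n_per_group = 6, n_rois = 8, n_t = 64, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    mats <- lapply(seq_len(2 * n_per_group), function(s)
      pearson_matrix(matrix(rnorm(n_rois * n_t), n_rois, n_t)))
    subjects <- data.frame(
      id = sprintf("s%02d", seq_len(2 * n_per_group)),
      group = rep(c("patient", "control"), each = n_per_group),
      site = rep_len(c("siteA", "siteB"), 2 * n_per_group),
      mean_fd = runif(2 * n_per_group, 0.05, 0.4),
      gender = rep_len(c("M", "F"), 2 * n_per_group))
    matrix_stack(subjects, mats, space = "r")
  })
}

# Tiny masked volume with random series.
make_test_volume <- function(dims = c(8, 8, 8), voxel = 2, n_t = 3,
                             mask_frac = 1, seed = 1) {
  set.seed(seed)
  g <- volume_grid(dims, voxel)
  mask <- array(runif(prod(dims)) <= mask_frac, dims)
  if (!any(mask)) mask[1] <- TRUE
  brain_volume4d(g, mask, matrix(rnorm(sum(mask) * n_t), ncol = n_t), tr = 2)
}

# Rebuild a symmetric zero-diagonal matrix from upper-triangle values.
mat_from_links_test <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}
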