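# The network-based statistic: F statistics, component search, permutation
# null, and subnetwork selection.

test_that("link F statistic matches hand ANOVA and equals t squared", {
  expect_equal(link_f_statistic(c(1, 2, 3), c(4, 5, 6)), 13.5)
  expect_equal(link_f_statistic(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_equal(link_f_statistic(c(1, 1), c(2, 2)), Inf)
  expect_error(link_f_statistic(1, c(2, 3)), ">= 2")
  set.seed(71)
  for (k in 1:100) {
    a <- rnorm(sample(3:9, 1))
    b <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    f <- link_f_statistic(a, b)
    t_ref <- t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t_ref)^2, tolerance = 1e-9)
  }
})

test_that("suprathreshold components match a union-find oracle", {
  # empty and path-graph base cases
  expect_length(suprathreshold_components(rand_sym(5) * 0, 1), 0)
  chain <- matrix(0, 4, 4)
  chain[cbind(1:3, 2:4)] <- 5
  chain <- chain + t(chain)
  comps <- suprathreshold_components(chain, 1)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_links, 3)
  expect_equal(comps[[1]]$nodes, 1:4)
  # threshold is a strict inequality
  expect_length(suprathreshold_components(chain, 5), 0)
  # random graphs against the oracle
  set.seed(72)
  for (k in 1:50) {
    f <- rand_sym(12, function(n) runif(n, 0, 2))
    thr <- runif(1, 0.5, 1.8)
    got <- vapply(suprathreshold_components(f, thr), `[[`, 0, "n_links")
    expect_equal(as.numeric(got), as.numeric(uf_component_sizes(f, thr)))
  }
})

test_that("raising the suprathreshold never grows a component", {
  set.seed(73)
  f <- rand_sym(10, function(n) runif(n, 0, 3))
  sizes <- sapply(c(0.5, 1, 1.5, 2, 2.5), function(thr) {
    comps <- suprathreshold_components(f, thr)
    if (length(comps)) max(vapply(comps, `[[`, 0, "n_links")) else 0
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("nbs_test p-values respect the +1 floor and detect planted effects", {
  spec <- cohort_spec(n_per_group = 10, n_rois = 10, n_timepoints = 256,
                      delta = 0.45, base_corr = 0.1, seed = 81)
  stack <- cohort_stack(generate_cohort(spec, mode = "series"))
  res <- nbs_test(stack, nbs_config(suprathreshold = 12.25, n_perm = 99,
                                    seed = 5))
  expect_length(res$null_max_sizes, 99)
  for (cc in res$components) {
    expect_gte(cc$p_value, 1 / 100)
    expect_lte(cc$p_value, 1)
  }
  sub <- select_primary_subnetwork(res)
  expect_false(is.null(sub))
  planted <- spec$planted_links
  expect_gte(sum(sub$link_mask[planted]), 4)
})

test_that("nbs_test is deterministic and invariant to subject order", {
  stack <- make_null_stack(5, 8, seed = 82)
  cfg <- nbs_config(suprathreshold = 4, n_perm = 200, seed = 9)
  r1 <- nbs_test(stack, cfg)
  r2 <- nbs_test(stack, cfg)
  expect_identical(r1$null_max_sizes, r2$null_max_sizes)
  perm <- rev(seq_along(stack$matrices))
  shuffled <- matrix_stack(stack$subjects[perm, ], stack$matrices[perm],
                           space = "r")
  r3 <- nbs_test(shuffled, cfg)
  expect_identical(r1$null_max_sizes, r3$null_max_sizes)
  expect_equal(r1$f_matrix, r3$f_matrix)
})

test_that("small-sample Monte-Carlo p brackets the full-enumeration p", {
  # n1 = n2 = 3: only 20 relabelings, enumerable exactly
  set.seed(83)
  r <- 6
  mats <- lapply(1:6, function(s) rand_sym(r, rnorm))
  subjects <- data.frame(id = paste0("s", 1:6),
                         group = rep(c("patient", "control"), each = 3),
                         site = "siteA", mean_fd = 0.1, gender = "M")
  stack <- matrix_stack(subjects, mats, space = "r")
  thr <- 4
  pairs <- link_pairs(r)
  w <- t(sapply(mats, function(m) m[upper.tri(m)]))
  combos <- combn(6, 3)
  exact_null <- apply(combos, 2, function(sel) {
    g1 <- seq_len(6) %in% sel
    f <- sapply(seq_len(ncol(w)), function(l)
      link_f_statistic(w[g1, l], w[!g1, l]))
    sizes <- uf_component_sizes(mat_from_links_test(f, r), thr)
    if (length(sizes)) max(sizes) else 0
  })
  res <- nbs_test(stack, nbs_config(suprathreshold = thr, n_perm = 500,
                                    seed = 11))
  for (cc in res$components) {
    p_exact <- mean(exact_null >= cc$n_links)
    se <- sqrt(p_exact * (1 - p_exact) / 500)
    expect_lt(abs(cc$p_value - p_exact), 3 * se + 1 / 501)
  }
})

test_that("primary subnetwork selection breaks ties toward the smallest node", {
  # two disjoint triangles, equal size; the one containing node 1 wins
  f <- matrix(0, 8, 8)
  tri1 <- rbind(c(1, 3), c(3, 5), c(1, 5))
  tri2 <- rbind(c(2, 4), c(4, 6), c(2, 6))
  f[tri1] <- 9; f[tri2] <- 9
  f <- f + t(f)
  comps <- suprathreshold_components(f, 5)
  expect_length(comps, 2)
  expect_equal(comps[[1]]$nodes, c(1, 3, 5))
  fake <- structure(list(f_matrix = f,
                         significant = comps, components = comps,
                         config = nbs_config()), class = "nbs_result")
  for (k in seq_along(fake$significant)) fake$significant[[k]]$p_value <- 0.01
  sub <- select_primary_subnetwork(fake)
  expect_equal(sub$nodes, c(1, 3, 5))
  # no significant components -> NULL
  fake$significant <- list()
  expect_null(select_primary_subnetwork(fake))
})
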