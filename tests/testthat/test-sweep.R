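# Sweep-level quantities: effect sizes, Hamming distances, Spearman
# correlation, link persistence, and the end-to-end kernel sweep.

test_that("Cohen's d from F matches the t-based effect size", {
  expect_equal(cohens_d_from_f(0, 10, 10), 0)
  expect_equal(cohens_d_from_f(12.25, 47, 47), 3.5 * sqrt(2 / 47))
  expect_equal(cohens_d_from_f(12.25, 47, 47), 0.722, tolerance = 1e-3)
  set.seed(101)
  for (k in 1:100) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    a <- rnorm(n1); b <- rnorm(n2, mean = runif(1, -1, 1))
    t_stat <- t.test(a, b, var.equal = TRUE)$statistic
    d_t <- unname(t_stat) * sqrt(1 / n1 + 1 / n2)
    d_f <- cohens_d_from_f(link_f_statistic(a, b), n1, n2,
                           sign_source = mean(a) - mean(b))
    expect_equal(d_f, d_t, tolerance = 1e-9)
  }
})

test_that("Hamming distance counts differing links and treats NULL as empty", {
  a <- mat_from_links_test(c(1, 0, 1, 0, 1, 0), 4)
  b <- mat_from_links_test(c(1, 0, 0, 0, 1, 0), 4)
  expect_equal(hamming_distance(a, a), 0)
  expect_equal(hamming_distance(a, b), 1)
  expect_equal(hamming_distance(a, NULL), 3) # n_links of a
  expect_equal(hamming_distance(NULL, NULL, n_rois = 4), 0)
  expect_error(hamming_distance(a, mat_from_links_test(rep(1, 3), 3)),
               "different ROI counts")
  expect_error(hamming_distance(a * 0.5, b), "binary")
})

test_that("Spearman correlation handles monotone and tied data", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(x, -x^3), -1)
  expect_error(spearman_rho(x, rep(2, 5)), "constant")
  set.seed(102)
  for (k in 1:20) {
    a <- sample(1:5, 12, replace = TRUE) # heavy ties
    b <- a + rnorm(12)
    manual <- cor(rank(a), rank(b)) # average ranks, then Pearson
    expect_equal(spearman_rho(a, b), manual, tolerance = 1e-12)
  }
})

test_that("link persistence tallies kernels per link with the stated ordering", {
  r <- 5
  mk <- function(links) {
    m <- matrix(0L, r, r); m[links] <- 1L; m[links[, 2:1, drop = FALSE]] <- 1L
    structure(list(link_mask = m, n_links = nrow(links),
                   p_value = 0.01, links = links), class = "subnetwork")
  }
  subs <- list(mk(rbind(c(1, 2), c(2, 3))),
               mk(rbind(c(1, 2), c(2, 3))),
               mk(rbind(c(1, 2), c(4, 5))))
  out <- link_persistence(subs, fwhms = c(0, 4, 8), n_rois = r)
  tab <- out$table
  expect_equal(out$summary$n_links_any, 3)
  expect_equal(out$summary$n_links_all, 1) # link 1-2 everywhere
  expect_equal(out$summary$n_links_75pct, 1) # >= ceil(0.75*3) = 3 kernels
  expect_equal(tab$first_fwhm, c(0, 0, 8)) # smallest first-kernel first
  expect_equal(tab$n_kernels[tab$roi_a == 1 & tab$roi_b == 2], 3)
  expect_equal(tab$kernels[tab$roi_a == 4], "8")
  # identical subnetworks at all kernels: every link has count K
  same <- link_persistence(subs[c(1, 1, 1)], c(0, 4, 8), r)
  expect_true(all(same$table$n_kernels == 3))
})

test_that("run_sweep detects the planted subnetwork and yields coherent summaries", {
  spec <- cohort_spec(n_per_group = 10, n_rois = 12, n_timepoints = 128,
                      delta = 0.4, seed = 5)
  cohort <- generate_cohort(spec, mode = "volumes")
  sw <- run_sweep(cohort, fwhms = c(0, 4, 8), suprathreshold = 12.25,
                  n_perm = 200, seed = 3)
  k <- 3
  # the planted links dominate the detections at most kernels
  planted <- spec$planted_links
  hits <- vapply(sw$subnetworks, function(s)
    if (is.null(s)) 0 else sum(s$link_mask[planted]), 0)
  expect_gte(sum(hits >= 4), 2)
  # Hamming matrix is a metric
  expect_equal(sw$hamming, t(sw$hamming))
  expect_true(all(diag(sw$hamming) == 0))
  for (a in 1:k) for (b in 1:k) for (cc in 1:k)
    expect_lte(sw$hamming[a, b], sw$hamming[a, cc] + sw$hamming[cc, b])
  # d grid covers the ever-significant links at every kernel, signed
  expect_equal(ncol(sw$d_grid), k)
  expect_equal(nrow(sw$d_grid), sw$persistence$summary$n_links_any)
  expect_true(all(is.finite(sw$d_grid)))
  # planted links should show positive d (patients more correlated)
  planted_rows <- rownames(sw$d_grid) %in%
    paste0(planted[, 1], "-", planted[, 2])
  expect_true(all(sw$d_grid[planted_rows, ] > 0))
  expect_true(all(sw$rho >= -1 & sw$rho <= 1))
  expect_length(sw$length_distributions, k)
  # reproducibility: the same seed reproduces the whole result
  sw2 <- run_sweep(cohort, fwhms = c(0, 4, 8), suprathreshold = 12.25,
                   n_perm = 200, seed = 3)
  expect_identical(sw, sw2)
})

test_that("rho over all links ignores the suprathreshold", {
  spec <- cohort_spec(n_per_group = 8, n_rois = 10, n_timepoints = 96,
                      delta = 0.3, seed = 9)
  cohort <- generate_cohort(spec, mode = "volumes")
  a <- run_sweep(cohort, fwhms = c(0, 4), suprathreshold = 12.25,
                 n_perm = 50, seed = 2)
  b <- run_sweep(cohort, fwhms = c(0, 4), suprathreshold = 30,
                 n_perm = 50, seed = 2)
  expect_equal(a$rho, b$rho)
})

test_that("flipping group labels negates every entry of the d grid", {
  spec <- cohort_spec(n_per_group = 10, n_rois = 10, n_timepoints = 128,
                      delta = 0.45, seed = 13)
  cohort <- generate_cohort(spec, mode = "volumes")
  flipped <- cohort
  flipped$subjects$group <- ifelse(cohort$subjects$group == "patient",
                                   "control", "patient")
  a <- run_sweep(cohort, fwhms = c(0, 4), n_perm = 100, seed = 4)
  b <- run_sweep(flipped, fwhms = c(0, 4), n_perm = 100, seed = 4)
  common <- intersect(rownames(a$d_grid), rownames(b$d_grid))
  expect_gte(length(common), 4) # the strong planted chain is found both ways
  expect_equal(b$d_grid[common, ], -a$d_grid[common, ], tolerance = 1e-9)
})
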