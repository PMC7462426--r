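# Gaussian smoothing, smoothness estimation, and blur-to-target.

test_that("fwhm/sigma conversion is exact and round-trips", {
  expect_identical(fwhm_to_sigma(0), 0)
  expect_equal(fwhm_to_sigma(8), 3.39728, tolerance = 1e-5)
  expect_equal(sigma_to_fwhm(fwhm_to_sigma(c(0, 2, 8, 32))), c(0, 2, 8, 32))
  expect_error(fwhm_to_sigma(-1), "nonnegative")
  k <- smoothing_kernel(8)
  expect_equal(k$truncation_radius, 4 * k$sigma)
})

test_that("smoothing a constant field returns it unchanged, FWHM 0 is identity", {
  vol <- make_test_volume(c(6, 6, 6), mask_frac = 0.5, seed = 3)
  expect_identical(gaussian_smooth(vol, 0), vol)
  const <- vol
  const$series[] <- 7.5
  for (f in c(4, 12)) {
    sm <- gaussian_smooth(const, f)
    expect_equal(sm$series, const$series, tolerance = 1e-12)
    expect_identical(sm$mask, const$mask)
  }
})

test_that("all smoothing paths match the brute-force weighted-average oracle", {
  vol <- make_test_volume(c(12, 12, 12), mask_frac = 0.4, seed = 7)
  # unit impulse plus random frames, several kernels
  vol$series[, 1] <- 0
  vol$series[10, 1] <- 1
  for (f in c(4, 6, 10)) {
    expected <- bf_gaussian_smooth(vol, f)
    expect_lt(max(abs(gaussian_smooth(vol, f, method = "operator")$series -
                        expected)), 1e-10)
    expect_lt(max(abs(gaussian_smooth(vol, f, method = "shift")$series -
                        expected)), 1e-10)
  }
})

test_that("3D smoothing equals sequential 1D smoothing on a full mask", {
  vol <- make_test_volume(c(10, 9, 8), n_t = 2, seed = 11)
  for (f in c(4, 8, 16)) {
    a <- gaussian_smooth(vol, f, method = "separable")$series
    b <- gaussian_smooth(vol, f, method = "operator")$series
    expect_lt(max(abs(a - b)), 1e-8)
  }
})

test_that("smoothing preserves the spatial mean of interior-supported fields", {
  # with the field zero within kernel range of the boundary, every source
  # voxel's weights are fully normalised, so frame means are conserved
  g <- volume_grid(c(20, 20, 20), 2)
  set.seed(5)
  fwhm <- 4
  rad <- ceiling(4 * fwhm_to_sigma(fwhm) / 2) # in voxels
  arr <- array(0, c(20, 20, 20, 2))
  core <- (2 * rad + 1):(20 - 2 * rad)
  arr[core, core, core, ] <- rnorm(length(core)^3 * 2)
  vol <- volume_from_array(arr, g, tr = 2)
  sm <- gaussian_smooth(vol, fwhm)
  for (t in 1:2)
    expect_equal(mean(sm$series[, t]), mean(vol$series[, t]),
                 tolerance = 1e-8)
})

test_that("smoothing homogenises voxel series monotonically over the sweep", {
  mean_cor <- function(v) {
    cc <- cor(t(v$series))
    mean(cc[upper.tri(cc)])
  }
  for (seed in 1:5) {
    spec <- cohort_spec(n_per_group = 2, n_rois = 6, n_timepoints = 48,
                        seed = seed)
    parc <- block_parcellation(spec)
    cv <- make_group_covariances(spec)$control
    series <- generate_roi_series(cv, 48, seed = seed)
    vol <- generate_subject_volume(parc, series, spec, seed = seed)
    sweep_out <- kernel_sweep_smooth(vol, c(0, 4, 8, 12))
    homog <- vapply(sweep_out, mean_cor, 0)
    expect_true(all(diff(homog) >= -1e-10))
  }
})

test_that("the default sweep holds sixteen kernels and order is preserved", {
  expect_length(default_kernel_sweep(), 16)
  expect_equal(default_kernel_sweep()[1:3], c(0, 4, 6))
  vol <- make_test_volume(c(5, 5, 5), seed = 2)
  out <- kernel_sweep_smooth(vol, c(0, 6))
  expect_length(out, 2)
  expect_identical(out[[1]], vol)
  expect_error(kernel_sweep_smooth(vol, c(4, 4)), "strictly increasing")
})

test_that("smoothness estimation recovers applied kernels and degrades to voxel scale on white noise", {
  g <- volume_grid(c(40, 40, 40), 2)
  ests <- sapply(1:4, function(seed) {
    set.seed(seed)
    wn <- brain_volume4d(g, array(TRUE, g$dims),
                         matrix(rnorm(40^3 * 2), ncol = 2), tr = 2)
    c(white = estimate_smoothness(wn),
      f8 = estimate_smoothness(gaussian_smooth(wn, 8)))
  })
  expect_true(all(ests["white", ] <= 2.5))
  expect_true(all(ests["f8", ] > 6.8 & ests["f8", ] < 9.2))
})

test_that("smoothness estimate is invariant to shifts and scalings", {
  vol <- make_test_volume(c(16, 16, 16), n_t = 2, seed = 9)
  vol <- gaussian_smooth(vol, 6)
  base <- estimate_smoothness(vol)
  shifted <- vol; shifted$series <- shifted$series + 100
  scaled <- vol; scaled$series <- scaled$series * 0.01
  expect_equal(estimate_smoothness(shifted), base, tolerance = 1e-9)
  expect_equal(estimate_smoothness(scaled), base, tolerance = 1e-9)
  const <- vol; const$series[] <- 1
  expect_error(estimate_smoothness(const), "constant")
})

test_that("blur_to_fwhm reaches the target and refuses to unsmooth", {
  g <- volume_grid(c(30, 30, 30), 2)
  set.seed(21)
  wn <- brain_volume4d(g, array(TRUE, g$dims),
                       matrix(rnorm(30^3 * 2), ncol = 2), tr = 2)
  out <- blur_to_fwhm(wn, 6)
  expect_true(attr(out, "blur_converged"))
  expect_lt(abs(attr(out, "blur_fwhm_estimate") - 6) / 6, 0.1)
  # already at target: no further smoothing
  again <- blur_to_fwhm(out, attr(out, "blur_fwhm_estimate"))
  expect_identical(attr(again, "blur_steps"), 0L)
  # target below current smoothness: warning flag, input returned
  expect_warning(down <- blur_to_fwhm(out, 3), "already smoother")
  expect_true(attr(down, "blur_already_smoother"))
  expect_equal(down$series, out$series)
})
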