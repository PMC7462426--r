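# Synthetic cohort generator: planted covariances, band-limited series,
# voxel rendering, and cohort-level bookkeeping.

test_that("group covariances carry the planted contrast and repair to PSD", {
  # null case: no contrast, identical matrices
  s0 <- cohort_spec(delta = 0, seed = 1)
  cv0 <- make_group_covariances(s0)
  expect_identical(cv0$control, cv0$patient)
  # hand-checkable 3x3: single planted link on a zero background is already
  # PSD (eigenvalues 1.5, 1, 0.5), so no repair happens
  s3 <- cohort_spec(n_rois = 3, base_corr = 0, delta = 0.5,
                    planted_links = cbind(1, 2), seed = 1)
  cv3 <- make_group_covariances(s3)
  expect_equal(cv3$control, diag(3))
  expect_equal(cv3$patient[1, 2], 0.5)
  expect_equal(sum(abs(cv3$patient)), 3 + 2 * 0.5)
  expect_equal(sort(eigen(cv3$patient)$values), c(0.5, 1, 1.5))
  expect_equal(cv3$ground_truth$delta_achieved, 0.5)
  # chain on a correlated background: achieved contrast close to requested
  s10 <- cohort_spec(n_rois = 10, base_corr = 0.2, delta = 0.3, seed = 1)
  cv10 <- make_group_covariances(s10)
  expect_true(all(abs(cv10$ground_truth$delta_achieved - 0.3) < 0.02))
  expect_gte(min(eigen(cv10$patient)$values), -1e-12)
  expect_equal(diag(cv10$patient), rep(1, 10))
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(base_corr = 0.6, delta = 0.5), "< 1")
  expect_error(cohort_spec(n_per_group = 1), ">= 2")
  expect_error(cohort_spec(planted_links = rbind(c(1, 2), c(4, 5))),
               "connected")
  expect_error(cohort_spec(planted_links = cbind(2, 1)), "i < j")
})

test_that("generated ROI series match the requested correlation structure", {
  # independent rows: off-diagonal correlations are sampling noise
  x <- generate_roi_series(diag(8), 1024, seed = 4)
  cc <- cor(t(x))
  expect_lt(abs(mean(cc[upper.tri(cc)])), 3 / sqrt(1024))
  expect_equal(rowMeans(x), rep(0, 8), tolerance = 1e-12)
  expect_equal(apply(x, 1, sd), rep(1, 8), tolerance = 0.05)
  # a planted 0.8 pair is recovered within the Fisher-z sampling interval
  cv <- diag(3); cv[1, 2] <- cv[2, 1] <- 0.8
  y <- generate_roi_series(cv, 4096, seed = 11)
  expect_gt(cor(y[1, ], y[2, ]), 0.74)
  expect_lt(cor(y[1, ], y[2, ]), 0.86)
})

test_that("series are band-limited with out-of-band attenuation >= 20 dB", {
  tr <- 2
  x <- generate_roi_series(diag(4), 512, tr = tr, band = c(0.01, 0.08),
                           seed = 2)
  for (r in 1:4) {
    spec <- Mod(fft(x[r, ]))^2
    f <- (seq_len(512) - 1) / (512 * tr)
    f <- pmin(f, 1 / tr - f)
    inband <- f >= 0.01 & f <= 0.08
    att <- 10 * log10(mean(spec[inband]) / max(mean(spec[!inband]), 1e-300))
    expect_gte(att, 20)
  }
  expect_error(generate_roi_series(diag(3), 64, tr = 2, band = c(0.01, 0.3)),
               "Nyquist")
  # full-band request reduces to correlated white noise (no masking applied)
  full <- generate_roi_series(diag(3), 64, tr = 2, band = c(0, 0.25), seed = 3)
  expect_equal(dim(full), c(3, 64))
})

test_that("noise-free volumes reproduce the latent ROI series exactly", {
  spec <- cohort_spec(n_rois = 6, voxel_noise_sd = 0, seed = 8)
  parc <- block_parcellation(spec)
  series <- generate_roi_series(diag(6), 32, seed = 8)
  vol <- generate_subject_volume(parc, series, spec, seed = 8)
  for (r in 1:6) {
    member <- which(parc$labels[which(vol$mask)] == r)
    expect_equal(vol$series[member, ],
                 matrix(series[r, ], length(member), 32, byrow = TRUE))
  }
  expect_equal(unname(roi_time_series(vol, parc)), series)
})

test_that("voxel noise averages down as 1/sqrt(v) within ROIs", {
  spec <- cohort_spec(n_rois = 8, roi_edge = 3, voxel_noise_sd = 0.5,
                      intrinsic_fwhm = 0, n_timepoints = 256, seed = 13)
  parc <- block_parcellation(spec)
  series <- matrix(0, 8, 256) # pure noise: latent signal zero
  vol <- generate_subject_volume(parc, series, spec, seed = 13)
  roi <- roi_time_series(vol, parc)
  v <- 27 # voxels per ROI
  ratio <- mean(apply(roi, 1, var)) / (0.5^2 / v)
  expect_gt(ratio, 1 / 1.3)
  expect_lt(ratio, 1.3)
})

test_that("intrinsically smooth noise fields carry the requested smoothness", {
  spec <- cohort_spec(n_rois = 8, roi_edge = 6, gap = 1, voxel_size = 2,
                      voxel_noise_sd = 1, intrinsic_fwhm = 6,
                      n_timepoints = 8, seed = 17)
  parc <- block_parcellation(spec)
  vol <- generate_subject_volume(parc, matrix(0, 8, 8), spec, seed = 17)
  est <- estimate_smoothness(vol)
  expect_gt(est, 6 * 0.8)
  expect_lt(est, 6 * 1.2)
})

test_that("cohort generation is deterministic and assigns sites round-robin", {
  spec <- cohort_spec(n_per_group = 5, n_rois = 6, n_timepoints = 32,
                      n_sites = 2, seed = 99)
  a <- generate_cohort(spec, mode = "series")
  b <- generate_cohort(spec, mode = "series")
  expect_identical(a, b)
  counts <- table(a$subjects$site[a$subjects$group == "patient"])
  expect_setequal(as.integer(counts), c(3, 2))
  expect_equal(nrow(a$subjects), 10)
  expect_true(all(a$subjects$mean_fd >= 0 & a$subjects$mean_fd <= 0.5))
  # volume mode shares the subject table and ground truth
  av <- generate_cohort(spec, mode = "volumes")
  expect_identical(av$subjects, a$subjects)
  expect_identical(av$ground_truth, a$ground_truth)
})

test_that("extracted connectivity recovers the generating covariance", {
  spec <- cohort_spec(n_per_group = 2, n_rois = 6, voxel_noise_sd = 0,
                      n_timepoints = 4096, base_corr = 0.2, delta = 0.3,
                      seed = 23)
  cv <- make_group_covariances(spec)
  parc <- block_parcellation(spec)
  # full-band series isolate the mixing fidelity: T = 4096 independent
  # samples put the 3-sigma Fisher band well inside 0.05 (band-limiting
  # would cut the effective sample count ~4-fold)
  series <- generate_roi_series(cv$patient, 4096, band = c(0, 0.25),
                                seed = 23)
  vol <- generate_subject_volume(parc, series, spec, seed = 23)
  emp <- pearson_matrix(roi_time_series(vol, parc))
  target <- cv$patient
  diag(target) <- 0
  expect_lt(max(abs(emp - target)), 0.05)
})
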