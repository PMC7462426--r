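---
title: "How smoothsweep measures the effect of spatial smoothing on group network differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How smoothsweep measures the effect of spatial smoothing on group network differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question

Spatial smoothing — replacing every voxel's fMRI time series by a Gaussian
weighted average of its neighbours' series — is a near-universal
preprocessing step, yet the kernel width (FWHM, in mm) is chosen by
convention. Because ROI-level functional connectivity is built from averaged
voxel series, the kernel width changes the networks being compared between a
patient and a control group, and therefore potentially changes *which* group
differences are detected. `smoothsweep` quantifies that dependence: it
re-runs the whole comparison pipeline over a sweep of kernels (by default 16
of them: 0 mm, then 4 mm to 32 mm in 2 mm steps) and measures how the
detected subnetworks move.

Clinical resting-state datasets offer no ground truth for which group
differences are "real". The package therefore ships a synthetic-cohort
generator with a *planted* group contrast, so every stage of the pipeline can
be validated against a known answer, and calibration claims (type-I error,
power) are checked by simulation rather than asserted.

## Pipeline

For each subject and each kernel width:

1. **Smoothing.** Each in-mask voxel series is replaced by
   `x_i(t) = sum_j G_i(j) x_j(t) / sum_j G_i(j)`, with both sums restricted
   to in-mask voxels, so a constant field is a fixed point and no signal
   bleeds in from outside the brain. `sigma = FWHM / (2 sqrt(2 ln 2))`.
2. **ROI extraction.** ROI series are unweighted means of member-voxel
   series; ROIs are nonoverlapping integer labels.
3. **Connectivity.** Pearson correlation between ROI series; Fisher
   transform `z = artanh(r)`; per-link OLS regression on nuisance covariates
   (site, mean framewise displacement) with the cleaned value defined as
   residual + fitted intercept; inverse transform back to `r` space. Group
   is never in the nuisance model.
4. **Network-based statistic (NBS).** A two-group F statistic per link
   (equal to the squared pooled-variance t, df = (1, n1+n2-2)); links with
   F strictly above the primary threshold (default 12.25, i.e. |t| = 3.5)
   enter a breadth-first component search; M label permutations build the
   null distribution of the maximal component size *in links*; each observed
   component gets `p = (1 + #{perm max >= size}) / (M + 1)`. Components with
   p below alpha are significant; the primary subnetwork is the largest
   significant component (ties broken toward the smallest node index).

Across kernels the package then assembles: per-kernel subnetworks and link
counts; a signed Cohen's d grid (`|d| = sqrt(F (1/n1 + 1/n2))`, sign from
the patient-minus-control mean difference) over every link significant at at
least one kernel, evaluated at *every* kernel; link persistence (at which
kernels each link is significant); the Hamming distance between every pair
of per-kernel subnetwork masks (upper-triangle mismatch count — a true
metric); the detected-link length distributions (mm between ROI centroids);
and the Spearman correlation between link length and F over all links.

A complementary "traditional" analysis thresholds each subject's matrix at
7% density, binarizes, computes five graph measures (degree, clustering,
local efficiency, betweenness, global efficiency), and compares groups by
two-sided permutation tests with Benjamini-Hochberg FDR across nodes;
link-wise permutation tests run on the thresholded, *weighted* matrices.

## The synthetic generator

`cohort_spec()` + `generate_cohort()` emulate what the pipeline needs from
preprocessed clinical data, nothing more:

- **Correlation structure.** The control group's ROI correlation matrix has
  a uniform background `base_corr` (default 0.1); the patient matrix adds
  `delta` (default 0.3; 0.4 in the power analyses) on a connected set of
  planted links (default: a 5-link chain over ROIs 1-6). Both matrices are
  repaired to the nearest positive-semidefinite correlation matrix by
  eigenvalue clipping and re-normalisation to unit diagonal; the *achieved*
  post-repair contrast is the ground truth, not the requested one.
- **Band-limited signals.** ROI series are Gaussian noise masked in the
  frequency domain to 0.01-0.08 Hz at TR = 2 s (the band of interest in
  resting-state work), standardised, then mixed with the symmetric square
  root of the target correlation matrix. Masking before mixing leaves the
  correlation structure intact.
- **Geometry.** ROIs are cubic blocks (default 2^3 voxels of 3 mm) tiled
  with 2-voxel gaps, so smoothing mixes neighbouring ROIs realistically on a
  grid small enough to sweep in seconds.
- **Voxel noise and intrinsic smoothness.** Every member voxel carries its
  ROI series plus noise of SD `voxel_noise_sd` (default 0.5). With
  `intrinsic_fwhm > 0` (default 3 mm, i.e. one voxel — a free parameter, not
  calibrated against any dataset) the noise field is smoothed to that FWHM
  and rescaled back to the target SD, so unsmoothed volumes already carry
  nonzero spatial autocorrelation, as scanner point-spread and interpolation
  would produce.
- **Nuisance.** Sites are assigned round-robin within each group (keeping
  site orthogonal to group); mean FD is log-normal(ln 0.15, 0.5) truncated
  at 0.5 mm, the usual inclusion cap; each subject's Fisher-z weights are
  shifted by site offset + slope x FD. The shift enters at the z level —
  exactly where the pipeline regresses nuisance out — so confound regression
  is tested against the structure it is meant to remove.

What the generator does **not** emulate: hemodynamics, scanner artifacts
beyond smooth noise, anatomically realistic parcellations, distance-dependent
noise correlations, or heterogeneous ROI sizes. Passing tests therefore show
that the *statistics* behave as claimed under controlled conditions, not that
any particular clinical finding would replicate.

## Numerical choices

- **Kernel truncation.** Per-axis support of 4 sigma (box, not sphere).
  Beyond 4 sigma the 1D weight is exp(-8) ~ 3e-4 of the peak; the box makes
  3D smoothing factor exactly into sequential 1D passes on full cuboid
  masks, which both the fast path and the separability test exploit. Three
  interchangeable paths (separable, dense pairwise operator, shift-and-
  accumulate) compute the same quantity and agree to ~1e-15.
- **Smoothness estimation.** Variance-of-first-differences: per axis,
  `FWHM_a = delta_a sqrt(-2 ln 2 / ln(1 - v_a/(2v)))`, the FWHM of the
  Gaussian kernel that would give white noise the observed neighbour
  correlation; axes rougher than white noise contribute the voxel size as a
  floor; the three axes combine by geometric mean. On 40^3 grids of 2 mm
  voxels the estimator recovers applied kernels of 4-12 mm within a few
  percent (positive bias ~1-4%, growing with FWHM as edge effects bite).
- **Blur-to-target.** Smoothness compounds approximately in quadrature, so
  each iteration applies the full quadrature gap
  `sqrt(max(target^2 - current^2, 0))` (floored at 0.5 mm) and re-estimates.
  Fractional-gap steps would stall: on a 2-3 mm grid a kernel much smaller
  than a voxel is numerically a delta. One to three steps typically land
  within 5-10% of the target; an input already smoother than the target is
  returned unchanged with a warning (smoothing cannot be undone). The
  voxelwise variant (freezing locally-too-smooth regions) is deliberately
  not implemented; adaptation is global only.
- **Fisher clipping.** |r| = 1 is clipped to 1 - 1e-7 before artanh.
- **Density thresholding.** Keeps `k = round(density R(R-1)/2)` links by
  *signed* weight by default (the dominant convention in binarized
  resting-state graph analysis); `mode = "absolute"` is available. Ties at
  the cutoff break toward the lower (row, col) index, deterministically.
- **Permutation machinery.** All permutation p-values use the +1 estimator
  (never zero); when the relabeling space has at most 10 x n_perm
  assignments the tests enumerate it exhaustively. NBS permutes group
  labels with group sizes preserved; subjects are canonicalised by (group,
  id) before permuting so results cannot depend on input order. Every
  stochastic stage takes a seed, and sweeps derive per-kernel sub-seeds by
  a fixed counter scheme (`derive_seed`), so any kernel is independently
  reproducible.
- **Suprathreshold.** Strict inequality (F *greater than* the threshold).
  The default 12.25 matches |t| = 3.5. For *null calibration* studies on
  small networks (R = 12, 66 links, n = 10 per group) the package's
  analyses use threshold 6 — the upper ~2.5% tail of F(1, 18) — because the
  null maximal-component distribution at 12.25 is so discrete there (almost
  always 0 links) that the test, while valid, rarely fires at all; at
  threshold 6 exceedances stay sparse and the observed significant-call
  rate sits at the nominal 3-5%.
- **Local efficiency** is the global efficiency of the subgraph *induced*
  on a node's neighbours (paths may not detour through the rest of the
  graph); betweenness uses fractional counting over tied shortest paths,
  normalised by (R-1)(R-2)/2; disconnected pairs contribute efficiency 0.
- **Effect sizes** are reported per link at every kernel for the union of
  ever-significant links, so a link's d can be tracked through kernels where
  it was not itself significant.

## Problem sizes

The shipped analyses and tests run on deliberately small instances chosen to
make simulation-based calibration cheap while keeping every statistical
regime visible: cohorts of 10-20 subjects per group, 12 ROIs, 128-512 time
points, sweeps of 4-5 kernels up to 12-16 mm, 200-1000 NBS permutations, 500
null cohorts for type-I calibration, and 50 repetitions for power. The
16-kernel default sweep and 10000-permutation defaults remain available for
larger runs.

## Known limitations

- The toy parcellation is a block lattice; link-length effects exist but
  span a narrow range of distances compared with a whole-brain atlas.
- The equicorrelated background is a single-parameter stand-in for the rich
  covariance of real resting-state networks.
- Nuisance enters as a per-subject scalar shift in z space; real site and
  motion effects are link-heterogeneous.
- `blur_to_fwhm` adapts globally; spatially varying intrinsic smoothness is
  not equalised voxel-wise.
- No one-sided (under/over-connectivity) NBS contrasts, no weighted graph
  metrics, no partial-correlation connectivity.
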