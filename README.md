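# smoothsweep

Spatial smoothing is one of the last preprocessing steps applied to fMRI
volumes before functional brain networks are built, and its Gaussian kernel
width (FWHM, mm) is usually picked by convention. `smoothsweep` measures how
that choice changes the *outcome* of a two-group network comparison: it
re-runs the full pipeline — voxel smoothing, ROI time-series averaging,
Pearson/Fisher connectivity with link-wise nuisance regression, and the
network-based statistic (NBS) — over a sweep of kernels, and quantifies how
the detected group-different subnetworks move as the kernel grows.

It is aimed at researchers analysing ROI-based resting-state connectivity
who want to know how sensitive their group results are to the smoothing
kernel, and at methodologists who need a fully synthetic, ground-truthed
testbed for NBS-style pipelines.

## The statistic at the core

For each link (ROI pair) the two-group difference is scored by the one-way
ANOVA statistic on the cleaned connectivity weights,

    F = MS_between / MS_within,  df = (1, n1 + n2 - 2),  F = t^2,

links with `F > F_thr` (default 12.25, i.e. |t| = 3.5) form a graph whose
connected components are candidate subnetworks. Significance is assessed by
the NBS permutation test: under M group-label permutations the maximal
component size (in links) is recorded, and an observed component of size s
gets

    p = (1 + #{permutations with max size >= s}) / (M + 1).

Across the kernel sweep the package reports per-kernel subnetworks and link
counts, signed effect sizes `|d| = sqrt(F (1/n1 + 1/n2))` for every
ever-significant link at every kernel, link persistence across kernels,
Hamming distances between per-kernel subnetwork masks, detected-link length
distributions, and the Spearman correlation between link length and F.

Because clinical data offer no ground truth, the package ships a
synthetic-cohort generator (`cohort_spec()`, `generate_cohort()`) that
plants a known connected subnetwork contrast into band-limited correlated
ROI signals, renders them as masked 4D volumes with spatially smooth voxel
noise, and injects site/motion nuisance at the Fisher-z level where the
pipeline regresses it out.

## Worked example

The numbered scripts under `analysis/` run the study end to end on a
simulated cohort (10 subjects per group, 12 ROIs, a planted 5-link chain
with contrast Δr = 0.4). The central one:

```sh
Rscript analysis/03_kernel_sweep.R
```

prints, for a sweep of 0/4/8/12/16 mm kernels:

```
<kernel_sweep_result> 5 kernels: 0, 4, 8, 12, 16 mm
  subnetwork links per kernel: 6, 6, 5, 6, 7
  links significant at >= 1 kernel: 8

Hamming distances between per-kernel subnetworks:
   0 4 8 12 16
0  0 0 1  2  3
4  0 0 1  2  3
8  1 1 0  1  2
12 2 2 1  0  1
16 3 3 2  1  0

5 link(s) significant at every kernel, 5 at >= 75% of kernels
```

Reading this: the five planted links are recovered at every kernel width,
but the *detected subnetwork is not stable* — the unsmoothed and 4 mm
analyses pick up a borderline extra link (1-5) that vanishes by 8 mm, while
12-16 mm kernels pull in spurious links (1-11, 3-5) created by smoothing
mixing neighbouring ROIs. The Hamming matrix makes the drift quantitative:
adjacent kernels differ by 0-1 links, distant kernels by up to 3 — one small
kernel change can alter the reported group difference. The signed Cohen's d
grid (`results/sweep/d_grid.tsv`) tracks each link's effect size across all
kernels, and `rho_by_kernel.tsv` records the link-length/F correlation per
kernel.

The other drivers: `01_simulate_cohort.R` writes the cohort (NIfTI volumes,
subject table, ground-truth edge list), `02_smoothing_calibration.R` checks
that the global smoothness estimator recovers applied kernels of 4-12 mm
within a few percent and that blur-to-target lands within 10%,
`04_threshold_metrics.R` runs the 7%-density graph-measure and link-wise
permutation tests (flagging the planted chain's hub nodes for degree and
betweenness), and `05_null_calibration.R` confirms the NBS significant-call
rate on null cohorts sits at the nominal alpha.

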