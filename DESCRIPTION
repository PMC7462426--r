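Package: smoothsweep
Title: Spatial Smoothing Sweeps for Group Comparison of Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the width of the Gaussian spatial-smoothing kernel
    applied to voxel-level fMRI data alters group-level differences in
    ROI-based functional connectivity networks. Provides mask-aware Gaussian
    smoothing over a sweep of kernels, global smoothness estimation and
    blur-to-target smoothing, ROI time-series extraction and fixed-size ROI
    construction, Pearson/Fisher connectivity matrices with link-wise nuisance
    regression, the network-based statistic (permutation test on maximal
    connected components of suprathreshold links), thresholded graph-metric
    and link-wise permutation tests with Benjamini-Hochberg control, and
    sweep-level summaries (effect-size grids, link persistence, Hamming
    distances between subnetworks, link-length/F-statistic correlations).
    A synthetic-cohort generator with a planted group-difference subnetwork
    supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
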