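#!/usr/bin/env Rscript
# The central analysis: smooth every subject's volume over a sweep of
# Gaussian kernels, rebuild connectivity networks at each width, run the
# network-based statistic per kernel, and compare the detected subnetworks
# across kernels (link counts, effect sizes, persistence, Hamming
# distances, link-length/F correlations). Writes results/sweep/.

library(smoothsweep)

seed <- 20260924L
spec <- cohort_spec(n_per_group = 10, n_rois = 12, n_timepoints = 128,
                    base_corr = 0.1, delta = 0.4, seed = seed)
cohort <- generate_cohort(spec, mode = "volumes")

sw <- run_sweep(cohort, fwhms = c(0, 4, 8, 12, 16), suprathreshold = 12.25,
                n_perm = 1000, alpha = 0.05,
                confounds = c("site", "mean_fd"),
                seed = derive_seed(seed, 1))
print(sw)

planted <- paste0(spec$planted_links[, 1], "-", spec$planted_links[, 2])
cat("\nPlanted links among ever-significant links:",
    sum(rownames(sw$d_grid) %in% planted), "of", length(planted), "\n")
cat("Spurious links pulled in by smoothing:",
    sum(!rownames(sw$d_grid) %in% planted), "\n")
cat("\nSigned Cohen's d per ever-significant link and kernel:\n")
print(round(sw$d_grid, 2))
cat("\nHamming distances between per-kernel subnetworks:\n")
print(sw$hamming)
cat("\nLink persistence (ordered by first detecting kernel):\n")
print(sw$persistence$table)
cat(sprintf("\n%d link(s) significant at every kernel, %d at >= 75%% of kernels\n",
            sw$persistence$summary$n_links_all,
            sw$persistence$summary$n_links_75pct))

write_sweep_result(sw, "results/sweep")
cat("\nwrote results/sweep/ (edge lists, hamming.tsv, d_grid.tsv,",
    "rho_by_kernel.tsv, persistence.tsv, run_log.txt)\n")
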