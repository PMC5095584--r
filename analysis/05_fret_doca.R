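#!/usr/bin/env Rscript
# FRET distance of closest approach (DOCA) of ligand-bound donors above a
# plane of membrane acceptors.
#
# Oligomer-bound ligands sit closer to the membrane than dimer-bound
# ligands.  This script simulates lifetime records at two donor heights
# mirroring that contrast (h = 0.65 R0 vs 1.0 R0, i.e. ~4.8 vs ~7.5 nm for
# R0 ~ 7.4 nm), fits the Monte Carlo donor-above-plane model to each, and
# reports the fitted heights with 1,000-fold bootstrap errors.

library(flimpr)

seed <- 20260928
densities <- seq(0.2, 2.5, length.out = 10)

fit_condition <- function(h, label, seed_off) {
  rec <- simulate_fret_dataset(h, densities, n_donors_per_density = 5,
                               lifetime_noise_cv = 0.03,
                               seed = seed + seed_off)
  fit <- fit_doca(rec, n_mc = 2000, B = 1000, seed = seed + seed_off + 1)
  cat(sprintf("%s: true h = %.2f R0, fitted %.3f +/- %.3f R0\n",
              label, h, fit$h_over_R0, fit$bootstrap_sd))
  data.frame(condition = label, h_true_R0 = h,
             h_fit_R0 = fit$h_over_R0, bootstrap_sd = fit$bootstrap_sd,
             n_records = fit$n_records)
}

res <- rbind(
  fit_condition(0.65, "oligomer-like (low)", 10),
  fit_condition(1.00, "dimer-like (high)", 20)
)

dir.create("results", showWarnings = FALSE)
write_table_txt(res, "results/doca_fits.tsv")

# model curve of efficiency vs density across heights, for reference
curve <- do.call(rbind, lapply(c(0.5, 0.65, 1, 1.5), function(h) {
  data.frame(h_over_R0 = h, density_per_R02 = densities,
             efficiency = vapply(densities, function(rho) {
               as.numeric(simulate_plane_fret(h, rho, n_mc = 2000,
                                              seed = seed + round(100 * h)))
             }, numeric(1)))
}))
write_table_txt(curve, "results/plane_fret_model.tsv")
cat("Wrote results/doca_fits.tsv and results/plane_fret_model.tsv\n")
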