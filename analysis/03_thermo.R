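#!/usr/bin/env Rscript
# Compartment-specific Gibbs energies of the IDH isozymes (oxidative
# direction, citrate lumped with aconitase) and the flux-force bounds on
# their backward-to-forward flux ratios. Standard Gibbs energies and
# cofactor-ratio assumptions come from a synthetic configuration file.

library(spatialflux)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- jsonlite::read_json(
  system.file("extdata", "thermo_synthetic.json", package = "spatialflux"),
  simplifyVector = FALSE)

rows <- lapply(cfg$thermo, function(block) {
  spec <- spatialflux:::thermo_spec_from_block(block)
  tr <- gibbs_mc(spec, n_draws = 10000, seed = 1)
  data.frame(name = tr$name, dg_mean = tr$dg_mean, dg_sd = tr$dg_sd,
             b = unname(tr$b_ratio), sigma_b = unname(tr$b_sd),
             lower = unname(tr$lower), upper = unname(tr$upper))
})
res <- do.call(rbind, rows)
utils::write.csv(res, file.path(out_dir, "thermo_results.csv"),
                 row.names = FALSE)

cat("Thermodynamic constraints written to results/thermo_results.csv\n")
for (i in seq_len(nrow(res))) {
  cat(sprintf("  %s: dG' = %6.2f +/- %.2f kJ/mol -> b in [%.3g, %.3g]\n",
              res$name[i], res$dg_mean[i], res$dg_sd[i],
              res$lower[i], res$upper[i]))
}
cat("A strongly negative dG' (far from equilibrium) forces a near-zero\n")
cat("backward:forward ratio, i.e. essentially irreversible oxidative flux.\n")
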