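# spatialflux

Compartment-resolved (mitochondrial vs. cytosolic) flux analysis of citrate
metabolism from rapid-fractionation ¹³C isotope-tracing experiments.

Whole-cell metabolomics cannot tell a cytosolic reaction from its
mitochondrial counterpart: isocitrate dehydrogenase alone runs as cytosolic
NADP-dependent IDH1, mitochondrial NADP-dependent IDH2 and mitochondrial
NAD-dependent IDH3, with citrate shuttling between compartments. This
package implements the computational chain that turns fraction-level
measurements into compartment fluxes:

1. **Quantification** — relative pool sizes by isotope ratio against a fully
   labeled internal standard, `(1 − R2/R1)/(R2 + R2/R1)`, combined across
   standard dilutions; natural-abundance correction of mass-isotopomer
   distributions (MIDs) by nonnegative least squares against the binomial
   convolution matrix.
2. **Deconvolution** — the mitochondrial and cytosolic fractions
   cross-contaminate each other (α = 0.13, β = 0.11 by small-molecule
   markers). Measured pools mix the true signals as
   `P_c = X_c + βX_m`, `P_m = αX_c + X_m`, giving the closed forms
   `P′_c = (P_c − βP_m)(1+α)/(1−αβ)` and `P′_m = (P_m − αP_c)(1+β)/(1−αβ)`
   (applied per isotopomer for MIDs), with Monte-Carlo propagation of
   measurement, pool and contamination uncertainty.
3. **Thermodynamics** — `Δ_rG′ = Δ_rG′° + RT·ln Q` per compartment for each
   IDH isozyme, and the flux-force relationship
   `Δ_rG′ = −RT·ln(J⁺/J⁻)` converted into bounds
   `(b − 2σ_b)·v_O ≤ v_R ≤ (b + 2σ_b)·v_O` on reductive vs. oxidative flux.
4. **Kinetic flux profiling** — four linear ODEs for citrate m+4 (m+3 in
   SDH-knockout cells) and m+5 labeling in both compartments, driven by
   measured α-ketoglutarate/malate labeling curves; constrained
   maximum-likelihood fit of the ten-flux network (two mass balances,
   nonnegativity, thermodynamic wedges) by multi-start barrier BFGS on a
   nullspace parameterization; 95% confidence intervals by profile
   likelihood against the χ²(1) threshold 3.841.
5. **ISA** — isotopomer spectral analysis of palmitate under the binomial
   acetyl-CoA model (8 units, m+2 probability `p`, newly synthesized
   fraction `g`).
6. **Synthetic studies** — a generator that simulates the whole experiment
   from a known flux vector, so every stage is validated by parameter
   recovery.

See `vignettes/spatial-fluxomics.Rmd` for the models, assumptions and design
choices, and `analysis/01_simulate.R` … `05_isa.R` for the narrative
workflow (each writes its tables under `results/`).

## Worked example

Simulate a contaminated triplicate study from a known truth, run the whole
pipeline, and profile the citrate-synthase flux:

```r
library(spatialflux)

cfg <- synthetic_config(seed = 7)        # true v_CS = 0.5 mM/h
fit <- fit_synthetic_study(cfg, n_starts = 4, profile = "v_CS")
round(unclass(fit$best), 3)
#>     v_CS  v_CIT_F  v_CIT_B v_IDH1_R v_IDH1_O v_IDH2_R v_IDH2_O v_IDH3_R
#>    0.507    0.142    0.084    0.030    0.016    0.089    0.192    0.033
#> v_IDH3_O  v_AcCoA
#>    0.379    0.072
fit$ci
#>          lower     upper
#> v_CS 0.4507608 0.5683714
```

The point estimates recover the generating fluxes (identifiable ones to a
few percent at this noise level) and the 95% profile-likelihood interval
covers the true 0.5 mM/h. On noiseless data the identifiable fluxes —
`v_CS`, `v_CIT_F`, `v_CIT_B`, `v_IDH1_R` and the sum
`v_IDH2_R + v_IDH3_R` — return to the truth to well under 0.1%.

Deconvolution and thermodynamics in isolation:

```r
deconvolve_pools(0.5, 0.5, contamination_model(0.13, 0.11, 0))$p_mito
#> [1] 0.4898549
idh_ratio_bounds(rep(-10, 1000))["b"]     # ΔrG' = −10 kJ/mol, oxidative
#>          b
#> 0.02069025
mid_fractions(isa_palmitate_mid(0.071, 1))[c(1, 3)]   # palmitate m+0, m+2
#> [1] 0.5547863 0.3392019
```

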