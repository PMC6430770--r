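---
title: "Compartmentalized citrate fluxomics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmentalized citrate fluxomics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialflux)
```

## The problem

Whole-cell metabolomics averages over organelles, yet central carbon
metabolism runs distinct, sometimes opposing, reactions in mitochondria and
cytosol: isocitrate dehydrogenase (IDH) alone exists as a cytosolic
NADP-dependent isozyme (IDH1), a mitochondrial NADP-dependent one (IDH2) and
the mitochondrial NAD-dependent complex (IDH3), and citrate itself shuttles
between the compartments. `spatialflux` implements the computational half of
a spatial-fluxomics workflow: starting from rapid-fractionation
isotope-tracing measurements (pool sizes and mass-isotopomer distributions
per subcellular fraction), it deconvolves cross-contamination between
fractions, derives thermodynamic bounds on the reversibility of the IDH
isozymes, and estimates mitochondrial versus cytosolic citrate-metabolism
fluxes by kinetic flux profiling with profile-likelihood confidence
intervals. A synthetic-study generator closes the loop so that every stage
is testable by parameter recovery against a known truth.

## Pool-size quantification and natural-abundance correction

Relative pool sizes of a metabolite in a subcellular fraction are measured
by isotope ratio against a fully labeled internal standard. With `R1` the
labeled:unlabeled intensity ratio in the standard-only extract and `R2` the
same ratio in the fraction-plus-standard mixture, the fraction's share of the
whole-cell pool is `(1 - R2/R1) / (R2 + R2/R1)`
(`isotope_ratio_pool_fraction()`). Because the dynamic range of the ratio
measurement is best when labeled and unlabeled signals are comparable,
multiple standard dilutions (1:1, 1:5, 1:10) are acquired;
`combine_dilutions()` keeps the estimate whose `R2` lies closest to 1 and
reports the spread across dilutions as its uncertainty. The selection rule is
this package's own choice — any dilution is an unbiased estimator, and the
closest-to-unity one simply minimizes relative ratio error.

Measured MIDs are corrected for natural ¹³C abundance (default 0.0107) with
a binomial convolution matrix over the non-tracer carbons
(`correct_natural_abundance()`). The inversion is solved as nonnegative
least squares rather than a plain matrix inverse so that noisy inputs always
yield a valid distribution; an unconstrained solution with a component below
−0.01 is treated as evidence of an inconsistent input and raises an error
instead of being silently repaired. Tracer impurity and non-carbon isotopes
are not modeled.

## Deconvolution of fraction cross-contamination

Rapid differential centrifugation leaves each fraction contaminated by the
other compartment. With `alpha` the relative abundance of cytosolic marker
signal in the mitochondrial fraction and `beta` the converse (defaults 0.13
and 0.11, sd 0.03), measured pool sizes mix the per-marker-unit compartment
signals `X_m`, `X_c` as

```
P_c = X_c + beta * X_m
P_m = alpha * X_c + X_m
```

Solving and re-attributing each compartment's contaminating share gives the
closed forms

```
P'_c = (P_c - beta * P_m) (1 + alpha) / (1 - alpha beta)
P'_m = (P_m - alpha * P_c) (1 + beta) / (1 - alpha beta)
```

which conserve `P'_m + P'_c = P_m + P_c` exactly (an algebraic identity the
test suite asserts on random inputs). Per-isotopomer pools obey the same
two-source mixing, so MIDs are deconvolved component-wise and renormalized.
Design choices here: small negative deconvoluted isotopomer components
(down to 1% of the compartment total by default, 5% on noisy Monte-Carlo
paths) are clipped to zero before renormalization — they are
indistinguishable from noise — while larger negatives raise an error because
they indicate inputs inconsistent with the mixing model. Nuclear content is
treated as cytosolic (nuclear-pore diffusion makes the nucleus kinetically
continuous with the cytosol); no separate nuclear pool exists in the model.

Uncertainty is propagated by Monte Carlo (`deconvolve_pools_mc()`,
`deconvolve_mid_mc()`): Gaussian draws of the measurements, pool sizes and
of `alpha`, `beta`, with unphysical draws (negative pools or contamination,
`alpha*beta >= 1`) rejected and resampled; a rejection rate above 50% aborts.
Pool draws are truncated at zero because negative pools are unphysical, a
mild strengthening of the plain-Gaussian noise assumption. Defaults are
10,000 draws for pools and 500–1,000 for MID time courses; a seed is
mandatory everywhere.

## Thermodynamic bounds on IDH reversibility

Reaction Gibbs energies follow `dG' = dG'0 + RT ln Q` at `T = 310.15 K`,
`R = 8.314e-3 kJ/mol/K`. Only within-compartment pool-size *ratios* enter
`Q`, so no assumption about compartment volumes is needed. The IDH reactions
are written citrate → αKG (oxidative direction) — i.e. lumped with
aconitase — because citrate, not isocitrate, is the measured species and
aconitase operates near equilibrium; this is recorded as an explicit model
assumption. Cofactor assumptions: mitochondrial NADH:NAD⁺ = 0.015,
mitochondrial NADPH:NADP⁺ = 100 with a 30% CV (Gaussian), cytosolic
NADPH:NADP⁺ uniform on [30, 100] (only a range is defensible), CO₂ fixed at
1.2 mM. Standard Gibbs energies are configured inputs with Gaussian
uncertainty — estimating them (e.g. by component-contribution methods) is
out of scope, and the values shipped in
`inst/extdata/thermo_synthetic.json` are synthetic illustrations.

The flux-force relationship `dG' = -RT ln(J+/J-)` converts each Gibbs-energy
draw into a backward-to-forward flux ratio `b = exp(dG'_ox / RT)`;
`idh_ratio_bounds()` summarizes the draws as mean `b`, sd `sigma_b`, and the
band `[max(b - 2 sigma_b, 0), b + 2 sigma_b]` that constrains reductive
against oxidative flux in the kinetic model. A reaction far from equilibrium
(strongly negative `dG'`, as for IDH3) therefore enters the flux fit as an
essentially irreversible reaction.

## The kinetic flux-profiling model

The network has ten nonnegative fluxes (mM/h): citrate synthase `v_CS`,
citrate transport `v_CIT_F`/`v_CIT_B`, oxidative and reductive directions of
IDH1/2/3, and cytosolic acetyl-CoA demand `v_AcCoA`, tied by two mass
balances (mitochondrial and cytosolic citrate). After switching cells to
[U-¹³C]-glutamine, the two informative citrate isotopomers are m+4 (from
malate m+4 via citrate synthase; m+3 from malate m+3 in SDH-knockout cells,
where the oxidative TCA cycle is blocked at succinate) and m+5 (from αKG m+5
via reductive carboxylation). Their fractional labeling in each compartment
obeys four linear ODEs driven by the measured αKG and malate labeling
curves ("forcings"); mitochondrial acetyl-CoA is taken as unlabeled, which
the near-absence of citrate m+6 justifies, and citrate m+6 is not modeled.
Both tracked isotopomers share the same 2×2 system matrix, whose sign
structure guarantees real eigenvalues. The package therefore propagates the
exact eigenmode solution — globally for saturating-exponential forcings,
segment-wise for piecewise-linear ones — and falls back to `deSolve::lsoda`
for arbitrary forcing functions; an explicit-Euler brute force exists only in
the test suite as an independent oracle. Fluxes are converted once from
mM/h to mM/min (factor 1/60, tested); pools are in mM on a common
cell-volume basis.

Forcings enter as smooth saturating-exponential curves fitted to the
measured (deconvolved) αKG and malate points (`fit_forcing_curve()`). This
was a genuinely open choice — raw piecewise-linear interpolation through the
measured points is also supported — and smoothing was chosen because
unsmoothed forcing noise propagates into the citrate trajectories as
unmodeled error that the likelihood cannot see, which in simulation produced
overconfident intervals.

## Estimation and confidence intervals

The estimator minimizes the variance-weighted SSR between measured and
simulated labeling over the seven fit times {2, 5, 10, 20, 30, 60, 180} min,
both isotopomers and both compartments, subject to the two equality
balances, nonnegativity, an upper bound (default 5 mM/h per flux), and the
thermodynamic ratio wedges. Residual SDs are floored at 0.002 absolute MID
fraction (`sigma_floor`) so near-zero replicate SDs cannot dominate the
objective. The equalities are eliminated exactly by a nullspace
reparameterization; the remaining linear inequalities are handled by a
logarithmic-barrier BFGS (`stats::constrOptim`) with numerical gradients,
run from random strictly feasible multi-starts (default 50; the recovery
experiments below use 4, which sufficed in simulation). Feasible interior
starts are found by a smooth hinge-penalty phase-1 minimization with a
decreasing margin ladder, because nearly irreversible reactions produce
ratio wedges of width 1e-5 and below that admit only tiny interior margins.
Start magnitudes are mixed across scales (log-uniform) so small-flux regimes
are reachable. Optimizer tolerances: inner relative tolerance 1e-10, up to
12 barrier stages, 300 BFGS iterations per stage; fits are bit-reproducible
given (data, config, seed).

Not every flux is separately identifiable from the labeling data: the ODEs
depend on `v_IDH2_R` and `v_IDH3_R` only through their sum (the thermodynamic
wedges are what separates them), and on `v_IDH1_O`, `v_IDH2_O`, `v_IDH3_O`,
`v_AcCoA` only through the constraints. Recovery tests therefore assert
`v_CS`, `v_CIT_F`, `v_CIT_B`, `v_IDH1_R` and the sum
`v_IDH2_R + v_IDH3_R` individually, and treat the rest as set-identified.

Confidence intervals come from profile likelihood (`profile_ci()`): the
target flux is stepped away from its MLE in 5%-of-MLE increments (5% of
`v_CS` if the MLE is at zero), all other fluxes re-optimized at each step
with the walked flux pinned by an equality, and the 95% bound placed where
the SSR first exceeds its minimum by 3.841459 (the 95% quantile of χ² with
one degree of freedom), linearly interpolated between the bracketing steps.
Non-monotone profiles report the widest crossing and are flagged; a flux
pinned rigid by the constraints yields a flagged zero-width interval. The
`sigma` entering the objective is the Monte-Carlo deconvolution SD, which
carries measurement, pool-size and contamination uncertainty into the
interval widths; replicate SDs alone proved too narrow in coverage
simulations because they ignore those shared error sources.

## The synthetic-study generator

`synthetic_config()` fixes the conditions of a simulated experiment: a true
flux vector (defaults are synthetic round numbers in a qualitatively
normoxic regime — dominant oxidative IDH3, small bidirectional IDH2, small
net-reductive IDH1, bidirectional citrate exchange, `v_CS = 0.5` mM/h);
saturating-exponential forcing kinetics (αKG m+5 plateaus 0.8/0.7 at rates
0.20/0.12 per min in mitochondria/cytosol, malate 0.5 at 0.10 — glutamine
labels αKG quickly and malate more slowly and incompletely); citrate pools
0.35/0.90 mM; contamination alpha = 0.13, beta = 0.11, sd 0.03; triplicate
measurements with per-replicate MID noise sd 0.005 and 10% CV pool noise;
sampling at {2, 5, 10, 20, 30, 60, 180} min. `generate_dataset()` integrates
the ODEs under the truth, forward-mixes compartment signals into
fraction-level observables with the same linear model the deconvolution
inverts, optionally convolves natural abundance, and adds noise — returning
the hidden truth alongside the observables.

What the generator emulates: compartmental labeling kinetics, contaminated
fractions, replicate noise, natural abundance. What it does not: LC-MS peak
integration artifacts, retention-time drift, correlated (non-Gaussian)
replicate error, metabolite channeling, or any isotopomer structure beyond
the tracked mass isotopomers (untracked citrate isotopomers are folded into
m+0). Passing recovery tests therefore demonstrates correctness of the
inference chain under its own assumptions, not robustness to every artifact
of real chromatography.

## Numerical choices and degenerate inputs

* MID construction renormalizes and warns beyond a 5% deviation from unit
  sum; table readers renormalize rows likewise.
* The analytic propagator guards small-exponent regimes with series
  expansions (switch at |x| = 1e-6) and resonance/defective cases by limit
  formulas or by delegating to `lsoda`.
* Monte-Carlo truncation at zero is by resampling, not clipping, to avoid
  point masses at the boundary.
* Degenerate ISA input (pure m+0 palmitate) leaves the newly synthesized
  fraction unidentifiable and is flagged rather than fitted.
* Problem sizes in the shipped tests and scripts — e.g. 100 noise replicates
  for the coverage experiment, 4 multi-starts for synthetic fits, Monte-Carlo
  sizes of 500–10,000 — were chosen as the smallest sizes at which the
  corresponding checks are statistically meaningful.

## Known limitations

The network is the fixed citrate model with a WT/SDH-KO switch, not a
general MFA framework; malate m+3 produced via CO₂ exchange is not modeled;
forcing-curve uncertainty is reduced by smoothing but not formally
propagated into the flux intervals; and the χ²(1) profile threshold assumes
the usual asymptotics, which triplicate-based variance estimates only
approximate. Benchmarking against absolute fluxes measured in real cells
requires primary LC-MS datasets that are not redistributed with the
package; all shipped validation is property-based and synthetic.
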