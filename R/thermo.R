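#' Quotient term of a reaction
#'
#' One multiplicative term of the reaction quotient Q: a species with its
#' stoichiometric coefficient (+ for products of the oxidative direction,
#' - for substrates) and the assumed value with its uncertainty. Within-
#' compartment pool-size *ratios* (product:substrate) can be entered directly
#' as a single term, so no assumption about compartment volume is needed.
#'
#' @param species Species or ratio label (e.g. `"akg_cit_ratio"`,
#'   `"NADPH_NADP_ratio"`, `"CO2"`).
#' @param coeff Stoichiometric coefficient (sign carries direction).
#' @param value Mean value (dimensionless ratio, or concentration in M).
#' @param sd Gaussian sd of `value` (used when `dist = "normal"`).
#' @param dist `"normal"` (truncated positive), `"uniform"` on `[lo, hi]`,
#'   or `"fixed"`.
#' @param lo,hi Uniform bounds (required when `dist = "uniform"`).
#' @export
quotient_term <- function(species, coeff, value = NA_real_, sd = 0,
                          dist = c("normal", "uniform", "fixed"),
                          lo = NA_real_, hi = NA_real_) {
  dist <- match.arg(dist)
  if (dist == "uniform") {
    stopifnot(is.finite(lo), is.finite(hi), lo > 0, hi >= lo)
    if (is.na(value)) value <- (lo + hi) / 2
  }
  stopifnot(is.finite(value), value > 0, sd >= 0)
  structure(list(species = species, coeff = coeff, value = value, sd = sd,
                 dist = dist, lo = lo, hi = hi),
            class = "quotient_term")
}

#' Thermodynamic specification of an IDH isozyme reaction
#'
#' The citrate <-> alpha-ketoglutarate interconversion catalysed by an IDH
#' isozyme (lumped with aconitase, since citrate rather than isocitrate is the
#' measured species), written in the oxidative direction. The standard
#' transformed Gibbs energy is a configured input with Gaussian uncertainty;
#' the quotient terms carry compartment pool-size ratios, cofactor redox
#' ratios and the assumed CO2 concentration.
#'
#' @param name Reaction name, one of `"IDH1"`, `"IDH2"`, `"IDH3"`.
#' @param dg0_prime Standard transformed Gibbs energy, kJ/mol (oxidative
#'   direction).
#' @param dg0_sd Gaussian sd of `dg0_prime`, kJ/mol.
#' @param quotient_terms List of [quotient_term] objects.
#' @param temperature Temperature in K (default 310.15).
#' @param gas_constant Gas constant in kJ/mol/K (default 8.314e-3).
#' @export
thermo_reaction_spec <- function(name, dg0_prime, dg0_sd = 0,
                                 quotient_terms = list(),
                                 temperature = 310.15,
                                 gas_constant = 8.314e-3) {
  name <- match.arg(name, c("IDH1", "IDH2", "IDH3"))
  stopifnot(is.finite(dg0_prime), dg0_sd >= 0, temperature > 0,
            gas_constant > 0)
  stopifnot(all(vapply(quotient_terms, inherits, logical(1), "quotient_term")))
  structure(list(name = name, dg0_prime = dg0_prime, dg0_sd = dg0_sd,
                 quotient_terms = quotient_terms, temperature = temperature,
                 gas_constant = gas_constant),
            class = "thermo_reaction_spec")
}

#' Reaction Gibbs energy at given quotient values
#'
#' `dG' = dG'0 + RT * ln(Q)` with `ln(Q) = sum(coeff * ln(value))`.
#'
#' @param spec A [thermo_reaction_spec].
#' @param point_values Optional named numeric overriding the mean quotient
#'   values by species label.
#' @return Gibbs energy in kJ/mol (oxidative direction).
#' @export
reaction_gibbs <- function(spec, point_values = NULL) {
  stopifnot(inherits(spec, "thermo_reaction_spec"))
  lnQ <- 0
  for (qt in spec$quotient_terms) {
    v <- qt$value
    if (!is.null(point_values) && qt$species %in% names(point_values)) {
      v <- point_values[[qt$species]]
    }
    if (!(v > 0)) stop("quotient term '", qt$species, "' must be positive")
    lnQ <- lnQ + qt$coeff * log(v)
  }
  spec$dg0_prime + spec$gas_constant * spec$temperature * lnQ
}

#' Monte-Carlo draws of the reaction Gibbs energy
#'
#' Gaussian draws of the standard Gibbs energy and of each quotient term
#' (normal terms truncated positive by resampling; uniform terms drawn on
#' their range; fixed terms held).
#'
#' @inheritParams reaction_gibbs
#' @param n_draws Number of draws (>= 1000).
#' @param seed Integer seed.
#' @return Numeric vector of `n_draws` Gibbs energies (kJ/mol).
#' @export
gibbs_draws <- function(spec, n_draws = 10000L, seed) {
  stopifnot(inherits(spec, "thermo_reaction_spec"), n_draws >= 1000L)
  if (missing(seed)) stop("a seed is required for Monte-Carlo thermodynamics")
  set.seed(seed)
  RT <- spec$gas_constant * spec$temperature
  dg0 <- if (spec$dg0_sd > 0) stats::rnorm(n_draws, spec$dg0_prime, spec$dg0_sd)
         else rep(spec$dg0_prime, n_draws)
  lnQ <- rep(0, n_draws)
  for (qt in spec$quotient_terms) {
    v <- switch(qt$dist,
      fixed = rep(qt$value, n_draws),
      uniform = stats::runif(n_draws, qt$lo, qt$hi),
      normal = {
        if (qt$sd == 0) rep(qt$value, n_draws) else {
          x <- stats::rnorm(n_draws, qt$value, qt$sd)
          bad <- x <= 0
          tries <- 0L
          while (any(bad)) {
            x[bad] <- stats::rnorm(sum(bad), qt$value, qt$sd)
            bad <- x <= 0
            tries <- tries + 1L
            if (tries > 1000L) stop("cannot draw positive value for ", qt$species)
          }
          x
        }
      })
    lnQ <- lnQ + qt$coeff * log(v)
  }
  dg0 + RT * lnQ
}

#' Mean and sd of the reaction Gibbs energy by Monte Carlo
#'
#' @inheritParams gibbs_draws
#' @return A `"thermo_result"` list with `name`, `dg_mean`, `dg_sd` (kJ/mol),
#'   and the backward-to-forward ratio summary from [idh_ratio_bounds()].
#' @export
gibbs_mc <- function(spec, n_draws = 10000L, seed) {
  dg <- gibbs_draws(spec, n_draws, seed)
  rb <- idh_ratio_bounds(dg, temperature = spec$temperature,
                         gas_constant = spec$gas_constant)
  structure(list(name = spec$name, dg_mean = mean(dg), dg_sd = stats::sd(dg),
                 b_ratio = rb["b"], b_sd = rb["sigma_b"],
                 lower = rb["lower"], upper = rb["upper"]),
            class = "thermo_result")
}

#' Flux-force relationship
#'
#' Converts a reaction Gibbs energy to the forward-to-backward flux ratio via
#' `dG' = -RT * ln(J+ / J-)`, i.e. returns `exp(-dG' / (RT))`.
#'
#' @param dg Gibbs energy in kJ/mol.
#' @param temperature Kelvin (default 310.15).
#' @param gas_constant kJ/mol/K (default 8.314e-3).
#' @return Dimensionless `J+ / J-`.
#' @export
flux_force_ratio <- function(dg, temperature = 310.15, gas_constant = 8.314e-3) {
  stopifnot(all(is.finite(dg)))
  exp(-dg / (gas_constant * temperature))
}

#' Backward-to-forward flux-ratio bounds from Gibbs-energy draws
#'
#' With the oxidative direction taken as forward, each Gibbs-energy draw maps
#' to a backward-to-forward ratio `exp(dG'_ox / RT)` (the reciprocal of the
#' flux-force forward ratio). Returns the mean `b`, sd `sigma_b`, and the
#' two-sigma constraint band `(max(b - 2*sigma_b, 0), b + 2*sigma_b)` used to
#' bound reductive against oxidative IDH flux in the kinetic model.
#'
#' @param dg_draws Numeric vector of Gibbs-energy draws (kJ/mol, oxidative
#'   direction), e.g. from [gibbs_draws()].
#' @inheritParams flux_force_ratio
#' @return Named numeric `c(b, sigma_b, lower, upper)`.
#' @export
idh_ratio_bounds <- function(dg_draws, temperature = 310.15,
                             gas_constant = 8.314e-3) {
  if (length(dg_draws) < 1L || !all(is.finite(dg_draws))) {
    stop("degenerate Gibbs-energy distribution")
  }
  bdraws <- exp(dg_draws / (gas_constant * temperature))
  b <- mean(bdraws)
  s <- if (length(bdraws) > 1L) stats::sd(bdraws) else 0
  c(b = b, sigma_b = s, lower = max(b - 2 * s, 0), upper = b + 2 * s)
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> %s: dG' = %.2f +/- %.2f kJ/mol; b = %.4g +/- %.4g (bounds %.4g..%.4g)\n",
              x$name, x$dg_mean, x$dg_sd, x$b_ratio, x$b_sd, x$lower, x$upper))
  invisible(x)
}
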