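RT310 <- 8.314e-3 * 310.15

test_that("reaction Gibbs energy follows dG'0 + RT ln Q", {
  spec0 <- thermo_reaction_spec("IDH2", dg0_prime = -4.2)
  expect_equal(reaction_gibbs(spec0), -4.2)   # Q = 1
  spec1 <- thermo_reaction_spec("IDH2", 0, quotient_terms = list(
    quotient_term("prod", 1, exp(1))))
  expect_equal(reaction_gibbs(spec1), RT310, tolerance = 1e-6)
  expect_equal(RT310, 2.5786, tolerance = 1e-4)
  # substrate coefficients enter with negative sign
  spec2 <- thermo_reaction_spec("IDH1", 1, quotient_terms = list(
    quotient_term("prod", 1, 10), quotient_term("sub", -1, 10)))
  expect_equal(reaction_gibbs(spec2), 1)
  # point-value override by species label
  expect_equal(reaction_gibbs(spec1, c(prod = 1)), 0)
  expect_error(reaction_gibbs(spec1, c(prod = -1)), "positive")
})

test_that("a more reduced cofactor pool raises the oxidative Gibbs energy", {
  spec <- thermo_reaction_spec("IDH3", -5, quotient_terms = list(
    quotient_term("NADH_NAD_ratio", 1, 0.015)))
  low <- reaction_gibbs(spec, c(NADH_NAD_ratio = 0.015))
  high <- reaction_gibbs(spec, c(NADH_NAD_ratio = 0.15))
  expect_gt(high, low)
})

test_that("Monte-Carlo Gibbs energies are calibrated and reproducible", {
  spec0 <- thermo_reaction_spec("IDH1", -3, dg0_sd = 0, quotient_terms = list(
    quotient_term("prod", 1, 2, sd = 0)))
  r0 <- gibbs_mc(spec0, n_draws = 2000, seed = 1)
  expect_equal(r0$dg_sd, 0)
  expect_equal(r0$dg_mean, reaction_gibbs(spec0))
  specn <- thermo_reaction_spec("IDH1", 0, dg0_sd = 2)
  dg <- gibbs_draws(specn, n_draws = 50000, seed = 2)
  expect_equal(mean(dg), 0, tolerance = 3 * 2 / sqrt(50000) + 0.02)
  expect_equal(sd(dg), 2, tolerance = 0.05)
  expect_identical(gibbs_draws(specn, 2000, seed = 9),
                   gibbs_draws(specn, 2000, seed = 9))
  # uniform quotient terms stay within their range
  specu <- thermo_reaction_spec("IDH1", 0, quotient_terms = list(
    quotient_term("NADPH_NADP_ratio", 1, dist = "uniform", lo = 30, hi = 100)))
  dgu <- gibbs_draws(specu, 2000, seed = 3)
  expect_true(all(dgu >= RT310 * log(30) - 1e-9))
  expect_true(all(dgu <= RT310 * log(100) + 1e-9))
})

test_that("flux-force relationship and its identities hold", {
  expect_equal(flux_force_ratio(0), 1)
  expect_equal(flux_force_ratio(-RT310 * log(10)), 10, tolerance = 1e-12)
  expect_equal(flux_force_ratio(2.5786), exp(-1), tolerance = 1e-4)
  set.seed(4)
  dg <- rnorm(100, 0, 15)
  expect_equal(flux_force_ratio(dg) * flux_force_ratio(-dg), rep(1, 100),
               tolerance = 1e-12)
})

test_that("backward-to-forward ratio bounds behave as specified", {
  b0 <- idh_ratio_bounds(rep(0, 1000))
  expect_equal(unname(b0["b"]), 1)
  expect_equal(unname(b0["sigma_b"]), 0)
  expect_equal(unname(b0[c("lower", "upper")]), c(1, 1))
  b10 <- idh_ratio_bounds(rep(-10, 1000))
  expect_equal(unname(b10["b"]), 0.0207, tolerance = 1e-3)
  # strongly oxidative reactions force the upper bound far below one
  bneg <- idh_ratio_bounds(rnorm(5000, -15, 1.5))
  expect_lt(unname(bneg["upper"]), 0.05)
  expect_gte(unname(bneg["lower"]), 0)
  # b is monotone increasing in the oxidative Gibbs energy
  dgs <- seq(-20, 10, by = 2)
  bs <- vapply(dgs, function(g) unname(idh_ratio_bounds(rep(g, 10))["b"]),
               numeric(1))
  expect_true(all(diff(bs) > 0))
  expect_error(idh_ratio_bounds(numeric(0)), "degenerate")
})
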