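test_that("flux vectors enforce nonnegativity and mass balance", {
  v <- synthetic_true_fluxes()
  expect_s3_class(v, "flux_vector")
  expect_equal(unname(mass_balance_residuals(v)), c(0, 0), tolerance = 1e-12)
  bad <- unclass(v); bad["v_CS"] <- bad["v_CS"] + 0.2
  expect_error(flux_vector(bad), "mass balance")
  neg <- unclass(v); neg["v_CS"] <- -0.5
  expect_error(flux_vector(neg), "nonnegative")
  expect_error(flux_vector(v_CS = 1), "must name")
})

test_that("forcing constructors cover the stated kinetic shapes", {
  # A = 0 is identically zero
  f0 <- forcing_exponential(0, 0.3)
  expect_equal(f0$fun(c(0, 10, 100)), c(0, 0, 0))
  # half-life arithmetic: value A/2 at t = ln(2)/k
  fh <- forcing_exponential(0.5, 0.1)
  expect_equal(fh$fun(log(2) / 0.1), 0.25, tolerance = 1e-12)
  # a very fast rate approximates a step to the plateau
  fs <- forcing_exponential(0.6, 1e4)
  expect_equal(fs$fun(c(0.01, 1, 50)), rep(0.6, 3), tolerance = 1e-6)
  expect_equal(fs$fun(0), 0)
  # measured points are anchored at zero and extrapolated flat
  fp <- forcing_points(c(2, 5, 10), c(0.1, 0.2, 0.25))
  expect_equal(fp$fun(0), 0)
  expect_equal(fp$fun(1), 0.05)    # linear between (0,0) and (2,0.1)
  expect_equal(fp$fun(50), 0.25)
  expect_error(forcing_points(c(5, 2), c(0.1, 0.2)))
})

test_that("zero forcings give identically zero labeling", {
  cfg <- test_model_config()
  f <- forcing_set(forcing_constant(0), forcing_constant(0),
                   forcing_constant(0))
  y <- simulate_labeling(synthetic_true_fluxes(), cfg, f,
                         c(1, 10, 100))
  expect_equal(max(abs(y[, -1])), 0)
})

test_that("simulation matches the explicit-Euler oracle", {
  cfg <- test_model_config()
  f <- test_forcings()
  set.seed(11)
  for (i in 1:3) {
    v <- random_flux()
    te <- c(2, 5, 10, 20, 30)
    ya <- simulate_labeling(v, cfg, f, te)
    ye <- euler_sim(v, cfg, f, te, dt = 0.001)
    expect_lt(max(abs(ya[, -1] - ye)), 1e-4)
  }
})

test_that("analytic propagation agrees with the adaptive integrator", {
  cfg <- test_model_config()
  set.seed(12)
  te <- c(0.5, 2, 5, 10, 20, 30, 60, 180)
  # exponential forcings (global closed form)
  f1 <- test_forcings()
  # piecewise-linear forcings (segment-wise propagation)
  tt <- c(2, 5, 10, 20, 30, 60, 180)
  f2 <- forcing_set(forcing_points(tt, 0.8 * (1 - exp(-0.2 * tt))),
                    forcing_points(tt, 0.7 * (1 - exp(-0.12 * tt))),
                    forcing_points(tt, 0.5 * (1 - exp(-0.1 * tt))))
  for (f in list(f1, f2)) {
    v <- random_flux()
    ya <- simulate_labeling(v, cfg, f, te, method = "analytic")
    yl <- simulate_labeling(v, cfg, f, te, method = "lsoda")
    expect_lt(max(abs(ya - yl)), 1e-7)
  }
})

test_that("SDH-KO variant obeys the same equations with the m+3 source", {
  cfg <- model_config(variant = "SDHKO", u_cit_mito = 0.35, u_cit_cyto = 0.9)
  f <- forcing_set(akg5_mito = forcing_exponential(0.8, 0.2),
                   akg5_cyto = forcing_exponential(0.7, 0.12),
                   mal_mito = forcing_exponential(0.45, 0.08))  # malate m+3
  set.seed(13)
  v <- random_flux()
  te <- c(2, 5, 10, 20, 30)
  ya <- simulate_labeling(v, cfg, f, te)
  expect_identical(attr(ya, "iso_low"), "m3")
  ye <- euler_sim(v, cfg, f, te, dt = 0.001)
  expect_lt(max(abs(ya[, -1] - ye)), 1e-4)
})

test_that("constant forcings converge to the analytic fixed point", {
  cfg <- test_model_config()
  v <- synthetic_true_fluxes()
  f <- forcing_set(forcing_constant(0.5), forcing_constant(0.5),
                   forcing_constant(0))
  y <- simulate_labeling(v, cfg, f, c(5000, 20000))
  sys <- spatialflux:::kfp_system(v, cfg)
  fp <- solve(sys$A, -c(sys$high$cm * 0.5, sys$high$cc * 0.5))
  expect_lt(max(abs(y[2, c("mito_m5", "cyto_m5")] - fp)), 1e-6)
  # m+4 channel has no label source here
  expect_equal(max(y[, c("mito_low", "cyto_low")]), 0)
})

test_that("labeling respects conservation and pool-rescaling symmetry", {
  cfg <- test_model_config()
  f <- test_forcings()
  v <- synthetic_true_fluxes()
  y <- simulate_labeling(v, cfg, f, c(1, 5, 50, 500, 5000))
  expect_true(all(y[, -1] >= 0))
  expect_true(all(y[, -1] <= 0.8 + 1e-9))   # max forcing plateau
  # halving both pools with fixed fluxes compresses the time axis two-fold
  cfg2 <- model_config(u_cit_mito = cfg$u_cit_mito / 2,
                       u_cit_cyto = cfg$u_cit_cyto / 2)
  # forcings must be rescaled in time as well for the symmetry to be exact
  f2 <- forcing_set(forcing_exponential(0.8, 0.4),
                    forcing_exponential(0.7, 0.24),
                    forcing_exponential(0.5, 0.2))
  y1 <- simulate_labeling(v, cfg, f, c(10, 40, 120))
  y2 <- simulate_labeling(v, cfg2, f2, c(5, 20, 60))
  expect_equal(y1[, -1], y2[, -1], tolerance = 1e-9)
})

test_that("smoothing recovers saturating-exponential forcing parameters", {
  tt <- c(2, 5, 10, 20, 30, 60, 180)
  y <- 0.65 * (1 - exp(-0.15 * tt))
  fit <- fit_forcing_curve(tt, y)
  expect_equal(fit$A, 0.65, tolerance = 1e-4)
  expect_equal(fit$k, 0.15, tolerance = 1e-3)
  expect_equal(fit_forcing_curve(tt, rep(0, 7))$A, 0)
})
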