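make_noiseless <- function(v = synthetic_true_fluxes(), sd = 0) {
  cfg <- spatialflux:::synthetic_model_config(
    synthetic_config(true_fluxes = v, noise_cv = 0, noise_sd_mid = 0))
  f <- test_forcings()
  tt <- cfg$fit_times
  Y <- simulate_labeling(v, cfg, f, tt)[, -1]
  list(data = labeling_dataset(tt, Y, matrix(sd, nrow(Y), 4)),
       cfg = cfg, f = f, v = v)
}

test_that("the objective is zero at truth and scales with sigma", {
  s <- make_noiseless(sd = 0.01)
  expect_equal(objective_ssr(s$v, s$data, s$cfg, s$f), 0)
  # residuals of exactly one sigma count one each: 7 times x 4 series
  X1 <- s$data$X + 0.01
  d1 <- labeling_dataset(s$data$times, pmin(X1, 1),
                         matrix(0.01, nrow(X1), 4))
  expect_equal(objective_ssr(s$v, d1, s$cfg, s$f), 28, tolerance = 1e-6)
  # doubling every sigma divides the objective by four
  d2 <- labeling_dataset(s$data$times, pmin(X1, 1),
                         matrix(0.02, nrow(X1), 4))
  expect_equal(objective_ssr(s$v, d2, s$cfg, s$f), 7, tolerance = 1e-6)
})

test_that("the objective is invariant to timepoint order in the data", {
  s <- make_noiseless(sd = 0.005)
  perm <- c(3, 1, 2, 5, 4, 7, 6)
  dperm <- labeling_dataset(s$data$times[perm][order(perm)],
                            s$data$X[perm, ][order(perm), ],
                            s$data$SD[perm, ][order(perm), ])
  expect_equal(objective_ssr(s$v, dperm, s$cfg, s$f),
               objective_ssr(s$v, s$data, s$cfg, s$f))
  # missing fit times are reported
  short <- labeling_dataset(s$data$times[-3], s$data$X[-3, ], s$data$SD[-3, ])
  expect_error(objective_ssr(s$v, short, s$cfg, s$f), "missing fit times")
})

test_that("noiseless data recover the identifiable fluxes within 2%", {
  s <- make_noiseless()
  fit <- fit_fluxes(s$data, s$cfg, s$f, n_starts = 4, seed = 101)
  est <- unclass(fit$best); tr <- unclass(s$v)
  for (fl in c("v_CS", "v_CIT_F", "v_CIT_B", "v_IDH1_R")) {
    expect_lt(abs(est[fl] - tr[fl]) / tr[fl], 0.02)
  }
  sum_est <- est["v_IDH2_R"] + est["v_IDH3_R"]
  sum_tr <- tr["v_IDH2_R"] + tr["v_IDH3_R"]
  expect_lt(abs(sum_est - sum_tr) / sum_tr, 0.02)
  expect_lt(fit$ssr, 1e-4)
  expect_gte(fit$n_converged, 1)
})

test_that("a boundary truth is recovered at the boundary", {
  v0 <- flux_vector(
    v_CS = 0.50, v_CIT_F = 0.15, v_CIT_B = 0.08,
    v_IDH1_R = 0, v_IDH1_O = 0.01,
    v_IDH2_R = 0.07, v_IDH2_O = 0.10,
    v_IDH3_R = 0.05, v_IDH3_O = 0.45,
    v_AcCoA = 0.06)
  cfg <- model_config(u_cit_mito = 0.35, u_cit_cyto = 0.9,
                      ratio_bounds = list(IDH1 = c(0, 5), IDH2 = c(0.35, 1.05),
                                          IDH3 = c(0.055, 0.17)))
  f <- test_forcings()
  Y <- simulate_labeling(v0, cfg, f, cfg$fit_times)[, -1]
  data <- labeling_dataset(cfg$fit_times, Y, matrix(0, nrow(Y), 4))
  fit <- fit_fluxes(data, cfg, f, n_starts = 4, seed = 7)
  expect_lt(unclass(fit$best)["v_IDH1_R"], 0.01 * unclass(fit$best)["v_CS"])
})

test_that("fits are reproducible and reject infeasible ratio bounds", {
  s <- make_noiseless(sd = 0.005)
  f1 <- fit_fluxes(s$data, s$cfg, s$f, n_starts = 2, seed = 5)
  f2 <- fit_fluxes(s$data, s$cfg, s$f, n_starts = 2, seed = 5)
  expect_identical(unclass(f1$best), unclass(f2$best))
  expect_identical(f1$ssr, f2$ssr)
  bad_cfg <- s$cfg
  bad_cfg$ratio_bounds$IDH2 <- c(2, 1)
  expect_error(fit_fluxes(s$data, bad_cfg, s$f, n_starts = 2, seed = 5),
               "infeasible ratio bounds")
})

test_that("profile likelihood brackets the MLE and widens with noise", {
  s <- make_noiseless(sd = 0.01)
  fit <- fit_fluxes(s$data, s$cfg, s$f, n_starts = 3, seed = 2)
  ci <- profile_ci(fit, "v_CS")
  est <- unclass(fit$best)["v_CS"]
  expect_lte(ci["lower"], est)
  expect_gte(ci["upper"], est)
  expect_gt(ci["upper"] - ci["lower"], 0)
  # with sigma = 0.01 everywhere the interval cannot be absurdly wide
  expect_lt(ci["upper"] - ci["lower"], 0.5)
  prof <- attr(ci, "profile")
  expect_true(all(diff(prof$value) > 0))
})
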