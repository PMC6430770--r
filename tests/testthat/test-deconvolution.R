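test_that("pool deconvolution matches a direct linear solve", {
  cm <- contamination_model(0.13, 0.11, 0)
  d <- deconvolve_pools(0.5, 0.5, cm)
  oracle <- solve_deconv(0.5, 0.5, 0.13, 0.11)
  expect_equal(d$p_mito, unname(oracle["p_mito"]), tolerance = 1e-9)
  expect_equal(d$p_cyto, unname(oracle["p_cyto"]), tolerance = 1e-9)
  expect_equal(d$p_mito, 0.489855, tolerance = 1e-6)
  expect_equal(d$p_cyto, 0.510145, tolerance = 1e-6)
  # identity without contamination
  d0 <- deconvolve_pools(0.3, 0.6, contamination_model(0, 0, 0))
  expect_equal(c(d0$p_mito, d0$p_cyto), c(0.3, 0.6))
  # pure cytosolic species: mitochondrial signal entirely contamination
  dc <- deconvolve_pools(0.13 * 0.7, 0.7, cm)
  expect_equal(dc$p_mito, 0, tolerance = 1e-12)
  expect_error(contamination_model(0.5, 2.5), "beta")
})

test_that("deconvolution conserves total pool and is monotone", {
  set.seed(42)
  for (i in 1:200) {
    a <- runif(1, 0, 0.5); b <- runif(1, 0, 0.5)
    pm <- runif(1, 0, 2); pc <- runif(1, 0, 2)
    d <- suppressWarnings(deconvolve_pools(pm, pc, contamination_model(a, b, 0)))
    expect_equal(d$p_mito + d$p_cyto, pm + pc, tolerance = 1e-12)
    oracle <- solve_deconv(pm, pc, a, b)
    expect_equal(d$p_mito, unname(oracle["p_mito"]), tolerance = 1e-9)
  }
  cm <- contamination_model()
  base <- deconvolve_pools(0.4, 0.6, cm)
  up <- deconvolve_pools(0.5, 0.6, cm)
  down <- deconvolve_pools(0.4, 0.9, cm)
  expect_gt(up$p_mito, base$p_mito)
  expect_lt(down$p_mito, base$p_mito)
})

test_that("Monte-Carlo pool deconvolution is calibrated and reproducible", {
  cm <- contamination_model(0.13, 0.11, 0)
  exact <- deconvolve_pools(0.4, 0.6, cm)
  mc0 <- deconvolve_pools_mc(0.4, 0.6, sds = c(0, 0), cm, n_draws = 500,
                             seed = 1)
  expect_equal(mc0$p_mito, exact$p_mito)
  expect_equal(mc0$sd_mito, 0)
  cm2 <- contamination_model(0.13, 0.11, 0.03)
  mc1 <- deconvolve_pools_mc(0.4, 0.6, sds = c(0.04, 0.06), cm2,
                             n_draws = 20000, seed = 7)
  expect_lt(abs(mc1$p_mito - exact$p_mito), 3 * mc1$sd_mito / sqrt(20000) + 0.01)
  expect_gt(mc1$sd_mito, 0)
  mc2 <- deconvolve_pools_mc(0.4, 0.6, sds = c(0.04, 0.06), cm2,
                             n_draws = 20000, seed = 7)
  expect_identical(mc1, mc2)
})

test_that("MID deconvolution inverts component-wise mixing", {
  cm <- contamination_model(0.13, 0.11, 0)
  # identical compositions are invariant under contamination
  same <- deconvolve_mid(c(0.6, 0.4), c(0.6, 0.4), 0.3, 0.7, cm)
  expect_equal(same$mid_mito$fractions, c(0.6, 0.4), tolerance = 1e-12)
  expect_equal(same$mid_cyto$fractions, c(0.6, 0.4), tolerance = 1e-12)
  # no contamination: inputs unchanged
  id <- deconvolve_mid(c(0.9, 0.1), c(0.5, 0.5), 0.3, 0.7,
                       contamination_model(0, 0, 0))
  expect_equal(id$mid_mito$fractions, c(0.9, 0.1))
  # component-wise oracle: solve the 2x2 system per isotopomer, renormalize
  im <- c(0.9, 0.1); ic <- c(0.5, 0.5); pm <- 0.5; pc <- 0.5
  d <- deconvolve_mid(im, ic, pm, pc, cm)
  oracle_m <- oracle_c <- numeric(2)
  for (j in 1:2) {
    o <- solve_deconv(im[j] * pm, ic[j] * pc, cm$alpha, cm$beta)
    oracle_m[j] <- o["p_mito"]; oracle_c[j] <- o["p_cyto"]
  }
  expect_equal(d$mid_mito$fractions, oracle_m / sum(oracle_m), tolerance = 1e-9)
  expect_equal(d$mid_cyto$fractions, oracle_c / sum(oracle_c), tolerance = 1e-9)
  # mutually inconsistent fraction MIDs (negative isotopomer pool beyond the
  # documented tolerance) are refused rather than silently clipped
  expect_error(deconvolve_mid(c(0.9, 0.1), c(0.5, 0.5), 0.3, 0.7, cm),
               "below")
})

test_that("forward mixing then deconvolution recovers compartment truth", {
  cm <- contamination_model(0.13, 0.11, 0)
  set.seed(5)
  for (i in 1:50) {
    k <- sample(2:7, 1)
    tm <- runif(k); tm <- tm / sum(tm)   # true mito MID
    tc <- runif(k); tc <- tc / sum(tc)
    pm_true <- runif(1, 0.1, 0.9); pc_true <- 1 - pm_true
    mixed <- spatialflux:::mix_mids(tm, tc, pm_true, pc_true, cm)
    mixed_p <- spatialflux:::mix_fractions(pm_true, pc_true, cm)
    d <- deconvolve_mid(mixed$mid_mito, mixed$mid_cyto,
                        mixed_p[["p_mito"]], mixed_p[["p_cyto"]], cm)
    expect_lt(max(abs(d$mid_mito$fractions - tm)), 1e-9)
    expect_lt(max(abs(d$mid_cyto$fractions - tc)), 1e-9)
    expect_equal(d$pools$p_mito, pm_true, tolerance = 1e-9)
  }
})

test_that("MC MID deconvolution is reproducible and propagates noise", {
  cm <- contamination_model(0.13, 0.11, 0.03)
  a <- deconvolve_mid_mc(c(0.8, 0.15, 0.05), c(0.5, 0.3, 0.2), 0.3, 0.7,
                         sd_mid_mito = 0.005, sd_mid_cyto = 0.005,
                         sd_pools = c(0.03, 0.05), cm = cm,
                         n_draws = 2000, seed = 3)
  b <- deconvolve_mid_mc(c(0.8, 0.15, 0.05), c(0.5, 0.3, 0.2), 0.3, 0.7,
                         sd_mid_mito = 0.005, sd_mid_cyto = 0.005,
                         sd_pools = c(0.03, 0.05), cm = cm,
                         n_draws = 2000, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$sd_mito > 0))
  expect_equal(sum(a$mid_mito$fractions), 1, tolerance = 1e-12)
})
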