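test_that("synthetic configurations validate their truth", {
  cfg <- synthetic_config()
  expect_s3_class(cfg$true_fluxes, "flux_vector")
  bad <- unclass(synthetic_true_fluxes()); bad["v_CS"] <- bad["v_CS"] + 1
  expect_error(synthetic_config(true_fluxes = bad), "mass balance")
  expect_error(synthetic_config(forcing_params = list(
    akg5_mito = c(A = 1.4, k = 0.1), akg5_cyto = c(A = 0.5, k = 0.1),
    mal_mito = c(A = 0.5, k = 0.1))))
})

test_that("generated datasets are valid and reproducible", {
  for (s in c(1, 99)) {
    ds <- generate_dataset(synthetic_config(seed = s))
    m_cols <- paste0("m", 0:6)
    for (i in seq_len(nrow(ds$mids))) {
      x <- as.numeric(ds$mids[i, m_cols])
      x <- x[!is.na(x)]
      expect_true(all(x >= 0 & x <= 1))
      expect_equal(sum(x), 1, tolerance = 1e-9)
    }
    expect_true(all(ds$pools$value >= 0))
  }
  a <- generate_dataset(synthetic_config(seed = 5))
  b <- generate_dataset(synthetic_config(seed = 5))
  expect_identical(a$pools, b$pools)
  expect_identical(a$mids, b$mids)
})

test_that("a noiseless uncontaminated study is the identity pipeline", {
  cfg <- synthetic_config(noise_cv = 0, noise_sd_mid = 0,
                          contamination = contamination_model(0, 0, 0))
  ds <- generate_dataset(cfg)
  truth_mid <- ds$truth$mids[["citrate_30"]]$mito
  row <- ds$mids[ds$mids$metabolite == "citrate" &
                   ds$mids$compartment_or_fraction == "mito_fraction" &
                   ds$mids$time_min == 30, paste0("m", 0:6)]
  expect_equal(as.numeric(row), truth_mid, tolerance = 1e-9)
})

test_that("contaminated noiseless measurements deconvolve back to truth", {
  cfg <- synthetic_config(noise_cv = 0, noise_sd_mid = 0)
  ds <- generate_dataset(cfg)
  cm <- cfg$contamination
  pf <- cfg$pool_fractions$citrate
  mixed_p <- spatialflux:::mix_fractions(pf[["mito"]], pf[["cyto"]], cm)
  for (t in c(5, 60)) {
    sel <- function(frac) as.numeric(
      ds$mids[ds$mids$metabolite == "citrate" &
                ds$mids$compartment_or_fraction == frac &
                ds$mids$time_min == t, paste0("m", 0:6)])
    d <- deconvolve_mid(sel("mito_fraction"), sel("cyto_fraction"),
                        mixed_p[["p_mito"]], mixed_p[["p_cyto"]], cm)
    expect_lt(max(abs(d$mid_mito$fractions - ds$truth$mids[[paste0("citrate_", t)]]$mito)),
              1e-9)
    expect_lt(max(abs(d$mid_cyto$fractions - ds$truth$mids[[paste0("citrate_", t)]]$cyto)),
              1e-9)
  }
})

test_that("natural abundance in the generator is inverted by correction", {
  cfg <- synthetic_config(noise_cv = 0, noise_sd_mid = 0,
                          abundance_13C = 0.0107,
                          contamination = contamination_model(0, 0, 0))
  ds <- generate_dataset(cfg)
  row <- as.numeric(ds$mids[ds$mids$metabolite == "citrate" &
                              ds$mids$compartment_or_fraction == "mito_fraction" &
                              ds$mids$time_min == 60, paste0("m", 0:6)])
  corrected <- correct_natural_abundance(row, 0.0107)
  expect_equal(corrected, ds$truth$mids[["citrate_60"]]$mito, tolerance = 1e-8)
})

test_that("the end-to-end synthetic fit recovers truth without noise", {
  cfg <- synthetic_config(noise_cv = 0, noise_sd_mid = 0, n_replicates = 1,
                          contamination = contamination_model(0.13, 0.11, 0))
  fit <- fit_synthetic_study(cfg, n_starts = 3)
  est <- unclass(fit$best); tr <- unclass(cfg$true_fluxes)
  for (fl in c("v_CS", "v_CIT_F", "v_CIT_B", "v_IDH1_R")) {
    expect_lt(abs(est[fl] - tr[fl]) / tr[fl], 0.02)
  }
})
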