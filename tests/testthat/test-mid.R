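test_that("MID construction normalizes and enforces invariants", {
  m <- mid("citrate", c(0.5, 0.3, 0.2))
  expect_s3_class(m, "mid")
  expect_equal(sum(m$fractions), 1, tolerance = 1e-12)
  expect_equal(m$n_carbons, 2L)
  expect_warning(mid("x", c(0.5, 0.3, 0.1)), "renormaliz")
  expect_error(mid("x", c(0.5, -0.2, 0.7)), "nonnegative")
  expect_error(mid("x", numeric(0)))
})

test_that("natural-abundance correction inverts the forward convolution", {
  # forward-generate an observed MID from a pure m+0 tracer distribution
  C2 <- na_correction_matrix(2, 0.0107)
  raw <- as.numeric(C2 %*% c(1, 0, 0))
  expect_equal(raw, c(0.978714, 0.021172, 0.000114), tolerance = 1e-3)
  expect_equal(correct_natural_abundance(raw, 0.0107), c(1, 0, 0),
               tolerance = 1e-9)
  # zero abundance is the identity mapping
  x <- c(0.7, 0.2, 0.1)
  expect_identical(correct_natural_abundance(x, 0), x)
  # fully labeled input has no heavier state to spread into
  expect_equal(correct_natural_abundance(c(0, 0, 0, 1), 0.0107),
               c(0, 0, 0, 1), tolerance = 1e-12)
})

test_that("correction round-trips random MIDs and flags inconsistent input", {
  set.seed(1)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    a <- runif(1, 0.001, 0.19)
    truth <- runif(n + 1)
    truth <- truth / sum(truth)
    raw <- as.numeric(na_correction_matrix(n, a) %*% truth)
    back <- correct_natural_abundance(raw, a)
    expect_lt(max(abs(back - truth)), 1e-8)
  }
  # an observed MID lighter than pure 12C under the model cannot be explained
  expect_error(correct_natural_abundance(c(1, 0, 0), 0.3), "correction failed")
})

test_that("isotope-ratio pool fraction follows the mixing formula", {
  expect_equal(isotope_ratio_pool_fraction(5, 5), 0)
  expect_equal(isotope_ratio_pool_fraction(100, 1), 0.980198, tolerance = 1e-6)
  # R1 -> Inf limit equals 1/R2
  expect_equal(isotope_ratio_pool_fraction(1e12, 2), 0.5, tolerance = 1e-6)
  # strictly decreasing in R2 at fixed R1
  r2 <- seq(0.1, 3, by = 0.1)
  vals <- suppressWarnings(vapply(r2, function(x)
    isotope_ratio_pool_fraction(2, x), numeric(1)))
  expect_true(all(diff(vals[r2 < 2]) < 0))
  expect_warning(isotope_ratio_pool_fraction(1, 2), "clipping")
  expect_error(isotope_ratio_pool_fraction(0, 1), "positive")
})

test_that("dilution combination picks the pair with R2 closest to one", {
  p1 <- isotope_ratio_pair(2, 1.5, "1:1")
  single <- combine_dilutions(list(p1))
  expect_equal(single$value, isotope_ratio_pool_fraction(p1))
  expect_equal(single$selection, "1:1")
  pairs <- list(isotope_ratio_pair(10, 0.05, "1:1"),
                isotope_ratio_pair(10, 0.9, "1:5"),
                isotope_ratio_pair(100, 12, "1:10"))
  picked <- combine_dilutions(pairs)
  expect_equal(picked$selection, "1:5")
  expect_equal(picked$value, isotope_ratio_pool_fraction(10, 0.9))
  # concordant pairs simulated from one true fraction agree
  truefrac <- 0.4
  conc <- lapply(c(0.8, 1.1, 2), function(r2) {
    # invert the formula: given fraction q and R2, R1 = R2 (1 + q R2)... solve
    # q = (1 - R2/R1)/(R2 + R2/R1) for R1
    q <- truefrac
    R1 <- uniroot(function(r1) isotope_ratio_pool_fraction(r1, r2) - q,
                  c(r2 + 1e-9, 1e6))$root
    isotope_ratio_pair(R1, r2, paste0("1:", r2))
  })
  res <- combine_dilutions(conc)
  expect_equal(res$value, truefrac, tolerance = 1e-6)
  expect_lt(res$sd, 1e-6)
  expect_error(combine_dilutions(list()), "at least one")
})
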