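test_that("the binomial palmitate model reproduces closed forms", {
  # no labeled precursor or no turnover: everything stays m+0
  expect_equal(mid_fractions(isa_palmitate_mid(0, 1))[1], 1)
  expect_equal(mid_fractions(isa_palmitate_mid(0.3, 0))[1], 1)
  m <- mid_fractions(isa_palmitate_mid(0.071, 1))
  expect_equal(m[1], 0.929^8, tolerance = 1e-6)
  expect_equal(m[1], 0.55479, tolerance = 1e-4)
  expect_equal(m[3], 8 * 0.071 * 0.929^7, tolerance = 1e-6)
  expect_equal(m[3], 0.33920, tolerance = 1e-4)
})

test_that("the model output is a valid MID with zero odd masses", {
  set.seed(21)
  for (i in 1:25) {
    p <- runif(1); g <- runif(1)
    m <- mid_fractions(isa_palmitate_mid(p, g))
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_true(all(m >= 0))
    expect_equal(m[seq(2, 16, by = 2)], rep(0, 8))
    # mean label count is g * 16 * p by linearity of expectation
    expect_equal(sum((0:16) * m), g * 16 * p, tolerance = 1e-9)
  }
})

test_that("the two-parameter fit round-trips and handles degeneracy", {
  truth <- isa_palmitate_mid(0.071, 0.6)
  fit <- isa_fit(truth)
  expect_equal(fit$p, 0.071, tolerance = 1e-6)
  expect_equal(fit$g, 0.6, tolerance = 1e-6)
  expect_lt(fit$ssr, 1e-12)
  pure <- isa_fit(c(1, rep(0, 16)))
  expect_equal(pure$g, 0)
  expect_true("g_unidentifiable" %in% pure$flags)
  expect_error(isa_fit(rep(1 / 10, 10)), "17 entries")
})

test_that("parameters are recovered from noisy palmitate MIDs", {
  set.seed(22)
  ok <- 0L
  for (i in 1:20) {
    m <- mid_fractions(isa_palmitate_mid(0.071, 0.6))
    noisy <- pmax(m + rnorm(17, 0, 0.005), 0)
    fit <- isa_fit(noisy / sum(noisy))
    # 0.005 absolute noise on ~0.3-0.5 peaks: parameters move by a few percent
    if (abs(fit$p - 0.071) < 0.02 && abs(fit$g - 0.6) < 0.1) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})
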