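test_that("sqrt-rule binning rounds to the nearest integer", {
  expect_identical(sqrt_bins(100), 10L)
  expect_identical(sqrt_bins(1), 1L)
  expect_identical(sqrt_bins(1451), 38L)   # sqrt = 38.09 -> nearest, not floor+1
  expect_identical(sqrt_bins(1520), 39L)   # sqrt = 38.99 -> floor would give 38
  expect_error(sqrt_bins(0), "n must be")
})

test_that("Gaussian histogram fit recovers generating parameters", {
  set.seed(421)
  g <- fit_gaussian(rnorm(10000, 32.8, 12.3))
  expect_true(g$converged)
  expect_lt(abs(g$mean - 32.8), 0.5)
  expect_lt(abs(g$sd - 12.3), 0.5)
  expect_gt(g$r_squared, 0.95)

  # noiseless identity: an ideal (quantile-spaced) Normal(5, 2) sample
  vals <- qnorm(ppoints(20001), mean = 5, sd = 2)
  g2 <- fit_gaussian(vals)
  expect_lt(abs(g2$mean - 5), 0.01 * 2)
  expect_lt(abs(g2$sd - 2) / 2, 0.01)

  # degenerate input signals failure without crashing
  g3 <- fit_gaussian(rep(5, 100))
  expect_false(g3$converged)
  expect_true(is.na(g3$mean))
})

test_that("double-Gaussian fit separates a bend-angle-like mixture", {
  set.seed(77)
  vals <- c(rnorm(500, 10.5, 7.0), rnorm(500, 34.8, 10.6))
  dg <- fit_double_gaussian(vals)
  expect_true(dg$converged)
  expect_lt(abs(dg$components$mean[1] - 10.5), 2)
  expect_lt(abs(dg$components$mean[2] - 34.8), 2)
  # components reported in ascending mean order, weights near the counts
  expect_true(diff(dg$components$mean) > 0)
  expect_lt(abs(sum(dg$components$weight) - 1000) / 1000, 0.25)

  # two well-separated spikes
  set.seed(78)
  spikes <- c(rnorm(100, 0, 0.5), rnorm(100, 90, 0.5))
  dg2 <- fit_double_gaussian(spikes, bins = 40)
  expect_lt(abs(dg2$components$mean[1] - 0), 2)
  expect_lt(abs(dg2$components$mean[2] - 90), 2)
})

test_that("exponential lifetime fit on the survival function", {
  set.seed(31)
  # median error over replicate draws from the tau = 14.4 s law
  errs <- vapply(1:11, function(i) {
    ef <- fit_exponential_lifetime(rexp(1000, 1 / 14.4))
    abs(ef$tau - 14.4)
  }, numeric(1))
  expect_lt(median(errs), 1.0)
  # tau = 1/k identity holds exactly
  ef <- fit_exponential_lifetime(rexp(100, 1 / 5))
  expect_identical(ef$tau, 1 / ef$k)
  # identical durations: positive rate, flagged poor fit
  ef2 <- fit_exponential_lifetime(rep(3, 50))
  expect_gt(ef2$k, 0)
  expect_true(is.na(ef2$r_squared) || ef2$r_squared < 0.9)
  expect_error(fit_exponential_lifetime(rep(0, 50)), "zero")
})

test_that("chi-squared test matches the Pearson formula and edge cases", {
  # agreement with direct evaluation of sum (O-E)^2/E on random tables
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    got <- chi_square_test(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    expect_lt(abs(got$statistic - stat), 1e-10)
    expect_equal(got$p_value, pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # identical row proportions -> p = 1
  expect_equal(chi_square_test(matrix(c(20, 40, 10, 20), 2))$p_value, 1,
               tolerance = 1e-12)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("Student's t test basics", {
  expect_equal(two_sample_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 1,
               tolerance = 1e-12)
  set.seed(12)
  a <- rnorm(50); b <- rnorm(50, 5)
  expect_lt(two_sample_t_test(a, b)$p_value, 1e-10)
  expect_equal(two_sample_t_test(a, b)$p_value,
               two_sample_t_test(b, a)$p_value, tolerance = 1e-12)
  expect_error(two_sample_t_test(rep(1, 5), rep(2, 5)), "variance")
})

test_that("bp/nm conversion uses the B-form rise and is invertible", {
  expect_equal(bp_to_nm(2030), 690.2, tolerance = 1e-9)
  expect_equal(nm_to_bp(130), 382.35, tolerance = 0.01)
  expect_identical(bp_to_nm(0), 0)
  set.seed(3)
  v <- runif(50, 0, 5000)
  expect_equal(nm_to_bp(bp_to_nm(v)), v, tolerance = 1e-12)
  expect_error(bp_to_nm(-1), "non-negative")
  # dose scaling of UV photoproduct density
  expect_equal(uv_lesion_spacing(80), 550, tolerance = 1e-12)
  expect_equal(uv_lesion_spacing(20), 2200, tolerance = 1e-12)
})
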