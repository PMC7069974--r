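test_that("depletion isotherm evaluates the closed form and its limits", {
  expect_equal(fraction_bound(0, 8, 253), 0)
  expect_equal(fraction_bound(300, 8, 1e-9), 100, tolerance = 1e-6)
  # hand evaluation: P = 253, D = 8, K_D = 253
  s <- 253 + 8 + 253
  expect_equal(fraction_bound(253, 8, 253),
               100 * (s - sqrt(s^2 - 4 * 253 * 8)) / 16, tolerance = 1e-12)
  expect_equal(round(fraction_bound(253, 8, 253), 1), 49.6)
  # monotone in P, anti-monotone in K_D
  P <- seq(0, 2000, by = 50)
  expect_true(all(diff(fraction_bound(P, 8, 250)) >= 0))
  expect_true(all(diff(sapply(c(50, 150, 400, 900), function(k)
    fraction_bound(300, 8, k))) <= 0))
})

test_that("K_D fitting inverts the isotherm", {
  # noiseless: exact inverse
  iso <- simulate_emsa(109, 8)
  fit <- fit_kd(iso)
  expect_true(fit$converged)
  expect_lt(abs(fit$K_D - 109), 0.1)
  # 3% noise: median recovery error over replicates below 10%
  errs <- vapply(1:20, function(i) {
    f <- fit_kd(simulate_emsa(109, 8, noise_sd_pct = 3, seed = i))
    abs(f$K_D - 109) / 109
  }, numeric(1))
  expect_lt(median(errs), 0.10)
  # flat input: failure status
  flat <- binding_isotherm(c(1, 2, 3, 4, 5), rep(50, 5), 8)
  expect_false(fit_kd(flat)$converged)
})

test_that("site-corrected specificity arithmetic", {
  expect_equal(site_corrected_specificity(253, 109, 37)$fold, 85.88, tolerance = 0.01)
  expect_equal(site_corrected_specificity(269, 189, 37)$fold, 52.66, tolerance = 0.01)
  expect_equal(site_corrected_specificity(100, 100, 37)$fold, 37)
  # linear in the number of sites
  expect_equal(site_corrected_specificity(253, 109, 74)$fold,
               2 * site_corrected_specificity(253, 109, 37)$fold)
  expect_error(site_corrected_specificity(-1, 5, 37), "positive")
})

test_that("position-distribution specificity matches its occupancy oracle", {
  # uniform positions: no enrichment
  set.seed(101)
  folds <- vapply(1:10, function(i)
    position_distribution_specificity(runif(2000, 0, 50))$fold, numeric(1))
  expect_lt(abs(mean(folds) - 1), 0.1)
  # everything in the window: infinite, flagged
  s <- position_distribution_specificity(runif(100, 21, 39))
  expect_true(is.infinite(s$fold) && s$capped)
  # known mixture vs closed-form accounting: fraction f_spec of binders
  # at the lesion, the rest uniform
  n_bp <- 538; w <- c(20, 40); endt <- 2.5
  f_spec <- 0.4
  set.seed(202)
  pos <- c(rep(30, 40000 * f_spec), runif(40000 * (1 - f_spec), endt, 50))
  got <- position_distribution_specificity(pos, w, n_bp, endt)$fold
  u <- (w[2] - w[1]) / (50 - endt)            # uniform mass landing in window
  f_in <- f_spec + (1 - f_spec) * u
  n_spec <- 2 * (w[2] - w[1]) / 100 * n_bp
  n_non <- 2 * (50 - endt - (w[2] - w[1])) / 100 * n_bp
  oracle <- (f_in / n_spec) / ((1 - f_in) / n_non)
  expect_lt(abs(got - oracle) / oracle, 0.01)
})

test_that("titration CSV round-trips", {
  iso <- simulate_emsa(150, 8, noise_sd_pct = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration_csv(iso, path)
  back <- read_titration_csv(path)
  expect_equal(back$fraction_bound_pct, iso$fraction_bound_pct, tolerance = 1e-9)
  expect_equal(attr(back, "dna_nM"), 8)
})
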