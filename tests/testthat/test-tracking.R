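test_that("kymograph construction slices the stack along the path", {
  stack <- replicate(5, matrix(2, 32, 32), simplify = FALSE)
  path <- cbind(seq(4, 28), 16)
  k <- build_kymograph(stack, path)
  expect_true(all(k$intensity == 2))
  expect_equal(ncol(k$intensity), 5)
  # single-frame stack -> one column
  k1 <- build_kymograph(stack[1], path)
  expect_equal(ncol(k1$intensity), 1)
  # moving spot: kymograph ridge follows the generator positions
  spot_stack <- lapply(1:6, function(t) {
    m <- matrix(0, 32, 32); m[10 + 2 * t, 16] <- 5; m
  })
  ks <- build_kymograph(spot_stack, cbind(1:32, 16))
  ridge <- apply(ks$intensity, 2, which.max)
  expect_equal(ridge, 10 + 2 * (1:6))
  expect_error(build_kymograph(stack, cbind(c(0, 5), c(5, 5))), "bounds")
})

test_that("bandpass filter removes DC, suppresses stripes, keeps ridges", {
  u <- kymograph(matrix(7, 64, 8))
  expect_lt(max(abs(bandpass_filter(u)$intensity)), 1e-9)
  # vertical stripes (frame-wide constants varying over time)
  st <- kymograph(matrix(rep(c(1, 9), each = 64, length.out = 64 * 10), 64, 10))
  out <- bandpass_filter(st)
  expect_gt(max(abs(st$intensity - mean(st$intensity))) /
            max(abs(out$intensity) + 1e-30), 10)
  # a PSF-scale Gaussian ridge survives with > 50% amplitude
  prof <- exp(-((1:64) - 32.5)^2 / (2 * 2^2))
  rg <- kymograph(matrix(prof, 64, 4))
  expect_gt(max(bandpass_filter(rg)$intensity) / max(prof), 0.5)
  # linearity
  set.seed(14)
  a <- kymograph(matrix(runif(64 * 4), 64, 4))
  b <- kymograph(matrix(runif(64 * 4), 64, 4))
  ab <- kymograph(a$intensity + b$intensity)
  expect_equal(bandpass_filter(ab)$intensity,
               bandpass_filter(a)$intensity + bandpass_filter(b)$intensity,
               tolerance = 1e-9)
})

test_that("1D Gaussian localization is exact, equivariant, and gated", {
  psz <- 43.3
  mk <- function(centres_px, amp = 100, noise = FALSE, seed = 1) {
    p <- 1:64
    m <- sapply(centres_px, function(c0)
      amp * exp(-(p - c0)^2 / (2 * 2^2)) + 1)
    if (noise) { set.seed(seed); m <- matrix(rpois(length(m), m), 64) }
    kymograph(m, psz, 0.1)
  }
  # noiseless: recovered centre equals truth to optimizer tolerance
  tr <- localize(mk(c(20.25, 33.7, 48)))
  expect_true(all(tr$valid))
  expect_lt(max(abs(tr$position_nm - (c(20.25, 33.7, 48) - 1) * psz)), 1e-4 * psz)
  # shift equivariance
  tr2 <- localize(mk(c(20.25, 33.7, 48) + 3.5))
  expect_equal(tr2$position_nm - tr$position_nm, rep(3.5 * psz, 3),
               tolerance = 1e-3)
  # blank frame marked invalid
  blank <- mk(30); blank$intensity[, 1] <- 1
  trb <- localize(blank)
  expect_false(trb$valid[1])
  # shot noise at SNR ~ 10: localization spread below half a pixel
  trn <- localize(mk(rep(32, 200), amp = 100, noise = TRUE, seed = 7))
  expect_gt(mean(trn$valid), 0.95)
  expect_lt(sd(trn$position_nm[trn$valid]) / psz, 0.5)
})

test_that("render/localize round trip matches the stated position uncertainty", {
  cfg <- tightrope_sim_config(duration_s = 60, seed = 30)
  out <- simulate_trajectory(cfg)
  # noiseless optics: localization returns the observed positions
  cfg0 <- cfg; cfg0$background_photons <- 1e-3
  tr0 <- localize(render_kymograph(out$trajectory, cfg0, poisson_noise = FALSE))
  ok <- tr0$valid & out$trajectory$valid
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(tr0$position_nm[ok] - out$trajectory$position_nm[ok])),
            0.1 * cfg$pixel_size_nm)
  # with photon noise: RMS deviation from the true path ~ 36 nm
  set.seed(31)
  tr1 <- localize(render_kymograph(out$trajectory, cfg))
  ok1 <- tr1$valid & out$truth$valid
  rms <- sqrt(mean((tr1$position_nm[ok1] - out$truth$position_nm[ok1])^2))
  expect_gt(rms, 26); expect_lt(rms, 46)
})

test_that("trajectory CSV round-trips", {
  tr <- simulate_trajectory(tightrope_sim_config(duration_s = 20, seed = 2))$trajectory
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$position_nm, tr$position_nm, tolerance = 1e-9)
  expect_equal(back$valid, tr$valid)
  expect_equal(attr(back, "frame_interval_s"), 0.1, tolerance = 1e-9)
})
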