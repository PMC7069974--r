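test_that("particle classification follows the range and gap rules", {
  cfg <- segmentation_config()
  set.seed(41)
  # jitter around a fixed point: stationary, persistent
  still <- trajectory(5000 + rnorm(3000, 0, 15), frame_interval_s = 0.1)
  cl <- classify_particle(still, cfg)
  expect_equal(cl$motility, "stationary")
  expect_equal(cl$persistence, "persistent")
  # random walk at D = 0.03 um^2/s: motile
  walk <- trajectory(5000 + cumsum(rnorm(3000, 0, sqrt(2 * 0.03e6 * 0.1))),
                     frame_interval_s = 0.1)
  expect_equal(classify_particle(walk, cfg)$motility, "motile")
  # terminal 250-frame gap: dissociated, and analysis truncated there
  x <- 5000 + rnorm(1000, 0, 15)
  v <- rep(TRUE, 1000); v[751:1000] <- FALSE
  gone <- trajectory(x, v, 0.1)
  cg <- classify_particle(gone, cfg)
  expect_equal(cg$persistence, "dissociated")
  expect_equal(cg$analyzed_frames, 750)
  expect_error(classify_particle(trajectory(rnorm(40), frame_interval_s = 0.1)),
               "too few")
})

test_that("segmentation reproduces the worked interruption examples", {
  cfg <- segmentation_config()
  # short-range motion, 10 s pause, short-range motion -> three phases
  x3 <- c(zigzag(200), rep(400, 100), zigzag(200))
  ph3 <- segment_phases(trajectory(x3, frame_interval_s = 0.1), cfg)
  expect_equal(ph3$mode, c("short", "paused", "short"))
  expect_equal(ph3$duration_s[2], 10)
  # the same pause lasting only 2 s -> a single short-range phase
  x1 <- c(zigzag(200), rep(400, 20), zigzag(200))
  ph1 <- segment_phases(trajectory(x1, frame_interval_s = 0.1), cfg)
  expect_equal(ph1$mode, "short")
  # static trace -> one paused phase
  phs <- segment_phases(trajectory(rep(7, 300), frame_interval_s = 0.1), cfg)
  expect_equal(phs$mode, "paused")
  # long-range run interrupted by a 6 s short window is split
  set.seed(5)
  xl <- c(cumsum(rnorm(100, 0, 90)), zigzag(60, amp = 300, base = 0),
          cumsum(rnorm(100, 0, 90)) + 300)
  phl <- segment_phases(trajectory(xl, frame_interval_s = 0.1), cfg)
  expect_true("short" %in% phl$mode)
  expect_true(all(phl$displacement_nm[phl$mode == "long"] > 690))
})

test_that("segmentation satisfies the exhaustive rule checker", {
  cfg <- segmentation_config()
  for (seed in 1:120) {
    tr <- random_piecewise_traj(n_frames = 60, dt = 0.5, seed = seed)
    ph <- segment_phases(tr, cfg)
    res <- check_segmentation(tr, ph, cfg)
    if (!isTRUE(res)) fail(sprintf("seed %d: %s", seed, res))
    # deterministic and idempotent
    expect_identical(ph, segment_phases(tr, cfg))
  }
  succeed()
})

test_that("mode fractions and pause sites", {
  x <- c(zigzag(100), rep(500, 100), zigzag(100, base = 1500))
  tr <- trajectory(x, frame_interval_s = 0.1)
  ph <- segment_phases(tr)
  fr <- mode_time_fractions(ph)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(unname(fr["paused"]), 1 / 3, tolerance = 0.01)
  # one paused phase -> one site
  expect_equal(pause_sites(ph, tr)$n_sites, 1)
  # two pauses 50 nm apart merge; three well-separated sites stay distinct
  x2 <- c(rep(0, 60), zigzag(20, amp = 300), rep(50, 60),
          zigzag(20, amp = 2000), rep(2000, 60))
  tr2 <- trajectory(x2, frame_interval_s = 0.1)
  ph2 <- segment_phases(tr2)
  expect_equal(pause_sites(ph2, tr2)$n_sites, 2)
  x3 <- c(rep(0, 60), zigzag(20, amp = 2000), rep(1500, 60),
          zigzag(20, amp = 2000), rep(3000, 60))
  tr3 <- trajectory(x3, frame_interval_s = 0.1)
  expect_equal(pause_sites(segment_phases(tr3), tr3)$n_sites, 3)
})

test_that("MSD matches closed forms and the double-loop oracle", {
  # constant position
  expect_true(all(msd(rep(3, 50), 0.1)$msd_nm2 == 0))
  # ballistic x = v t
  v <- 12.5
  xb <- v * (0:79) * 0.1
  mb <- msd(xb, 0.1)
  expect_equal(mb$msd_nm2, (v * mb$lag_s)^2, tolerance = 1e-12)
  # random walks against the naive oracle, including invalid frames
  set.seed(51)
  for (i in 1:25) {
    x <- cumsum(rnorm(60, 0, 25))
    if (i %% 3 == 0) x[sample(60, 8)] <- NA
    m <- msd(x, 0.1, min_pairs = 5)
    for (r in seq_len(nrow(m)))
      expect_equal(m$msd_nm2[r], msd_oracle(x, m$lag_frames[r]),
                   tolerance = 1e-12)
  }
})

test_that("diffusion fit recovers D and applies the acceptance filters", {
  # exact line MSD = 2 D t with D = 0.01 um^2/s
  t <- (1:20) * 0.1
  mc <- structure(data.frame(lag_frames = 1:20, lag_s = t,
                             msd_nm2 = 2 * 0.01 * 1e6 * t + 500,
                             n_pairs = 50),
                  n_frames = 81, class = c("msd_curve", "data.frame"))
  fit <- fit_diffusion(mc)
  expect_true(fit$accepted)
  expect_equal(fit$D_um2_s, 0.01, tolerance = 1e-9)
  expect_equal(fit$intercept_um2, 500 / 1e6, tolerance = 1e-9)
  # two usable lags -> rejected
  mc2 <- structure(mc[1:2, ], n_frames = 9,
                   class = c("msd_curve", "data.frame"))
  expect_false(fit_diffusion(mc2)$accepted)
  # noisy curve failing R^2 is rejected
  set.seed(52)
  mc3 <- structure(data.frame(lag_frames = 1:40, lag_s = (1:40) * 0.1,
                              msd_nm2 = abs(rnorm(40, 2000, 3000)),
                              n_pairs = 30),
                   n_frames = 161, class = c("msd_curve", "data.frame"))
  f3 <- fit_diffusion(mc3)
  expect_false(f3$accepted)
})

test_that("sliding-limit theory behaves physically", {
  p <- theory_params()
  d0 <- d_limit(p)
  expect_gt(d0, 0.010); expect_lt(d0, 0.020)   # ~0.015 um^2/s scale
  # infinite pitch removes the rotational drag: Stokes-Einstein limit
  pinf <- theory_params(pitch_bp = 1e12)
  se <- p$kBT_J / (6 * pi * p$viscosity_Pa_s * p$radius_nm * 1e-9) * 1e12
  expect_equal(d_limit(pinf), se, tolerance = 1e-6)
  # strictly decreasing in particle radius
  ds <- vapply(c(6, 9, 12, 15, 20), function(a)
    d_limit(theory_params(radius_nm = a)), numeric(1))
  expect_true(all(diff(ds) < 0))
})

test_that("energy-barrier relation and closed forms", {
  expect_equal(energy_barrier(0.01, 0.01), 0)
  expect_equal(energy_barrier(0.01 / exp(1), 0.01), 1, tolerance = 1e-12)
  expect_error(energy_barrier(2, 1), "exceed")
  expect_error(energy_barrier(-1, 1), "positive")
})
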