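# small synthetic height maps built in code
flat_map <- function(level = 0, n = 64, noise = 0, psz = 1000 / 512, seed = 1) {
  set.seed(seed)
  height_map(matrix(level + rnorm(n * n, 0, noise), n, n), psz)
}

add_square_blob <- function(map, r0, c0, size, h) {
  map$heights[r0:(r0 + size - 1), c0:(c0 + size - 1)] <-
    map$heights[r0:(r0 + size - 1), c0:(c0 + size - 1)] + h
  map
}

test_that("background estimation finds the substrate plane", {
  expect_equal(as.numeric(estimate_background(flat_map(0))), 0)
  m <- add_square_blob(flat_map(0.2, noise = 0.05, seed = 2), 20, 20, 6, 2)
  expect_lt(abs(as.numeric(estimate_background(m)) - 0.2), 0.02)
})

test_that("particle detection and the volume identity", {
  expect_length(detect_particles(flat_map(0, noise = 0.02, seed = 3)), 0)
  m <- add_square_blob(flat_map(0, noise = 0.02, seed = 4), 30, 30, 4, 1.0)
  parts <- detect_particles(m)
  expect_length(parts, 1)
  psz <- m$pixel_size_nm
  # V = A (H - B) equals the per-pixel sum identically
  fp <- parts[[1]]
  expect_equal(fp$volume_nm3,
               sum(fp$heights - fp$background_nm) * psz^2, tolerance = 1e-9)
  expect_equal(particle_volume(fp), fp$volume_nm3, tolerance = 1e-12,
               ignore_attr = TRUE)
  # two separated blobs -> two footprints; volumes additive
  m2 <- add_square_blob(m, 10, 10, 4, 0.8)
  parts2 <- detect_particles(m2)
  expect_length(parts2, 2)
  v <- sort(vapply(parts2, function(p) p$volume_nm3, numeric(1)))
  expect_equal(v[2], fp$volume_nm3, tolerance = 0.15)
})

test_that("rendered Gaussian blob volume matches the analytic truncation", {
  V <- 30; sigma <- 2
  h0 <- V / (2 * pi * sigma^2)
  vols <- c()
  for (sd in 1:4) {
    f <- simulate_afm_field(afm_sim_config(n_molecules = 0, n_free_proteins = 6,
                                           protein_volume_sd_nm3 = 1e-3,
                                           seed = 18 + sd))
    parts <- detect_particles(f$map)
    B <- as.numeric(estimate_background(f$map))
    thr <- B + 3 * estimate_noise_sd(f$map, B)
    v <- vapply(parts, function(p) p$volume_nm3, numeric(1))
    vols <- c(vols, v)
    # each blob agrees with the analytic volume of the Gaussian cap above
    # the detection threshold (the numeric-integration oracle)
    expected <- V * (1 - thr / h0)
    expect_lt(max(abs(v - expected)) / expected, 0.15)
  }
  expect_gt(length(vols), 15)
  # ensemble mean within 15% of the rendered 30 nm^3 (threshold truncation
  # loses the sub-threshold skirt; documented)
  expect_lt(abs(mean(vols) - V) / V, 0.15)
})

test_that("calibration line fit, inversion, and printed coefficients", {
  mw <- c(25, 37, 42.8, 85.6)
  cal <- fit_calibration(mw, 1.14 * mw - 2.00)
  expect_equal(cal$slope, 1.14, tolerance = 1e-9)
  expect_equal(cal$intercept, -2.00, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1, tolerance = 1e-9)
  set.seed(6)
  caln <- fit_calibration(mw, 1.14 * mw - 2.00 + rnorm(4, 0, 2))
  expect_lt(abs(caln$slope - 1.14) / 1.14, 0.10)
  expect_error(fit_calibration(c(30, 30), c(10, 12)), "distinct")
  # inverse identity and negative-MW flag
  expect_equal(as.numeric(volume_to_mw(mw_to_volume(50, cal), cal)), 50,
               tolerance = 1e-12)
  expect_true(attr(volume_to_mw(-10, cal), "flagged"))
})

test_that("flanking-DNA subtraction arithmetic", {
  expect_equal(as.numeric(protein_volume_on_dna(30, 10, 10)), 20)
  expect_equal(as.numeric(protein_volume_on_dna(7, 7, 7)), 0)
  expect_true(attr(protein_volume_on_dna(5, 10, 10), "flagged"))
})

test_that("DNA tracing recovers contour length and applies the filters", {
  # near-straight chain (long persistence length)
  f <- simulate_afm_field(afm_sim_config(n_molecules = 1,
                                         persistence_length_nm = 5000,
                                         seed = 21))
  ct <- trace_dna(f$map)
  expect_length(ct, 1)
  true_len <- f$truth$molecules[[1]]$contour_length_nm
  expect_lt(abs(ct[[1]]$contour_length_nm - true_len) / true_len, 0.05)
  expect_true(ct[[1]]$accepted)
  # wrong expected length triggers the +/-10% rejection
  ct2 <- trace_dna(f$map, expected_length_nm = 120)
  expect_false(ct2[[1]]$accepted)
  # curved worm-like chains at the physiological persistence length:
  # median tracing error across molecules below 5%
  errs <- c()
  for (sd in 1:3) {
    f3 <- simulate_afm_field(afm_sim_config(n_molecules = 3, seed = 30 + sd))
    ct3 <- trace_dna(f3$map)
    t3 <- f3$truth$molecules[[1]]$contour_length_nm
    errs <- c(errs, vapply(ct3, function(ct)
      abs(ct$contour_length_nm - t3) / t3, numeric(1)))
  }
  expect_gt(length(errs), 5)
  expect_lt(median(errs), 0.05)
})

test_that("binding position respects the closest-end convention", {
  pts <- cbind(x = seq(0, 100, by = 1), y = rep(50, 101))
  ct <- structure(list(points = pts, contour_length_nm = 100,
                       expected_length_nm = 100, accepted = TRUE,
                       reason = "ok", mean_height_nm = 0.3,
                       mean_width_nm = 5), class = "dna_contour")
  expect_equal(as.numeric(binding_position(ct, c(50, 50))), 50)
  expect_equal(as.numeric(binding_position(ct, c(0, 50))), 0)
  expect_equal(as.numeric(binding_position(ct, c(30, 52))), 30)
  # reversal invariance
  ctr <- ct; ctr$points <- pts[nrow(pts):1, ]
  expect_equal(as.numeric(binding_position(ctr, c(30, 52))),
               as.numeric(binding_position(ct, c(30, 52))))
  expect_error(binding_position(ct, c(30, 90)), "capture")
})

test_that("bend angle on known polylines and mirror symmetry", {
  line <- cbind(x = 0:100, y = rep(0, 101))
  ct <- structure(list(points = line, contour_length_nm = 100),
                  class = "dna_contour")
  expect_equal(bend_angle(ct, 50, 10), 0, tolerance = 1e-9)
  # right-angle polyline
  ra <- rbind(cbind(0:50, 0), cbind(50, 1:50))
  ctr <- structure(list(points = ra), class = "dna_contour")
  expect_equal(bend_angle(ctr, 50, 10), 90, tolerance = 1e-9)
  # 60-degree kink, mirrored copy gives the same theta
  th <- 60 * pi / 180
  kink <- rbind(cbind(0:50, 0),
                cbind(50 + (1:50) * cos(th), (1:50) * sin(th)))
  ctk <- structure(list(points = kink), class = "dna_contour")
  expect_equal(bend_angle(ctk, 50, 10), 60, tolerance = 1e-6)
  ctm <- ctk; ctm$points[, 2] <- -ctm$points[, 2]
  expect_equal(bend_angle(ctm, 50, 10), bend_angle(ctk, 50, 10),
               tolerance = 1e-9)
  expect_error(bend_angle(ctk, 5, 10), "arm length")
})

test_that("complex classification separates blobs from bare DNA", {
  # bare DNA yields no complexes
  f0 <- simulate_afm_field(afm_sim_config(n_molecules = 2, occupancy = 0,
                                          seed = 55))
  tab0 <- measure_complexes(f0$map)
  expect_equal(nrow(tab0), 0)
  expect_gt(attr(tab0, "n_molecules"), 0)
  # fully occupied field yields one complex per traced molecule
  f1 <- simulate_afm_field(afm_sim_config(n_molecules = 2, occupancy = 1,
                                          at_lesion_frac = 1,
                                          protein_volume_sd_nm3 = 1e-3,
                                          seed = 56))
  tab1 <- measure_complexes(f1$map)
  expect_equal(nrow(tab1), attr(tab1, "n_molecules"))
  expect_true(all(!tab1$end_bound))
})

test_that("height-map TIFF + sidecar round-trips", {
  m <- add_square_blob(flat_map(0.1, noise = 0.03, seed = 9), 12, 12, 5, 1.2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_height_map(m, path)
  back <- read_height_map(path)
  expect_equal(back$heights, m$heights, tolerance = 1e-6)
  expect_equal(back$pixel_size_nm, m$pixel_size_nm)
})
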