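#' Configuration for the tightrope switching-diffusion simulator
#'
#' Defines the study conditions emulated by [simulate_trajectory()]:
#' 300 s recordings at 10 fps of a quantum-dot-labelled protein moving on
#' an elongated DNA tightrope, switching among a paused, a short-range
#' (D = 3.2e-3 um^2/s) and a long-range (D = 3.7e-2 um^2/s) mode with
#' exponential dwells of ~14 s, observed with 36 nm positional
#' uncertainty.
#'
#' @param duration_s Recording length (s). Default 300.
#' @param fps Frames per second. Default 10.
#' @param pixel_size_nm Camera pixel size along the DNA (nm). Default 43.3.
#' @param D_short,D_long Diffusion coefficients of the two motile modes
#'   (um^2/s). Defaults 3.2e-3 and 3.7e-2.
#' @param mean_dwell_s Mean dwell per mode (s); named vector
#'   (paused, short, long) or a scalar applied to all. Default 14.
#' @param lesion_positions_nm Positions of lesions on the tightrope (nm).
#'   Default none.
#' @param pause_bias Multiplier on the pause-entry weight when the
#'   particle is within `capture_radius_nm` of a lesion. Default 3.
#' @param capture_radius_nm Lesion capture radius (nm). Default 200.
#' @param localization_noise_nm Positional uncertainty added to the true
#'   positions (nm): the stationary sd of an Ornstein-Uhlenbeck noise
#'   process. Default 36.
#' @param noise_corr_time_s Correlation time of the positional noise (s).
#'   The dominant contributions to tracking uncertainty (stage drift, DNA
#'   and tightrope fluctuations) vary on the seconds scale rather than
#'   frame to frame; 0 gives white noise. Default 2.
#' @param psf_sigma_nm PSF sigma used when rendering movies (nm).
#'   Default 100.
#' @param photon_rate Expected signal photons per frame. Default 200.
#' @param background_photons Expected background photons per pixel per
#'   frame. Default 5.
#' @param blink_prob Per-frame probability of a dark (invalid) frame.
#'   Default 0.02.
#' @param dissociation_rate_s Dissociation rate (1/s); 0 means the
#'   particle persists. Default 0.
#' @param tightrope_length_nm Length of the DNA tightrope (nm). Default
#'   13600 (40 kbp of B-form DNA).
#' @param start_position_nm Initial position; default the midpoint.
#' @param seed Optional RNG seed; the generator is bit-reproducible given
#'   (config, seed).
#' @return List of class `tightrope_sim_config`.
#' @export
tightrope_sim_config <- function(duration_s = 300, fps = 10,
                                 pixel_size_nm = 43.3,
                                 D_short = 3.2e-3, D_long = 3.7e-2,
                                 mean_dwell_s = 14,
                                 lesion_positions_nm = numeric(),
                                 pause_bias = 3, capture_radius_nm = 200,
                                 localization_noise_nm = 36,
                                 noise_corr_time_s = 2,
                                 psf_sigma_nm = 100, photon_rate = 200,
                                 background_photons = 5, blink_prob = 0.02,
                                 dissociation_rate_s = 0,
                                 tightrope_length_nm = 13600,
                                 start_position_nm = tightrope_length_nm / 2,
                                 seed = NULL) {
  if (length(mean_dwell_s) == 1)
    mean_dwell_s <- c(paused = mean_dwell_s, short = mean_dwell_s,
                      long = mean_dwell_s)
  stopifnot(duration_s * fps >= 100, all(mean_dwell_s > 0),
            D_short >= 0, D_long >= 0, localization_noise_nm >= 0,
            blink_prob >= 0, blink_prob < 1, dissociation_rate_s >= 0,
            tightrope_length_nm > 0)
  structure(as.list(environment()), class = "tightrope_sim_config")
}

#' Simulate a three-state switching-diffusion trajectory
#'
#' Continuous-time three-state Markov switching (paused / short-range /
#' long-range) with exponential dwells. Positions evolve as 1D Brownian
#' motion with the mode's diffusion coefficient, reflected at the
#' tightrope ends; paused positions are fixed, and a pause entered within
#' the capture radius of a lesion snaps to the lesion (damage-induced
#' pausing). Lesion proximity multiplies the pause-entry weight by
#' `pause_bias`. Observed positions add Gaussian localization noise;
#' blinking and dissociation set validity flags.
#'
#' @param cfg A [tightrope_sim_config()].
#' @return List with `trajectory` (an `sm_trajectory` of observed
#'   positions) and `truth` (data.frame `frame`, `time_s`,
#'   `position_nm` (true), `mode`, `valid`).
#' @export
simulate_trajectory <- function(cfg = tightrope_sim_config()) {
  stopifnot(inherits(cfg, "tightrope_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fps)
  dt <- 1 / cfg$fps
  modes <- c("paused", "short", "long")
  D_nm2 <- c(paused = 0, short = cfg$D_short, long = cfg$D_long) * 1e6
  x <- numeric(n); state <- character(n)
  cur <- sample(modes, 1)
  pos <- cfg$start_position_nm
  near_lesion <- function(p) length(cfg$lesion_positions_nm) > 0 &&
    min(abs(cfg$lesion_positions_nm - p)) <= cfg$capture_radius_nm
  snap <- function(p) {
    if (length(cfg$lesion_positions_nm) == 0) return(p)
    i <- which.min(abs(cfg$lesion_positions_nm - p))
    if (abs(cfg$lesion_positions_nm[i] - p) <= cfg$capture_radius_nm)
      cfg$lesion_positions_nm[i] else p
  }
  if (cur == "paused") pos <- snap(pos)
  i <- 1L
  while (i <= n) {
    dwell <- stats::rexp(1, 1 / cfg$mean_dwell_s[[cur]])
    nfr <- max(1L, round(dwell / dt))
    last <- min(i + nfr - 1L, n)
    sdstep <- sqrt(2 * D_nm2[[cur]] * dt)
    for (j in i:last) {
      if (sdstep > 0) {
        pos <- pos + stats::rnorm(1, 0, sdstep)
        # reflect at the tightrope ends
        if (pos < 0) pos <- -pos
        if (pos > cfg$tightrope_length_nm)
          pos <- 2 * cfg$tightrope_length_nm - pos
        pos <- min(max(pos, 0), cfg$tightrope_length_nm)
      }
      x[j] <- pos; state[j] <- cur
    }
    i <- last + 1L
    if (i > n) break
    # choose the next mode; pause entry is biased near lesions
    others <- setdiff(modes, cur)
    w <- rep(1, length(others))
    if (cur != "paused") {
      wp <- which(others == "paused")
      if (near_lesion(pos)) w[wp] <- cfg$pause_bias
    }
    cur <- sample(others, 1, prob = w)
    if (cur == "paused") pos <- snap(pos)
  }
  valid <- stats::runif(n) >= cfg$blink_prob
  if (cfg$dissociation_rate_s > 0) {
    t_off <- stats::rexp(1, cfg$dissociation_rate_s)
    valid[which((seq_len(n) - 1) * dt >= t_off)] <- FALSE
  }
  if (cfg$localization_noise_nm > 0 && cfg$noise_corr_time_s > 0) {
    # correlated (OU) tracking noise with stationary sd localization_noise_nm
    a <- exp(-dt / cfg$noise_corr_time_s)
    eps <- stats::rnorm(n, 0, cfg$localization_noise_nm)
    noise <- numeric(n); noise[1] <- eps[1]
    for (j in 2:n) noise[j] <- a * noise[j - 1] + sqrt(1 - a^2) * eps[j]
  } else {
    noise <- stats::rnorm(n, 0, cfg$localization_noise_nm)
  }
  obs <- x + noise
  truth <- data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) * dt,
                      position_nm = x, mode = state, valid = valid)
  list(trajectory = trajectory(obs, valid, dt),
       truth = truth)
}

#' Extract complete mode dwell times from simulator truth
#'
#' Run lengths of the true mode sequence, in seconds; the final (right-
#' censored) dwell is dropped.
#'
#' @param truth Truth table from [simulate_trajectory()].
#' @param mode Optional mode name to filter on.
#' @return Numeric vector of dwell durations (s).
#' @export
true_dwells <- function(truth, mode = NULL) {
  r <- rle(truth$mode)
  dt <- diff(truth$time_s[1:2])
  keep <- seq_len(max(length(r$lengths) - 1L, 0))
  d <- r$lengths[keep] * dt
  m <- r$values[keep]
  if (!is.null(mode)) d <- d[m == mode]
  d
}

#' Render a fluorescence kymograph from a trajectory
#'
#' Paints each frame's Gaussian PSF line profile at the particle's
#' observed position over the whole tightrope, adds Poisson photon noise
#' on top of a uniform background, and renders invalid (blinked or
#' dissociated) frames as background only.
#'
#' @param traj An `sm_trajectory` (typically the observed trajectory of
#'   [simulate_trajectory()], or its truth positions for noiseless
#'   rendering).
#' @param cfg A [tightrope_sim_config()].
#' @param poisson_noise Add Poisson photon noise. Default TRUE.
#' @return A [kymograph()] whose row `p` is centred at position
#'   `(p - 1) * pixel_size_nm`.
#' @export
render_kymograph <- function(traj, cfg = tightrope_sim_config(),
                             poisson_noise = TRUE) {
  stopifnot(inherits(traj, "sm_trajectory"))
  psz <- cfg$pixel_size_nm
  npx <- ceiling(cfg$tightrope_length_nm / psz) + 1L
  centres <- (seq_len(npx) - 1L) * psz
  sig <- cfg$psf_sigma_nm
  inten <- matrix(cfg$background_photons, npx, nrow(traj))
  for (j in seq_len(nrow(traj))) {
    if (!traj$valid[j] || !is.finite(traj$position_nm[j])) next
    prof <- exp(-(centres - traj$position_nm[j])^2 / (2 * sig^2))
    prof <- prof / sum(prof) * cfg$photon_rate
    inten[, j] <- inten[, j] + prof
  }
  if (poisson_noise)
    inten <- matrix(stats::rpois(length(inten), inten), nrow = npx)
  kymograph(inten, psz, attr(traj, "frame_interval_s"))
}

#' Configuration for the AFM field simulator
#'
#' Emulates 1 x 1 um, 512 x 512 px AFM fields of ~538 bp worm-like-chain
#' DNA deposited on mica, with an optional in-plane bend at the lesion
#' position (30% from one end by default) and optional bound-protein
#' blobs of defined integrated volume.
#'
#' @param field_nm Field edge length (nm). Default 1000.
#' @param resolution_px Pixels per edge (>= 64). Default 512.
#' @param dna_length_bp DNA length (bp). Default 538.
#' @param persistence_length_nm Worm-like-chain persistence length (nm).
#'   Default 50.
#' @param n_molecules Molecules attempted per field. Default 6.
#' @param lesion_frac Lesion position as a fraction of contour length,
#'   in (0, 0.5]. Default 0.30.
#' @param lesion_bend_deg In-plane bend imposed at the lesion (degrees,
#'   random sign). Default 0 (no bend).
#' @param occupancy Fraction of molecules carrying a bound protein.
#'   Default 0.
#' @param end_binding_frac Fraction of bound proteins placed at a DNA
#'   end. Default 0.
#' @param at_lesion_frac Fraction of internally bound proteins placed at
#'   the lesion (the rest are uniform over 10-90% of the contour).
#'   Default 0.
#' @param protein_volume_mean_nm3,protein_volume_sd_nm3 Normal
#'   distribution of integrated protein blob volumes (nm^3). Defaults 30
#'   and 13 (truncated at 5).
#' @param protein_sigma_nm Gaussian radius of the protein blob (nm).
#'   Default 2.
#' @param ridge_height_nm,ridge_sigma_nm DNA ridge height and Gaussian
#'   half-width (nm). Defaults 0.3 and 2 (typical for dsDNA imaged in
#'   air).
#' @param noise_sd_nm Additive Gaussian surface roughness (nm).
#'   Default 0.05.
#' @param border_margin_nm Minimum molecule distance from the field edge
#'   (nm). Default 20.
#' @param min_separation_nm Minimum distance between molecules (nm).
#'   Default 30.
#' @param n_free_proteins Free protein blobs (not on DNA) per field.
#'   Default 0.
#' @param seed Optional RNG seed.
#' @return List of class `afm_sim_config`.
#' @export
afm_sim_config <- function(field_nm = 1000, resolution_px = 512,
                           dna_length_bp = 538, persistence_length_nm = 50,
                           n_molecules = 6, lesion_frac = 0.30,
                           lesion_bend_deg = 0, occupancy = 0,
                           end_binding_frac = 0, at_lesion_frac = 0,
                           protein_volume_mean_nm3 = 30,
                           protein_volume_sd_nm3 = 13,
                           protein_sigma_nm = 2, ridge_height_nm = 0.3,
                           ridge_sigma_nm = 2, noise_sd_nm = 0.05,
                           border_margin_nm = 20, min_separation_nm = 30,
                           n_free_proteins = 0, seed = NULL) {
  stopifnot(resolution_px >= 64, lesion_frac > 0, lesion_frac <= 0.5,
            occupancy >= 0, occupancy <= 1, end_binding_frac >= 0,
            end_binding_frac <= 1, persistence_length_nm > 0)
  structure(as.list(environment()), class = "afm_sim_config")
}

# sample a 2D worm-like chain: tangent angle diffuses with variance
# ds / lp per step (equilibrated-in-plane convention), plus an optional
# in-plane bend of `bend_deg` (random sign) at `bend_frac` of the contour
.wlc_path <- function(length_nm, lp_nm, start, theta0, ds = 1,
                      bend_frac = NA, bend_deg = 0) {
  n <- max(ceiling(length_nm / ds), 2)
  dtheta <- stats::rnorm(n, 0, sqrt(ds / lp_nm))
  if (is.finite(bend_frac) && bend_deg != 0) {
    k <- max(2, round(bend_frac * n))
    dtheta[k] <- dtheta[k] + sample(c(-1, 1), 1) * bend_deg * pi / 180
  }
  theta <- theta0 + cumsum(dtheta)
  cbind(x = start[1] + c(0, cumsum(cos(theta) * ds))[1:n],
        y = start[2] + c(0, cumsum(sin(theta) * ds))[1:n])
}

# stamp a Gaussian ridge along a path into the height matrix (max-combine,
# so overlapping stamps do not double-count height)
.stamp_ridge <- function(H, path, height, sigma, psz) {
  half <- ceiling(3 * sigma / psz)
  n <- nrow(H)
  for (i in seq_len(nrow(path))) {
    cx <- path[i, 1] / psz; cy <- path[i, 2] / psz
    r0 <- max(1, floor(cy - half)); r1 <- min(n, ceiling(cy + half))
    c0 <- max(1, floor(cx - half)); c1 <- min(n, ceiling(cx + half))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - cy)^2, (cc - cx)^2, "+") * psz^2
    H[rr, cc] <- pmax(H[rr, cc], height * exp(-d2 / (2 * sigma^2)))
  }
  H
}

# additively stamp a Gaussian cap of integrated volume V (nm^3)
.stamp_blob <- function(H, centre, volume, sigma, psz) {
  h0 <- volume / (2 * pi * sigma^2)
  half <- ceiling(4 * sigma / psz)
  n <- nrow(H)
  cx <- centre[1] / psz; cy <- centre[2] / psz
  r0 <- max(1, floor(cy - half)); r1 <- min(n, ceiling(cy + half))
  c0 <- max(1, floor(cx - half)); c1 <- min(n, ceiling(cx + half))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - cy)^2, (cc - cx)^2, "+") * psz^2
  H[rr, cc] <- H[rr, cc] + h0 * exp(-d2 / (2 * sigma^2))
  H
}

#' Simulate an AFM height-map field with ground truth
#'
#' Places worm-like-chain DNA molecules (rejection-sampled to stay inside
#' the field and apart from each other), renders them as Gaussian ridges,
#' optionally bends them at the lesion position, adds protein blobs of
#' known integrated volume at lesion / internal / end positions, free
#' protein blobs, and Gaussian surface roughness. Fully reproducible
#' given (config, seed). If placement repeatedly fails the field carries
#' fewer molecules than requested (recorded in the truth table).
#'
#' @param cfg An [afm_sim_config()].
#' @return List with `map` (a [height_map()]) and `truth` (list with
#'   `molecules`: per-molecule path, contour length, bend, protein
#'   placement and volume; `free_proteins`: positions and volumes).
#' @export
simulate_afm_field <- function(cfg = afm_sim_config()) {
  stopifnot(inherits(cfg, "afm_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  psz <- cfg$field_nm / cfg$resolution_px
  H <- matrix(0, cfg$resolution_px, cfg$resolution_px)
  L <- bp_to_nm(cfg$dna_length_bp)
  margin <- cfg$border_margin_nm
  molecules <- list()
  placed_pts <- NULL
  for (m in seq_len(cfg$n_molecules)) {
    path <- NULL
    for (try in 1:60) {
      start <- stats::runif(2, margin, cfg$field_nm - margin)
      cand <- .wlc_path(L, cfg$persistence_length_nm, start,
                        stats::runif(1, 0, 2 * pi),
                        bend_frac = cfg$lesion_frac,
                        bend_deg = cfg$lesion_bend_deg)
      if (any(cand < margin) || any(cand > cfg$field_nm - margin)) next
      if (!is.null(placed_pts)) {
        sub <- cand[seq(1, nrow(cand), by = 4), , drop = FALSE]
        dmin <- min(vapply(seq_len(nrow(sub)), function(i)
          min((placed_pts[, 1] - sub[i, 1])^2 + (placed_pts[, 2] - sub[i, 2])^2),
          numeric(1)))
        if (sqrt(dmin) < cfg$min_separation_nm) next
      }
      path <- cand
      break
    }
    if (is.null(path)) next                     # overcrowded field
    placed_pts <- rbind(placed_pts, path[seq(1, nrow(path), by = 4), ])
    H <- .stamp_ridge(H, path, cfg$ridge_height_nm, cfg$ridge_sigma_nm, psz)
    prot <- NULL
    if (stats::runif(1) < cfg$occupancy) {
      v <- max(stats::rnorm(1, cfg$protein_volume_mean_nm3,
                            cfg$protein_volume_sd_nm3), 5)
      u <- stats::runif(1)
      if (u < cfg$end_binding_frac) {
        frac <- sample(c(0, 1), 1)
      } else if (stats::runif(1) < cfg$at_lesion_frac) {
        frac <- cfg$lesion_frac
      } else {
        frac <- stats::runif(1, 0.1, 0.9)
      }
      idx <- min(max(1, round(frac * nrow(path))), nrow(path))
      H <- .stamp_blob(H, path[idx, ], v, cfg$protein_sigma_nm, psz)
      prot <- list(position_frac = frac, volume_nm3 = v,
                   end_bound = frac %in% c(0, 1),
                   centre_nm = path[idx, ])
    }
    seg <- sqrt(rowSums(diff(path)^2))
    molecules[[length(molecules) + 1L]] <-
      list(path = path, contour_length_nm = sum(seg),
           lesion_frac = cfg$lesion_frac,
           bend_deg = cfg$lesion_bend_deg, protein = prot)
  }
  free <- list()
  for (k in seq_len(cfg$n_free_proteins)) {
    v <- max(stats::rnorm(1, cfg$protein_volume_mean_nm3,
                          cfg$protein_volume_sd_nm3), 5)
    ctr <- stats::runif(2, margin, cfg$field_nm - margin)
    H <- .stamp_blob(H, ctr, v, cfg$protein_sigma_nm, psz)
    free[[length(free) + 1L]] <- list(centre_nm = ctr, volume_nm3 = v)
  }
  if (cfg$noise_sd_nm > 0)
    H <- H + matrix(stats::rnorm(length(H), 0, cfg$noise_sd_nm), nrow(H))
  list(map = height_map(H, psz),
       truth = list(molecules = molecules, free_proteins = free))
}

#' Simulate an EMSA titration from the depletion isotherm
#'
#' Percent bound from the single-site depletion model plus truncated
#' Gaussian noise, clipped to \[0, 100\].
#'
#' @param K_D True dissociation constant (nM).
#' @param D Total DNA concentration (nM). Default 8.
#' @param P_grid Protein concentrations (nM).
#' @param noise_sd_pct Additive noise sd in percentage points. Default 0.
#' @param seed Optional RNG seed.
#' @return A [binding_isotherm()] with attribute `true_K_D`.
#' @export
simulate_emsa <- function(K_D, D = 8,
                          P_grid = c(0, 25, 50, 100, 200, 400, 800, 1600,
                                     3200, 6400),
                          noise_sd_pct = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fb <- fraction_bound(P_grid, D, K_D)
  if (noise_sd_pct > 0)
    fb <- pmin(pmax(fb + stats::rnorm(length(fb), 0, noise_sd_pct), 0), 100)
  iso <- binding_isotherm(P_grid, fb, D)
  attr(iso, "true_K_D") <- K_D
  iso
}
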