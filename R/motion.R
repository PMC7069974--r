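#' Segmentation configuration for episodic-diffusion analysis
#'
#' Thresholds defining the three behavioural modes of a DNA-bound
#' particle: paused (positional range <= `motile_threshold_nm`),
#' short-range diffusion (range <= `long_threshold_nm`) and long-range
#' diffusion (range > `long_threshold_nm`). A shorter-range mode may
#' interrupt a longer-range one only if it persists for at least
#' `min_phase_s`; a particle already paused when recording starts may
#' produce a leading paused phase as short as `lead_min_phase_s`.
#'
#' @param motile_threshold_nm Paused/motile displacement threshold (nm).
#'   Default 130 (~3 pixels, ~400 bp; about 3.6x the positional
#'   uncertainty of 36 nm).
#' @param long_threshold_nm Short/long displacement threshold (nm).
#'   Default 690 (2030 bp of B-form DNA, the lesion spacing of the
#'   defined-array substrate).
#' @param min_phase_s Minimum duration for an interrupting phase (s).
#'   Default 5.
#' @param lead_min_phase_s Minimum duration for a leading paused phase
#'   (s). Default `min_phase_s / 2`.
#' @param dissociation_gap_frames Invalid-frame gap interpreted as
#'   dissociation (frames). Default 200 (~20 s).
#' @param pause_site_merge_nm Paused phases closer than this are one
#'   pause site (nm). Default 130.
#' @param min_msd_pairs Minimum displacement pairs per MSD lag. Default 5.
#' @param msd_lag_frac Fraction of available lags used in the diffusion
#'   fit. Default 0.25.
#' @param r2_min Minimum R^2 for an accepted diffusion fit. Default 0.8.
#' @param min_lag_frac Minimum fraction of the MSD curve the fit must
#'   use. Default 0.10.
#' @return List of class `segmentation_config`.
#' @export
segmentation_config <- function(motile_threshold_nm = 130,
                                long_threshold_nm = 690,
                                min_phase_s = 5,
                                lead_min_phase_s = min_phase_s / 2,
                                dissociation_gap_frames = 200,
                                pause_site_merge_nm = 130,
                                min_msd_pairs = 5,
                                msd_lag_frac = 0.25,
                                r2_min = 0.8,
                                min_lag_frac = 0.10) {
  stopifnot(long_threshold_nm > motile_threshold_nm, motile_threshold_nm > 0,
            min_phase_s > 0, dissociation_gap_frames >= 1)
  structure(list(motile_threshold_nm = motile_threshold_nm,
                 long_threshold_nm = long_threshold_nm,
                 min_phase_s = min_phase_s,
                 lead_min_phase_s = lead_min_phase_s,
                 dissociation_gap_frames = dissociation_gap_frames,
                 pause_site_merge_nm = pause_site_merge_nm,
                 min_msd_pairs = min_msd_pairs,
                 msd_lag_frac = msd_lag_frac,
                 r2_min = r2_min, min_lag_frac = min_lag_frac),
            class = "segmentation_config")
}

# analyzed window: frames before the first invalid gap of at least
# `gap` frames; returns index range and whether a terminal gap exists
.analysis_window <- function(valid, gap) {
  n <- length(valid)
  r <- rle(!valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  big <- which(r$values & r$lengths >= gap)
  if (length(big) == 0)
    return(list(last = n, dissociated = FALSE))
  first <- big[1]
  list(last = starts[first] - 1L,
       dissociated = any(r$values & r$lengths >= gap & ends == n))
}

#' Classify a particle as stationary/motile and persistent/dissociated
#'
#' A particle is motile when the range of its valid positions exceeds the
#' motile threshold over the analyzed window, and dissociated when its
#' signal disappears for at least `dissociation_gap_frames` through the
#' end of the recording. An interior gap of that length truncates the
#' analyzed trajectory at the gap.
#'
#' @param traj An `sm_trajectory`.
#' @param cfg A [segmentation_config()].
#' @return List with `motility` ("stationary"/"motile"), `persistence`
#'   ("persistent"/"dissociated"), `range_nm`, `analyzed_frames`.
#'   Trajectories with fewer than 50 valid frames in the analyzed window
#'   raise an error (unclassifiable).
#' @export
classify_particle <- function(traj, cfg = segmentation_config()) {
  stopifnot(inherits(traj, "sm_trajectory"))
  win <- .analysis_window(traj$valid, cfg$dissociation_gap_frames)
  x <- traj$position_nm[seq_len(win$last)]
  x <- x[is.finite(x)]
  if (length(x) < 50) stop("too few valid frames to classify")
  rng <- diff(range(x))
  list(motility = if (rng > cfg$motile_threshold_nm) "motile" else "stationary",
       persistence = if (win$dissociated) "dissociated" else "persistent",
       range_nm = rng, analyzed_frames = win$last)
}

# greedy maximal-window scan: from each start, extend while the range of
# valid positions stays within `thr`; accept when the window lasts at
# least `need(start)` seconds, else advance one frame. Deterministic
# (earliest start, longest extension).
.scan_windows <- function(x, dt, thr, need_s, lead_s = need_s) {
  n <- length(x)
  out <- list(); s <- 1L
  while (s <= n) {
    lo <- Inf; hi <- -Inf; e <- s - 1L
    while (e < n) {
      xv <- x[e + 1L]
      nlo <- if (is.finite(xv)) min(lo, xv) else lo
      nhi <- if (is.finite(xv)) max(hi, xv) else hi
      if (is.finite(nlo) && is.finite(nhi) && nhi - nlo > thr) break
      lo <- nlo; hi <- nhi; e <- e + 1L
    }
    need <- if (s == 1L) lead_s else need_s
    if (e >= s && (e - s + 1L) * dt >= need) {
      out[[length(out) + 1L]] <- c(s, e)
      s <- e + 1L
    } else s <- s + 1L
  }
  out
}

.phase_row <- function(mode, s, e, x, dt) {
  xv <- x[s:e]; xv <- xv[is.finite(xv)]
  data.frame(mode = mode, start = s, end = e + 1L,           # half-open
             duration_s = (e - s + 1L) * dt,
             displacement_nm = if (length(xv) >= 2) diff(range(xv)) else 0,
             n_valid = length(xv))
}

#' Segment a motile trajectory into paused / short / long phases
#'
#' Deterministic left-to-right segmentation by positional range:
#' 1. maximal paused runs (range <= motile threshold, lasting at least
#'    `min_phase_s`; a leading run may be as short as `lead_min_phase_s`)
#'    are extracted greedily;
#' 2. the remaining runs are labelled short-range (range <= long
#'    threshold) or long-range;
#' 3. a run exceeding the long threshold is split once by any embedded
#'    short-range windows of at least `min_phase_s` (the interruption
#'    rule), and the remaining fragments are relabelled by their own
#'    range.
#' Phases partition the analyzed frames.
#'
#' @param traj An `sm_trajectory`.
#' @param cfg A [segmentation_config()].
#' @return data.frame of phases: `mode` ("paused"/"short"/"long"),
#'   `start`, `end` (half-open frame interval, 1-based), `duration_s`,
#'   `displacement_nm`, `n_valid`.
#' @export
segment_phases <- function(traj, cfg = segmentation_config()) {
  stopifnot(inherits(traj, "sm_trajectory"))
  dt <- attr(traj, "frame_interval_s")
  win <- .analysis_window(traj$valid, cfg$dissociation_gap_frames)
  x <- traj$position_nm[seq_len(win$last)]
  n <- length(x)
  if (n < 2) stop("trajectory too short to segment")
  pauses <- .scan_windows(x, dt, cfg$motile_threshold_nm,
                          cfg$min_phase_s, cfg$lead_min_phase_s)
  phases <- list()
  bounds <- c(0L, unlist(lapply(pauses, function(p) p)), n + 1L)
  # walk alternating motile gap / pause
  cursor <- 1L
  emit_motile <- function(a, b) {
    # a..b inclusive motile run
    xv <- x[a:b]; rng <- if (sum(is.finite(xv)) >= 2) diff(range(xv, na.rm = TRUE)) else 0
    if (rng <= cfg$long_threshold_nm)
      return(list(.phase_row("short", a, b, x, dt)))
    shorts <- .scan_windows(x[a:b], dt, cfg$long_threshold_nm,
                            cfg$min_phase_s, cfg$min_phase_s)
    if (length(shorts) == 0)
      return(list(.phase_row("long", a, b, x, dt)))
    res <- list(); pos <- a
    for (sw in shorts) {
      sa <- a + sw[1] - 1L; sb <- a + sw[2] - 1L
      if (sa > pos) {
        xr <- x[pos:(sa - 1L)]
        rr <- if (sum(is.finite(xr)) >= 2) diff(range(xr, na.rm = TRUE)) else 0
        res[[length(res) + 1L]] <-
          .phase_row(if (rr > cfg$long_threshold_nm) "long" else "short",
                     pos, sa - 1L, x, dt)
      }
      res[[length(res) + 1L]] <- .phase_row("short", sa, sb, x, dt)
      pos <- sb + 1L
    }
    if (pos <= b) {
      xr <- x[pos:b]
      rr <- if (sum(is.finite(xr)) >= 2) diff(range(xr, na.rm = TRUE)) else 0
      res[[length(res) + 1L]] <-
        .phase_row(if (rr > cfg$long_threshold_nm) "long" else "short",
                   pos, b, x, dt)
    }
    res
  }
  for (p in pauses) {
    if (p[1] > cursor)
      phases <- c(phases, emit_motile(cursor, p[1] - 1L))
    phases <- c(phases, list(.phase_row("paused", p[1], p[2], x, dt)))
    cursor <- p[2] + 1L
  }
  if (cursor <= n)
    phases <- c(phases, emit_motile(cursor, n))
  out <- do.call(rbind, phases)
  rownames(out) <- NULL
  attr(out, "frame_interval_s") <- dt
  out
}

#' Fraction of time spent in each diffusive mode
#'
#' @param phases Phase table from [segment_phases()].
#' @return Named numeric vector of per-mode duration fractions
#'   (paused, short, long), summing to 1.
#' @export
mode_time_fractions <- function(phases) {
  stopifnot(nrow(phases) >= 1)
  tot <- sum(phases$duration_s)
  fr <- vapply(c("paused", "short", "long"),
               function(m) sum(phases$duration_s[phases$mode == m]) / tot,
               numeric(1))
  fr
}

#' Count distinct pause sites
#'
#' A pause site is a tightrope position at which the particle spent at
#' least one paused phase; the mean positions of paused phases within
#' `pause_site_merge_nm` of each other (single linkage) belong to one
#' site.
#'
#' @param phases Phase table from [segment_phases()].
#' @param traj The `sm_trajectory` the phases came from.
#' @param cfg A [segmentation_config()].
#' @return List with `n_sites` and `site_positions_nm`.
#' @export
pause_sites <- function(phases, traj, cfg = segmentation_config()) {
  paused <- phases[phases$mode == "paused", , drop = FALSE]
  if (nrow(paused) == 0) return(list(n_sites = 0L, site_positions_nm = numeric()))
  pos <- vapply(seq_len(nrow(paused)), function(i) {
    xv <- traj$position_nm[paused$start[i]:(paused$end[i] - 1L)]
    mean(xv, na.rm = TRUE)
  }, numeric(1))
  ord <- sort(pos)
  grp <- cumsum(c(1, diff(ord) > cfg$pause_site_merge_nm))
  sites <- tapply(ord, grp, mean)
  list(n_sites = length(sites), site_positions_nm = as.numeric(sites))
}

#' Mean squared displacement of a trajectory phase
#'
#' Time-averaged MSD: `MSD(n dt) = 1/(N-n) * sum_i (x_{i+n} - x_i)^2`
#' over the `N` frames of the phase, evaluated over pairs in which both
#' frames are valid. Lags supported by fewer than `min_pairs` pairs are
#' dropped.
#'
#' @param position_nm Positions (nm) of the phase; `NA` where invalid.
#' @param frame_interval_s Seconds per frame.
#' @param min_pairs Minimum valid pairs per lag. Default 5.
#' @return Object of class `msd_curve`: data.frame `lag_frames`, `lag_s`,
#'   `msd_nm2`, `n_pairs`, with attribute `n_frames`. Errors when the
#'   phase has fewer than 10 valid frames.
#' @export
msd <- function(position_nm, frame_interval_s = 0.1, min_pairs = 5) {
  x <- position_nm
  N <- length(x)
  if (sum(is.finite(x)) < 10) stop("phase has fewer than 10 valid frames")
  rows <- lapply(seq_len(N - 1), function(n) {
    d <- x[(n + 1):N] - x[seq_len(N - n)]
    d <- d[is.finite(d)]
    if (length(d) < min_pairs) return(NULL)
    data.frame(lag_frames = n, lag_s = n * frame_interval_s,
               msd_nm2 = mean(d^2), n_pairs = length(d))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no MSD lags with enough pairs")
  structure(out, n_frames = N, class = c("msd_curve", "data.frame"))
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Ordinary least squares of `MSD(n dt) = 2 D (n dt) + y` over the first
#' `msd_lag_frac` of the available lags (at least 2), where the intercept
#' `y` absorbs static localization error. Fits with R^2 below `r2_min`,
#' using fewer than `min_lag_frac` of the MSD points, with fewer than 3
#' fitted lags, or with non-positive slope are not accepted.
#'
#' @param curve An `msd_curve`.
#' @param cfg A [segmentation_config()].
#' @return Object of class `diffusion_fit`: list with `D_um2_s`,
#'   `intercept_um2`, `r_squared`, `n_lags_used`, `accepted`, `reason`.
#' @export
fit_diffusion <- function(curve, cfg = segmentation_config()) {
  stopifnot(inherits(curve, "msd_curve"))
  N <- attr(curve, "n_frames")
  n_use <- max(floor(cfg$msd_lag_frac * (N - 1)), 2)
  sel <- curve[curve$lag_frames <= n_use, , drop = FALSE]
  reject <- function(reason) structure(
    list(D_um2_s = NA_real_, intercept_um2 = NA_real_, r_squared = NA_real_,
         n_lags_used = nrow(sel), accepted = FALSE, reason = reason),
    class = "diffusion_fit")
  if (nrow(sel) < 3) return(reject("fewer than 3 usable lags"))
  fit <- stats::lm(msd_nm2 ~ lag_s, data = sel)
  slope <- unname(stats::coef(fit)[2]); icpt <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  D <- slope / 2 / 1e6                       # nm^2/s -> um^2/s
  y <- icpt / 1e6
  accepted <- TRUE; reason <- "ok"
  if (r2 < cfg$r2_min) { accepted <- FALSE; reason <- "low R^2" }
  else if (nrow(sel) / nrow(curve) < cfg$min_lag_frac) {
    accepted <- FALSE; reason <- "fit uses <10% of MSD points"
  } else if (D <= 0) { accepted <- FALSE; reason <- "non-positive slope" }
  structure(list(D_um2_s = D, intercept_um2 = y, r_squared = r2,
                 n_lags_used = nrow(sel), accepted = accepted,
                 reason = reason),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Diffusion fit: D = %.3g um^2/s, R^2 = %.3f, %s\n",
              x$D_um2_s, x$r_squared,
              if (x$accepted) "accepted" else paste0("rejected (", x$reason, ")")))
  invisible(x)
}

#' Physical parameters for sliding-theory calculations
#'
#' @param temperature_K Temperature. Default 298.
#' @param viscosity_Pa_s Solvent viscosity. Default 1e-3 (water).
#' @param radius_nm Hydrodynamic radius of the tracked particle (protein
#'   plus quantum-dot label). Default 12.
#' @param pitch_bp Helical pitch of B-form DNA in bp/turn. Default 10.5.
#' @param rise_nm Helical rise per bp. Default 0.34.
#' @param offcenter_nm Distance from the particle centre to the helical
#'   axis. Default `radius_nm + 1`.
#' @return List of class `theory_params`, including `kBT_J`.
#' @export
theory_params <- function(temperature_K = 298, viscosity_Pa_s = 1e-3,
                          radius_nm = 12, pitch_bp = 10.5, rise_nm = 0.34,
                          offcenter_nm = radius_nm + 1) {
  stopifnot(temperature_K > 0, viscosity_Pa_s > 0, radius_nm > 0,
            pitch_bp > 0, rise_nm > 0, offcenter_nm > 0)
  structure(list(temperature_K = temperature_K,
                 viscosity_Pa_s = viscosity_Pa_s, radius_nm = radius_nm,
                 pitch_bp = pitch_bp, rise_nm = rise_nm,
                 offcenter_nm = offcenter_nm,
                 kBT_J = 1.380649e-23 * temperature_K),
            class = "theory_params")
}

#' Theoretical diffusion limit for rotation-coupled sliding
#'
#' Upper bound on the 1D diffusion coefficient of a particle that tracks
#' the DNA helix while sliding, so every helical pitch of translation
#' costs one full rotation: the translational Stokes drag is augmented by
#' the rotational drag of the sphere spinning about the helical axis at a
#' distance `R_OC`,
#' `D_lim = kBT / (6 pi eta a + (2 pi / pitch)^2 (8 pi eta a^3 + 6 pi eta a R_OC^2))`
#' with pitch in metres of contour per turn. As the pitch goes to
#' infinity the expression reduces to the Stokes-Einstein coefficient.
#'
#' @param params A [theory_params()].
#' @return D_lim in um^2/s.
#' @export
d_limit <- function(params = theory_params()) {
  stopifnot(inherits(params, "theory_params"))
  a <- params$radius_nm * 1e-9
  roc <- params$offcenter_nm * 1e-9
  pitch_m <- params$pitch_bp * params$rise_nm * 1e-9
  eta <- params$viscosity_Pa_s
  drag <- 6 * pi * eta * a +
    (2 * pi / pitch_m)^2 * (8 * pi * eta * a^3 + 6 * pi * eta * a * roc^2)
  params$kBT_J / drag * 1e12                   # m^2/s -> um^2/s
}

#' Energy-landscape roughness from a diffusion-coefficient ratio
#'
#' For diffusion on a rugged binding-energy landscape with Gaussian
#' roughness sigma, the observed coefficient is suppressed as
#' `D_obs = D_ref * exp(-(sigma/kBT)^2)`; inverting gives
#' `sigma = sqrt(ln(D_ref / D_obs))` in units of kBT.
#'
#' @param d_obs Observed diffusion coefficient (same units as `d_ref`).
#' @param d_ref Reference (smooth-landscape) diffusion coefficient.
#' @return Roughness sigma in kBT units.
#' @export
energy_barrier <- function(d_obs, d_ref) {
  if (d_obs <= 0 || d_ref <= 0) stop("diffusion coefficients must be positive")
  if (d_obs > d_ref) stop("d_obs must not exceed d_ref")
  sqrt(log(d_ref / d_obs))
}
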