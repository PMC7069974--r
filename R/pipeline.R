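#' Run the tightrope analysis pipeline end to end
#'
#' Simulates (or accepts) a set of particle recordings, optionally
#' renders and re-localizes them through the kymograph stage, classifies
#' each particle, segments the motile ones into paused / short-range /
#' long-range phases, and aggregates mode time fractions, pause-site
#' counts, per-phase diffusion coefficients and phase-lifetime fits into
#' a JSON-serializable summary report with a reproducibility manifest.
#'
#' @param n_particles Number of recordings. Default 10.
#' @param sim A [tightrope_sim_config()]; its `seed` field is ignored in
#'   favour of `seed`.
#' @param cfg A [segmentation_config()].
#' @param seed Integer seed; recording `i` uses `seed + i`. Default 1.
#' @param render Push each recording through rendering and Gaussian
#'   re-localization instead of using the simulator's observed positions
#'   directly. Default FALSE (faster; identical downstream logic).
#' @param trajectories Optional list of `sm_trajectory` objects to
#'   analyze instead of simulating.
#' @return List of class `tightrope_report`: `n_particles`,
#'   `classification` (counts), `mode_fractions` (time fractions over
#'   motile particles; sums to 1), `pause_site_counts`, `phases`
#'   (combined phase table), `diffusion` (per-phase accepted D fits),
#'   `lifetimes` (per-mode exponential fits, when enough phases),
#'   `manifest`.
#' @export
run_tightrope_pipeline <- function(n_particles = 10,
                                   sim = tightrope_sim_config(),
                                   cfg = segmentation_config(),
                                   seed = 1, render = FALSE,
                                   trajectories = NULL) {
  if (is.null(trajectories)) {
    trajectories <- lapply(seq_len(n_particles), function(i) {
      s <- sim; s$seed <- seed + i
      out <- simulate_trajectory(s)
      if (render) {
        set.seed(seed + i)
        localize(render_kymograph(out$trajectory, s))
      } else out$trajectory
    })
  }
  n_particles <- length(trajectories)
  cls <- lapply(trajectories, function(tr)
    tryCatch(classify_particle(tr, cfg), error = function(e) NULL))
  keep <- !vapply(cls, is.null, logical(1))
  motile <- vapply(cls[keep], function(x) x$motility == "motile", logical(1))
  classification <- c(
    stationary = sum(!motile), motile = sum(motile),
    persistent = sum(vapply(cls[keep], function(x)
      x$persistence == "persistent", logical(1))),
    dissociated = sum(vapply(cls[keep], function(x)
      x$persistence == "dissociated", logical(1))))
  phase_tabs <- list(); site_counts <- integer(); dcoef <- list()
  idx_keep <- which(keep)
  for (k in seq_along(idx_keep)) {
    if (!motile[k]) next
    tr <- trajectories[[idx_keep[k]]]
    ph <- segment_phases(tr, cfg)
    ph$particle <- idx_keep[k]
    phase_tabs[[length(phase_tabs) + 1L]] <- ph
    site_counts <- c(site_counts, pause_sites(ph, tr, cfg)$n_sites)
    dt <- attr(tr, "frame_interval_s")
    for (r in seq_len(nrow(ph))) {
      if (ph$mode[r] == "paused" || ph$n_valid[r] < 10) next
      mc <- tryCatch(msd(tr$position_nm[ph$start[r]:(ph$end[r] - 1L)], dt,
                         cfg$min_msd_pairs), error = function(e) NULL)
      if (is.null(mc)) next
      df <- fit_diffusion(mc, cfg)
      if (df$accepted)
        dcoef[[length(dcoef) + 1L]] <- data.frame(
          particle = idx_keep[k], mode = ph$mode[r],
          duration_s = ph$duration_s[r], D_um2_s = df$D_um2_s,
          r_squared = df$r_squared)
    }
  }
  phases <- if (length(phase_tabs)) do.call(rbind, phase_tabs) else NULL
  mode_fractions <- if (!is.null(phases)) mode_time_fractions(phases) else
    c(paused = NA_real_, short = NA_real_, long = NA_real_)
  diffusion <- if (length(dcoef)) do.call(rbind, dcoef) else NULL
  lifetimes <- list()
  if (!is.null(phases)) {
    for (m in c("paused", "short", "long")) {
      d <- phases$duration_s[phases$mode == m]
      if (length(d) >= 20)
        lifetimes[[m]] <- unclass(fit_exponential_lifetime(d))
    }
  }
  structure(list(
    n_particles = n_particles, classification = classification,
    mode_fractions = mode_fractions, pause_site_counts = site_counts,
    phases = phases, diffusion = diffusion, lifetimes = lifetimes,
    manifest = list(seed = seed, sim = unclass(sim), cfg = unclass(cfg),
                    package_version = as.character(utils::packageVersion("dnatracks")))),
    class = "tightrope_report")
}

#' Run the AFM quantification pipeline end to end
#'
#' Simulates AFM fields, then runs background estimation, particle
#' detection, DNA tracing, complex classification, volume / position /
#' bend-angle measurement and Gaussian distribution fits; protein volumes
#' are converted to molecular weight with the supplied calibration line.
#' Fields without DNA (free-protein depositions) contribute particle
#' volumes only.
#'
#' @param n_fields Number of fields. Default 4.
#' @param sim An [afm_sim_config()]; its `seed` is ignored in favour of
#'   `seed`.
#' @param calibration A [calibration_line()] for MW conversion. Default
#'   slope 1.14 nm^3/kDa, intercept -2.00 nm^3.
#' @param seed Integer seed; field `i` uses `seed + i`. Default 1.
#' @param ... Passed to [measure_complexes()].
#' @return List of class `afm_report`: `complexes` (combined measurement
#'   table), `free_volumes_nm3`, `n_molecules`, and Gaussian fits
#'   `position_fit`, `volume_fit`, `angle_fit` (NULL when too few
#'   measurements), plus `manifest`.
#' @export
run_afm_pipeline <- function(n_fields = 4, sim = afm_sim_config(),
                             calibration = calibration_line(1.14, -2.00),
                             seed = 1, ...) {
  complexes <- list(); free_v <- numeric(); n_mol <- 0L
  for (i in seq_len(n_fields)) {
    s <- sim; s$seed <- seed + i
    field <- simulate_afm_field(s)
    if (s$n_molecules > 0) {
      tab <- measure_complexes(field$map, bp_to_nm(s$dna_length_bp),
                               calibration = calibration, ...)
      n_mol <- n_mol + attr(tab, "n_molecules")
      if (nrow(tab) > 0) {
        tab$field <- i
        complexes[[length(complexes) + 1L]] <- tab
      }
    }
    if (s$n_free_proteins > 0) {
      parts <- detect_particles(field$map)
      free_v <- c(free_v, vapply(parts, function(p) p$volume_nm3, numeric(1)))
    }
  }
  complexes <- if (length(complexes)) do.call(rbind, complexes) else NULL
  gfit_or_null <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 10) unclass(fit_gaussian(v)) else NULL
  }
  structure(list(
    complexes = complexes, free_volumes_nm3 = free_v, n_molecules = n_mol,
    n_complexes = if (is.null(complexes)) 0L else nrow(complexes),
    position_fit = if (!is.null(complexes))
      gfit_or_null(complexes$position_pct[!complexes$end_bound]) else NULL,
    volume_fit = if (!is.null(complexes))
      gfit_or_null(complexes$v_protein_nm3) else gfit_or_null(free_v),
    angle_fit = if (!is.null(complexes))
      gfit_or_null(complexes$theta_deg) else NULL,
    manifest = list(seed = seed, sim = unclass(sim),
                    calibration = unclass(calibration),
                    package_version = as.character(utils::packageVersion("dnatracks")))),
    class = "afm_report")
}
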