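#' Construct a calibrated AFM height map
#'
#' @param heights Numeric matrix of heights in nm (rows = y, cols = x).
#' @param pixel_size_nm Physical pixel size in nm/px. The default
#'   1000/512 corresponds to a 1 x 1 um field scanned at 512 x 512 px.
#' @return Object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size_nm = 1000 / 512) {
  stopifnot(is.matrix(heights), is.numeric(heights), pixel_size_nm > 0)
  if (any(!is.finite(heights))) stop("heights must be finite")
  structure(list(heights = heights, pixel_size_nm = pixel_size_nm),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("AFM height map: %d x %d px, %.3f nm/px, heights %.2f..%.2f nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size_nm,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Estimate the background (substrate) height of an AFM image
#'
#' The mica substrate dominates the image area, so the background height
#' is taken as the mode of the height distribution (peak of a kernel
#' density estimate). If the distribution has no pronounced peak, the
#' median is returned instead and flagged via the `"method"` attribute.
#'
#' @param map A [height_map()].
#' @return Background height in nm, with attribute `method` equal to
#'   `"mode"` or `"median"`.
#' @export
estimate_background <- function(map) {
  stopifnot(inherits(map, "height_map"))
  h <- as.vector(map$heights)
  if (diff(range(h)) == 0)
    return(structure(h[1], method = "mode"))
  d <- stats::density(h, n = 512)
  peak <- d$x[which.max(d$y)]
  # peak prominence: a real substrate plane towers over the rest
  if (max(d$y) < 2 * stats::median(d$y))
    return(structure(stats::median(h), method = "median"))
  structure(peak, method = "mode")
}

#' Estimate background noise of an AFM image
#'
#' Robust noise standard deviation from the sub-background residuals:
#' pixels below the background plane carry only noise (particles only add
#' height), so sigma is estimated as `median(|h - B| for h < B) / 0.6745`.
#'
#' @param map A [height_map()].
#' @param background Background height (nm); estimated if missing.
#' @return Noise sd in nm.
#' @export
estimate_noise_sd <- function(map, background = estimate_background(map)) {
  r <- as.vector(map$heights) - as.numeric(background)
  neg <- r[r < 0]
  if (length(neg) < 10) return(0)
  stats::median(abs(neg)) / 0.6745
}

# 4-connected labelling of a logical mask (EBImage::bwlabel convention).
.label_mask <- function(mask) {
  EBImage::bwlabel(mask * 1)
}

#' Detect particle footprints above a density threshold
#'
#' Thresholds the image at `background + threshold_sigma * noise sd` and
#' extracts 4-connected components. Each footprint carries its area
#' `A` (nm^2), mean height `H` (nm), volume `V = A * (H - B)` (nm^3) and
#' height-weighted centroid (nm). Components smaller than `min_px` pixels
#' are discarded as noise.
#'
#' @param map A [height_map()].
#' @param background Background height (nm); estimated if missing.
#' @param threshold_sigma Detection threshold in units of the background
#'   noise sd. Default 3.
#' @param min_px Minimum footprint size in pixels. Default 4.
#' @return A list of `particle_footprint` objects (possibly empty), each a
#'   list with `pixels` (two-column matrix of row/col indices), `area_nm2`,
#'   `mean_height_nm`, `background_nm`, `volume_nm3`, `centroid_nm`,
#'   `pixel_size_nm`.
#' @export
detect_particles <- function(map, background = estimate_background(map),
                             threshold_sigma = 3, min_px = 4) {
  stopifnot(inherits(map, "height_map"))
  B <- as.numeric(background)
  sn <- estimate_noise_sd(map, B)
  mask <- map$heights > B + threshold_sigma * sn
  if (!any(mask)) return(list())
  lab <- .label_mask(mask)
  ids <- setdiff(unique(as.vector(lab)), 0)
  psz <- map$pixel_size_nm
  out <- list()
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_px) next
    h <- map$heights[idx]
    w <- pmax(h - B, 0)
    centroid <- c(x = sum(idx[, 2] * w) / sum(w) * psz,
                  y = sum(idx[, 1] * w) / sum(w) * psz)
    fp <- structure(list(pixels = idx, heights = h,
                         area_nm2 = nrow(idx) * psz^2,
                         mean_height_nm = mean(h), background_nm = B,
                         volume_nm3 = nrow(idx) * psz^2 * (mean(h) - B),
                         centroid_nm = centroid, pixel_size_nm = psz),
                    class = "particle_footprint")
    out[[length(out) + 1L]] <- fp
  }
  out
}

#' Particle volume from a footprint
#'
#' `V = A x (H - B)`, the footprint area times the mean height above
#' background; algebraically identical to the per-pixel sum
#' `sum(h_i - B) * pixel_size^2`. Footprints whose mean height falls below
#' the background give a negative volume and are flagged via the
#' `"flagged"` attribute.
#'
#' @param footprint A `particle_footprint` from [detect_particles()].
#' @param background Background height (nm); defaults to the footprint's
#'   stored value.
#' @return Volume in nm^3.
#' @export
particle_volume <- function(footprint, background = footprint$background_nm) {
  stopifnot(inherits(footprint, "particle_footprint"))
  V <- footprint$area_nm2 * (footprint$mean_height_nm - background)
  structure(V, flagged = V < 0)
}

#' Fit a molecular-weight calibration line to AFM volumes
#'
#' Ordinary least-squares regression of measured AFM volume (nm^3) on
#' known molecular weight (kDa) for a panel of globular standards. AFM
#' volumes scale linearly with molecular weight; tip convolution is
#' absorbed by the empirical line rather than deconvolved.
#'
#' @param mw_kDa Known molecular weights (>= 2 distinct values).
#' @param volume_nm3 Measured mean AFM volumes.
#' @return Object of class `calibration_line`: list with `slope`
#'   (nm^3/kDa), `intercept` (nm^3), `r_squared`.
#' @export
fit_calibration <- function(mw_kDa, volume_nm3) {
  stopifnot(length(mw_kDa) == length(volume_nm3))
  if (length(unique(mw_kDa)) < 2) stop("need >= 2 distinct molecular weights")
  fit <- stats::lm(volume_nm3 ~ mw_kDa)
  co <- stats::coef(fit)
  r2 <- if (length(mw_kDa) > 2)
    suppressWarnings(summary(fit)$r.squared) else 1
  calibration_line(unname(co[2]), unname(co[1]), r2)
}

#' Construct a calibration line from known coefficients
#'
#' @param slope Slope in nm^3/kDa (> 0).
#' @param intercept Intercept in nm^3.
#' @param r_squared Optional goodness of fit.
#' @return Object of class `calibration_line`.
#' @export
calibration_line <- function(slope, intercept, r_squared = NA_real_) {
  if (slope <= 0) stop("calibration slope must be positive")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared), class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Volume (nm^3) = %.3g x MW (kDa) %+.3g   (R^2 = %.3g)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Convert an AFM volume to molecular weight
#'
#' Inverts the calibration line: `MW = (V - intercept) / slope`. Negative
#' results are allowed but flagged via the `"flagged"` attribute.
#'
#' @param volume_nm3 AFM volume(s) in nm^3.
#' @param cal A [calibration_line()].
#' @return Molecular weight(s) in kDa.
#' @export
volume_to_mw <- function(volume_nm3, cal) {
  stopifnot(inherits(cal, "calibration_line"))
  mw <- (volume_nm3 - cal$intercept) / cal$slope
  structure(mw, flagged = mw < 0)
}

#' Convert a molecular weight to the expected AFM volume
#'
#' @param mw_kDa Molecular weight(s) in kDa.
#' @param cal A [calibration_line()].
#' @return Expected volume(s) in nm^3.
#' @export
mw_to_volume <- function(mw_kDa, cal) {
  stopifnot(inherits(cal, "calibration_line"))
  mw_kDa * cal$slope + cal$intercept
}

#' Protein volume on DNA by flanking-DNA subtraction
#'
#' The volume of a protein bound to DNA cannot be measured directly
#' because the DNA running through the complex contributes height. The
#' protein volume is the total complex volume minus the average of two
#' equal-length unbound DNA regions flanking it:
#' `V_protein = V_complex - (V_DNA1 + V_DNA2) / 2`.
#'
#' @param v_complex,v_dna1,v_dna2 Volumes in nm^3 (>= 0).
#' @return Protein volume in nm^3; negative results are flagged via the
#'   `"flagged"` attribute.
#' @export
protein_volume_on_dna <- function(v_complex, v_dna1, v_dna2) {
  stopifnot(all(c(v_complex, v_dna1, v_dna2) >= 0))
  v <- v_complex - (v_dna1 + v_dna2) / 2
  structure(v, flagged = v < 0)
}
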