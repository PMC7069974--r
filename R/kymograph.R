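#' Construct a kymograph
#'
#' Intensity as a function of position along the DNA (rows) and frame
#' (columns).
#'
#' @param intensity Numeric matrix, position (px) x frame.
#' @param pixel_size_nm nm per pixel along the DNA. Default 43.3 (three
#'   pixels correspond to 130 nm).
#' @param frame_interval_s Seconds per frame. Default 0.1 (10 fps).
#' @return Object of class `kymograph`.
#' @export
kymograph <- function(intensity, pixel_size_nm = 43.3, frame_interval_s = 0.1) {
  stopifnot(is.matrix(intensity), pixel_size_nm > 0, frame_interval_s > 0)
  structure(list(intensity = intensity, pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s), class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d px x %d frames, %.1f nm/px, %.3f s/frame\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_nm,
              x$frame_interval_s))
  invisible(x)
}

#' Build a kymograph from a frame stack along a path
#'
#' Samples each frame of a movie along a fixed polyline (the DNA
#' tightrope axis) with a width-one, nearest-pixel slice, producing one
#' kymograph column per frame.
#'
#' @param stack List of numeric matrices (one per frame), all of equal
#'   dimension, or a 3D array with the third dimension indexing frames.
#' @param path Two-column matrix of (row, col) pixel coordinates; sampled
#'   at unit-pixel spacing along the polyline.
#' @param pixel_size_nm,frame_interval_s Calibration passed to
#'   [kymograph()].
#' @return A [kymograph()].
#' @export
build_kymograph <- function(stack, path, pixel_size_nm = 43.3,
                            frame_interval_s = 0.1) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  stopifnot(is.list(stack), length(stack) >= 1, ncol(path) == 2)
  dims <- dim(stack[[1]])
  if (any(path[, 1] < 1 | path[, 1] > dims[1] |
          path[, 2] < 1 | path[, 2] > dims[2]))
    stop("path lies outside image bounds")
  # resample the polyline at unit spacing, then round to nearest pixel
  seg <- sqrt(rowSums(diff(path)^2))
  s_cum <- c(0, cumsum(seg))
  ss <- seq(0, s_cum[length(s_cum)], by = 1)
  pts <- t(vapply(ss, function(s) {
    i <- findInterval(s, s_cum, rightmost.closed = TRUE)
    i <- min(max(i, 1), nrow(path) - 1)
    f <- if (s_cum[i + 1] > s_cum[i]) (s - s_cum[i]) / (s_cum[i + 1] - s_cum[i]) else 0
    path[i, ] + f * (path[i + 1, ] - path[i, ])
  }, numeric(2)))
  rr <- pmin(pmax(round(pts[, 1]), 1), dims[1])
  cc <- pmin(pmax(round(pts[, 2]), 1), dims[2])
  lin <- cbind(rr, cc)
  inten <- vapply(stack, function(fr) fr[lin], numeric(nrow(lin)))
  if (is.null(dim(inten))) inten <- matrix(inten, nrow = nrow(lin))
  kymograph(inten, pixel_size_nm, frame_interval_s)
}

#' FFT bandpass filter for kymographs
#'
#' Filters each kymograph column (the spatial intensity profile of one
#' frame) in the frequency domain, retaining spatial structure between
#' `low_px` and `high_px` pixels with Gaussian-edged cutoffs. The gain is
#' zero at spatial DC, which removes frame-wide constant offsets --- the
#' vertical-stripe components of the kymograph. The filter is linear.
#'
#' @param kymo A [kymograph()].
#' @param low_px Smallest retained structure scale (px). Default 3.
#' @param high_px Largest retained structure scale (px). Default 40.
#' @return A filtered [kymograph()].
#' @export
bandpass_filter <- function(kymo, low_px = 3, high_px = 40) {
  stopifnot(inherits(kymo, "kymograph"), low_px < high_px)
  n <- nrow(kymo$intensity)
  if (n < low_px) stop("kymograph shorter than the filter scale")
  f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / n   # cycles per px
  # suppress structures larger than high_px and smaller than low_px;
  # half-gain at the nominal scales
  gain <- (1 - exp(-log(2) * (f * high_px)^2)) * exp(-log(2) * (f * low_px)^2)
  filt <- apply(kymo$intensity, 2, function(col) Re(stats::fft(stats::fft(col) * gain,
                                                               inverse = TRUE)) / n)
  if (is.null(dim(filt))) filt <- matrix(filt, nrow = n)
  kymograph(filt, kymo$pixel_size_nm, kymo$frame_interval_s)
}

#' Localize the particle in each kymograph frame
#'
#' Fits a one-dimensional Gaussian with offset
#' (`A exp(-(p - c)^2 / 2 w^2) + b`) to the intensity profile of each
#' frame and converts the fitted centre from pixels to nm. Frames failing
#' the quality gates --- fitted width outside `width_range_px`, amplitude
#' below `min_amp_sigma` times the residual sd, or profile R^2 below
#' `min_r2` --- are marked invalid.
#'
#' @param kymo A [kymograph()].
#' @param width_range_px Acceptable fitted PSF sd range in px.
#'   Default `c(0.5, 6)`.
#' @param min_amp_sigma Minimum amplitude in units of residual sd.
#'   Default 2.
#' @param min_r2 Minimum per-frame fit R^2. Default 0.5.
#' @return Object of class `sm_trajectory`: data.frame with columns
#'   `frame`, `time_s`, `position_nm`, `valid`, `sd_nm` and attribute
#'   `frame_interval_s`. `position_nm` is `NA` on invalid frames.
#' @export
localize <- function(kymo, width_range_px = c(0.5, 6), min_amp_sigma = 2,
                     min_r2 = 0.5) {
  stopifnot(inherits(kymo, "kymograph"))
  n_px <- nrow(kymo$intensity); n_fr <- ncol(kymo$intensity)
  p <- seq_len(n_px)
  pos <- rep(NA_real_, n_fr); sdl <- rep(NA_real_, n_fr); ok <- rep(FALSE, n_fr)
  for (j in seq_len(n_fr)) {
    y <- kymo$intensity[, j]
    if (all(!is.finite(y)) || stats::sd(y) == 0) next
    i0 <- which.max(y)
    df <- data.frame(p = p, y = y)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-(p - c0)^2 / (2 * w^2)) + b, data = df,
                        start = list(A = max(y) - stats::median(y), c0 = i0,
                                     w = 2, b = stats::median(y)),
                        lower = c(A = 0, c0 = 1, w = 0.1, b = -Inf),
                        upper = c(A = Inf, c0 = n_px, w = n_px, b = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    resid_sd <- stats::sd(df$y - stats::fitted(fit))
    r2 <- .r_squared(df$y, stats::fitted(fit))
    if (cf["w"] < width_range_px[1] || cf["w"] > width_range_px[2]) next
    if (resid_sd > 0 && cf["A"] < min_amp_sigma * resid_sd) next
    if (!is.na(r2) && r2 < min_r2) next
    pos[j] <- (unname(cf["c0"]) - 1) * kymo$pixel_size_nm   # row p sits at (p-1)*px
    se <- tryCatch(sqrt(diag(stats::vcov(fit))["c0"]), error = function(e) NA_real_)
    sdl[j] <- unname(se) * kymo$pixel_size_nm
    ok[j] <- TRUE
  }
  trajectory(position_nm = pos, valid = ok,
             frame_interval_s = kymo$frame_interval_s, sd_nm = sdl)
}

#' Construct a particle trajectory
#'
#' @param position_nm Per-frame particle position (nm); `NA` where the
#'   particle was not localized.
#' @param valid Logical per-frame validity flags. Default: positions that
#'   are finite.
#' @param frame_interval_s Seconds per frame. Default 0.1.
#' @param sd_nm Optional per-frame localization sd (nm).
#' @return Object of class `sm_trajectory` (data.frame `frame`, `time_s`,
#'   `position_nm`, `valid`, `sd_nm`; attribute `frame_interval_s`).
#' @export
trajectory <- function(position_nm, valid = is.finite(position_nm),
                       frame_interval_s = 0.1, sd_nm = NA_real_) {
  n <- length(position_nm)
  stopifnot(length(valid) == n, frame_interval_s > 0)
  position_nm[!valid] <- NA_real_
  structure(data.frame(frame = seq_len(n) - 1L,
                       time_s = (seq_len(n) - 1L) * frame_interval_s,
                       position_nm = position_nm, valid = valid,
                       sd_nm = rep_len(sd_nm, n)),
            frame_interval_s = frame_interval_s,
            class = c("sm_trajectory", "data.frame"))
}
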