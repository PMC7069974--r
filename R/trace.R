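# --- low-level raster helpers -------------------------------------------

# shift a matrix by (dr, dc), zero-filling
.shift <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0L, n, p)
  rs <- seq_len(n) - dr; cs <- seq_len(p) - dc
  ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= p
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Zhang-Suen morphological thinning of a binary mask to a 1-px skeleton.
# Written in-package: the imaging stack available to R has morphological
# erosion/dilation but no homotopic skeletonization.
.thin_mask <- function(mask) {
  m <- (mask > 0) * 1L
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- .shift(m, -1, 0);  p3 <- .shift(m, -1, 1)
      p4 <- .shift(m, 0, 1);   p5 <- .shift(m, 1, 1)
      p6 <- .shift(m, 1, 0);   p7 <- .shift(m, 1, -1)
      p8 <- .shift(m, 0, -1);  p9 <- .shift(m, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (phase == 1) {
        cond <- m == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Order skeleton pixels into a path by double BFS (farthest-endpoint rule):
# BFS from the lowest-index pixel finds one extremity; BFS from there finds
# the other and the path between them. Ties broken by lowest pixel index so
# the ordering is deterministic. Returns NULL when more than
# `1 - min_coverage` of the skeleton lies farther than one pixel from the
# main path (true side branches / crossings; staircase pixels of the
# thinning are adjacent to the path and tolerated).
.order_skeleton <- function(skel, min_coverage = 0.9) {
  px <- which(skel == 1L, arr.ind = TRUE)
  n <- nrow(px)
  if (n < 3) return(NULL)
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(n)
  nbrs <- function(i) {
    r <- px[i, 1]; c <- px[i, 2]
    rr <- pmax(r - 1, 1):pmin(r + 1, nrow(skel))
    cc <- pmax(c - 1, 1):pmin(c + 1, ncol(skel))
    v <- id[rr, cc]
    sort(v[v > 0 & v != i])
  }
  bfs <- function(start) {
    dist <- rep(-1L, n); parent <- rep(0L, n)
    dist[start] <- 0L; queue <- c(start); head <- 1L
    while (head <= length(queue)) {
      u <- queue[head]; head <- head + 1L
      for (v in nbrs(u)) if (dist[v] < 0) {
        dist[v] <- dist[u] + 1L; parent[v] <- u
        queue <- c(queue, v)
      }
    }
    list(dist = dist, parent = parent)
  }
  b1 <- bfs(1L)
  if (any(b1$dist < 0)) return(NULL)              # disconnected (shouldn't happen)
  e1 <- which(b1$dist == max(b1$dist))[1]
  b2 <- bfs(e1)
  e2 <- which(b2$dist == max(b2$dist))[1]
  path <- e2
  while (path[1] != e1) path <- c(b2$parent[path[1]], path)
  onpath <- matrix(FALSE, nrow(skel), ncol(skel))
  onpath[px[path, , drop = FALSE]] <- TRUE
  near <- vapply(seq_len(n), function(i) {
    rr <- pmax(px[i, 1] - 1, 1):pmin(px[i, 1] + 1, nrow(skel))
    cc <- pmax(px[i, 2] - 1, 1):pmin(px[i, 2] + 1, ncol(skel))
    any(onpath[rr, cc])
  }, logical(1))
  if (mean(near) < min_coverage) return(NULL)
  px[path, , drop = FALSE]
}

# moving-average smoothing of a polyline (k points each side, shrinking
# at the ends); tames pixel jaggedness before arclength measurement.
# k = 1 balances the staircase overestimate of the raw chain code against
# corner-cutting of genuine curvature (checked on rendered chains).
.smooth_polyline <- function(pts, k = 1) {
  n <- nrow(pts)
  out <- pts
  for (i in seq_len(n)) {
    w <- max(1, i - k):min(n, i + k)
    out[i, ] <- colMeans(pts[w, , drop = FALSE])
  }
  out
}

.arclengths <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

# point on the polyline at a given arclength (linear interpolation)
.point_at <- function(pts, s_cum, s) {
  s <- min(max(s, 0), s_cum[length(s_cum)])
  i <- findInterval(s, s_cum, rightmost.closed = TRUE)
  i <- min(max(i, 1), nrow(pts) - 1)
  f <- if (s_cum[i + 1] > s_cum[i]) (s - s_cum[i]) / (s_cum[i + 1] - s_cum[i]) else 0
  pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
}

# --- contour tracing -----------------------------------------------------

#' Trace DNA molecules in an AFM height map
#'
#' Thresholds the image above background, skeletonizes each connected
#' ridge and orders the skeleton into a polyline whose arclength is the
#' DNA contour length. Molecules touching the image border are rejected;
#' branched skeletons (crossed or overlapping molecules) are rejected by
#' requiring the main end-to-end path to cover at least 90% of the
#' skeleton. When an expected length is supplied, molecules outside
#' +/-10% of it are marked not accepted.
#'
#' @param map A [height_map()].
#' @param expected_length_nm Expected contour length (nm), or `NA` to skip
#'   the length filter. Default `bp_to_nm(538)`.
#' @param background Background height (nm); estimated if missing.
#' @param threshold_sigma Ridge threshold in noise-sd units. Default 2.
#' @param min_px Minimum component size in pixels. Default 10.
#' @param length_tol Relative length tolerance for acceptance. Default 0.1.
#' @return List of `dna_contour` objects: `points` (n x 2 matrix, nm, x/y),
#'   `contour_length_nm`, `expected_length_nm`, `accepted`, `reason`,
#'   `mean_height_nm`, `mean_width_nm` (ridge statistics used for complex
#'   classification).
#' @export
trace_dna <- function(map, expected_length_nm = bp_to_nm(538),
                      background = estimate_background(map),
                      threshold_sigma = 2, min_px = 10, length_tol = 0.1) {
  stopifnot(inherits(map, "height_map"))
  B <- as.numeric(background)
  sn <- estimate_noise_sd(map, B)
  mask <- map$heights > B + threshold_sigma * sn
  lab <- .label_mask(mask)
  ids <- setdiff(unique(as.vector(lab)), 0)
  psz <- map$pixel_size_nm
  out <- list()
  for (idc in ids) {
    comp <- lab == idc
    idx <- which(comp, arr.ind = TRUE)
    if (nrow(idx) < min_px) next
    if (any(idx[, 1] %in% c(1, nrow(comp))) || any(idx[, 2] %in% c(1, ncol(comp))))
      next                                       # touches border
    skel <- .thin_mask(comp)
    path <- .order_skeleton(skel)
    if (is.null(path)) next                      # branched / crossing
    pts <- cbind(x = path[, 2] * psz, y = path[, 1] * psz)
    pts <- .smooth_polyline(pts)
    len <- sum(sqrt(rowSums(diff(pts)^2)))
    accepted <- TRUE; reason <- "ok"
    if (is.finite(expected_length_nm) &&
        abs(len - expected_length_nm) > length_tol * expected_length_nm) {
      accepted <- FALSE; reason <- "length_out_of_range"
    }
    heights <- map$heights[path] - B
    mean_h <- mean(heights)
    # ridge width at half the mean ridge height (threshold-independent,
    # comparable to a footprint extent)
    half_px <- sum(comp & map$heights > B + 0.5 * mean_h)
    out[[length(out) + 1L]] <- structure(
      list(points = pts, contour_length_nm = len,
           expected_length_nm = expected_length_nm,
           accepted = accepted, reason = reason,
           mean_height_nm = mean_h,
           mean_width_nm = half_px * psz^2 / max(len, psz)),
      class = "dna_contour")
  }
  out
}

#' @export
print.dna_contour <- function(x, ...) {
  cat(sprintf("DNA contour: %.1f nm (expected %.1f), %s\n",
              x$contour_length_nm, x$expected_length_nm,
              if (x$accepted) "accepted" else paste0("rejected (", x$reason, ")")))
  invisible(x)
}

#' Binding position of a protein along a DNA contour
#'
#' Arclength from the contour point nearest the protein centroid to the
#' closer DNA end, divided by the total contour length, as a percentage.
#' By the closest-end convention the result lies in \[0, 50\] and is
#' invariant under reversal of the contour orientation.
#'
#' @param contour A `dna_contour`.
#' @param centroid Numeric length-2 (x, y) in nm.
#' @param capture_nm Maximum centroid-to-contour distance for the protein
#'   to be considered bound. Default 20.
#' @return Percent position in \[0, 50\], with attribute `arclength_nm`
#'   (distance along the contour from the start of `points`). Errors if
#'   the centroid is farther than `capture_nm` from the contour.
#' @export
binding_position <- function(contour, centroid, capture_nm = 20) {
  stopifnot(inherits(contour, "dna_contour"), length(centroid) == 2)
  d2 <- rowSums(sweep(contour$points, 2, as.numeric(centroid))^2)
  i <- which.min(d2)
  if (sqrt(d2[i]) > capture_nm) stop("centroid is not on the DNA (capture distance exceeded)")
  s_cum <- .arclengths(contour$points)
  s <- s_cum[i]; L <- s_cum[length(s_cum)]
  structure(100 * min(s, L - s) / L, arclength_nm = s)
}

#' DNA bend angle at a point on the contour
#'
#' The bend angle theta is the supplement of the interior angle of the
#' DNA path at the vertex: two chords are drawn from the vertex to points
#' `tangent_window_nm` of arclength away on each side, and theta is the
#' angle between the incoming and outgoing chord directions. A straight
#' path gives 0 degrees; theta lies in \[0, 180).
#'
#' @param contour A `dna_contour`.
#' @param vertex_arclength_nm Arclength of the vertex from the start of
#'   the contour (nm).
#' @param tangent_window_nm Chord length on each side (nm). Default 15:
#'   chords must clear the corner-rounding radius that ridge rendering
#'   and skeletonization impose at a kink (about the ridge half-width),
#'   or sharp bends read low.
#' @return Bend angle in degrees.
#' @export
bend_angle <- function(contour, vertex_arclength_nm, tangent_window_nm = 15) {
  stopifnot(inherits(contour, "dna_contour"))
  s_cum <- .arclengths(contour$points)
  L <- s_cum[length(s_cum)]
  v <- vertex_arclength_nm; w <- tangent_window_nm
  if (v < w || v > L - w)
    stop("tangent window exceeds available arm length")
  p0 <- .point_at(contour$points, s_cum, v - w)
  p1 <- .point_at(contour$points, s_cum, v)
  p2 <- .point_at(contour$points, s_cum, v + w)
  u <- p1 - p0; vv <- p2 - p1
  cosang <- sum(u * vv) / (sqrt(sum(u^2)) * sqrt(sum(vv^2)))
  acos(min(max(cosang, -1), 1)) * 180 / pi
}

#' Classify a footprint on a DNA molecule as a protein-DNA complex
#'
#' A bound protein must stand out from the bare DNA in both dimensions:
#' (a) the footprint's mean height must exceed the molecule's mean ridge
#' height and (b) its width must exceed the mean ridge width. Width of the
#' footprint is measured as the minor extent of its pixel cloud
#' (4 x sqrt of the smaller eigenvalue of the coordinate covariance).
#'
#' @param contour A `dna_contour`.
#' @param footprint A `particle_footprint`.
#' @param end_threshold_pct Binding positions at or below this percentage
#'   of contour length count as end-bound. Default 2.5.
#' @param capture_nm Passed to [binding_position()]. Default 20.
#' @return List with `is_complex`, `end_bound`, `position_pct`,
#'   `footprint_height_nm`, `footprint_width_nm`.
#' @export
classify_complex <- function(contour, footprint, end_threshold_pct = 2.5,
                             capture_nm = 20) {
  stopifnot(inherits(contour, "dna_contour"),
            inherits(footprint, "particle_footprint"))
  psz <- footprint$pixel_size_nm
  xy <- cbind(footprint$pixels[, 2], footprint$pixels[, 1]) * psz
  wd <- if (nrow(xy) > 2) {
    ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
    4 * sqrt(max(min(ev), 0))
  } else psz
  hgt <- footprint$mean_height_nm - footprint$background_nm
  pos <- tryCatch(binding_position(contour, footprint$centroid_nm, capture_nm),
                  error = function(e) NA_real_)
  is_complex <- is.finite(pos) &&
    hgt > contour$mean_height_nm && wd > contour$mean_width_nm
  list(is_complex = is_complex,
       end_bound = is.finite(pos) && pos <= end_threshold_pct,
       position_pct = as.numeric(pos),
       footprint_height_nm = hgt, footprint_width_nm = wd)
}

# volume (nm^3) inside a tube of given radius around the contour between
# arclengths s0..s1. Each pixel is assigned the arclength of its nearest
# point on the full contour and counted when that arclength falls in
# [s0, s1] and the perpendicular distance is within the radius -- so the
# complex tube and its flanking tubes tile the molecule without overlap.
.tube_volume <- function(map, contour, s0, s1, radius_nm, background) {
  psz <- map$pixel_size_nm
  s_cum <- .arclengths(contour$points)
  L <- s_cum[length(s_cum)]
  s0 <- max(s0, 0); s1 <- min(s1, L)
  ss_all <- seq(0, L, by = psz / 2)
  samp <- t(vapply(ss_all, function(s) .point_at(contour$points, s_cum, s),
                   numeric(2)))
  inseg <- ss_all >= s0 & ss_all <= s1
  if (!any(inseg)) return(0)
  r0 <- max(1, floor(min(samp[inseg, 2] - radius_nm) / psz))
  r1 <- min(nrow(map$heights), ceiling(max(samp[inseg, 2] + radius_nm) / psz))
  c0 <- max(1, floor(min(samp[inseg, 1] - radius_nm) / psz))
  c1 <- min(ncol(map$heights), ceiling(max(samp[inseg, 1] + radius_nm) / psz))
  vol <- 0
  for (r in r0:r1) for (cc in c0:c1) {
    d2 <- (cc * psz - samp[, 1])^2 + (r * psz - samp[, 2])^2
    k <- which.min(d2)
    if (inseg[k] && d2[k] <= radius_nm^2)
      vol <- vol + (map$heights[r, cc] - background) * psz^2
  }
  vol
}

#' Measure protein-DNA complexes in an AFM field
#'
#' Full complex pipeline on one height map: estimates the background,
#' traces DNA molecules, detects candidate protein blobs (footprints whose
#' height clears `height_factor` times the mean DNA ridge height),
#' classifies them against the height-and-width criteria, and for each
#' complex measures the binding position, the DNA bend angle at the
#' binding site, and the protein volume by flanking-DNA subtraction
#' (complex volume minus the average of two equal-length unbound DNA
#' spans; flanks are relocated elsewhere on the molecule when the protein
#' sits near an end).
#'
#' @param map A [height_map()].
#' @param expected_length_nm Expected DNA contour length (nm).
#' @param calibration Optional [calibration_line()] for MW conversion.
#' @param height_factor Protein detection threshold as a multiple of the
#'   mean DNA ridge height. Default 1.5.
#' @param tangent_window_nm Chord length for bend angles (nm). Default 15.
#' @param vertex_search_nm The bend vertex is the point within this
#'   arclength of the binding site that maximizes the measured angle
#'   (kink localization is uncertain by a few nm). Default 5.
#' @param tube_radius_nm Radius of the integration tube for complex and
#'   flanking-DNA volumes (nm). Default 8.
#' @param end_threshold_pct End-binding threshold. Default 2.5.
#' @param capture_nm Centroid capture distance. Default 20.
#' @return data.frame with one row per detected complex: `molecule`,
#'   `position_pct`, `end_bound`, `theta_deg`, `v_complex_nm3`,
#'   `v_dna1_nm3`, `v_dna2_nm3`, `v_protein_nm3`, `mw_kDa`. Attribute
#'   `n_molecules` gives the number of accepted DNA contours.
#' @export
measure_complexes <- function(map, expected_length_nm = bp_to_nm(538),
                              calibration = NULL, height_factor = 1.5,
                              tangent_window_nm = 15, vertex_search_nm = 5,
                              tube_radius_nm = 8,
                              end_threshold_pct = 2.5, capture_nm = 20) {
  B <- estimate_background(map)
  sn <- estimate_noise_sd(map, B)
  contours <- trace_dna(map, expected_length_nm, B)
  contours <- Filter(function(ct) ct$accepted, contours)
  empty <- data.frame(molecule = integer(), position_pct = numeric(),
                      end_bound = logical(), theta_deg = numeric(),
                      v_complex_nm3 = numeric(), v_dna1_nm3 = numeric(),
                      v_dna2_nm3 = numeric(), v_protein_nm3 = numeric(),
                      mw_kDa = numeric())
  if (length(contours) == 0)
    return(structure(empty, n_molecules = 0L))
  h_dna <- mean(vapply(contours, function(ct) ct$mean_height_nm, numeric(1)))
  thr_sigma <- if (sn > 0) height_factor * h_dna / sn else 3
  blobs <- detect_particles(map, B, threshold_sigma = thr_sigma)
  rows <- empty
  for (fp in blobs) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(contours)) {
      d <- sqrt(min(rowSums(sweep(contours[[i]]$points, 2, fp$centroid_nm)^2)))
      if (d < best_d) { best_d <- d; best <- i }
    }
    if (is.null(best) || best_d > capture_nm) next
    ct <- contours[[best]]
    cls <- classify_complex(ct, fp, end_threshold_pct, capture_nm)
    if (!cls$is_complex) next
    s_cum <- .arclengths(ct$points)
    L <- s_cum[length(s_cum)]
    pos <- binding_position(ct, fp$centroid_nm, capture_nm)
    sv <- attr(pos, "arclength_nm")
    # kink localization is uncertain by a few nm: take the maximal angle
    # over a small arclength neighbourhood of the binding site
    theta <- suppressWarnings(max(vapply(
      seq(sv - vertex_search_nm, sv + vertex_search_nm, length.out = 11),
      function(s) tryCatch(bend_angle(ct, s, tangent_window_nm),
                           error = function(e) NA_real_),
      numeric(1)), na.rm = TRUE))
    if (!is.finite(theta)) theta <- NA_real_
    # complex span: arclength extent of the footprint projected on the contour
    psz <- map$pixel_size_nm
    proj <- apply(fp$pixels, 1, function(rc) {
      p <- c(rc[2], rc[1]) * psz
      s_cum[which.min(rowSums(sweep(ct$points, 2, p)^2))]
    })
    s0 <- max(min(proj) - psz, 0); s1 <- min(max(proj) + psz, L)
    span <- s1 - s0
    # flanking spans: adjacent when available, else relocated on the molecule
    flanks <- list()
    if (s0 - span >= 0) flanks[[length(flanks) + 1]] <- c(s0 - span, s0)
    if (s1 + span <= L) flanks[[length(flanks) + 1]] <- c(s1, s1 + span)
    if (length(flanks) < 2) {
      free <- if (s0 - span >= 0) c(0, s0) else c(s1, L)
      at <- seq(free[1], free[2] - span, by = span)
      for (a in at) {
        flanks[[length(flanks) + 1]] <- c(a, a + span)
        if (length(flanks) == 2) break
      }
    }
    if (length(flanks) < 2) next                  # molecule too short to measure
    vc <- .tube_volume(map, ct, s0, s1, tube_radius_nm, B)
    v1 <- .tube_volume(map, ct, flanks[[1]][1], flanks[[1]][2], tube_radius_nm, B)
    v2 <- .tube_volume(map, ct, flanks[[2]][1], flanks[[2]][2], tube_radius_nm, B)
    vp <- vc - (v1 + v2) / 2
    rows <- rbind(rows, data.frame(
      molecule = best, position_pct = as.numeric(pos),
      end_bound = cls$end_bound, theta_deg = theta,
      v_complex_nm3 = vc, v_dna1_nm3 = v1, v_dna2_nm3 = v2,
      v_protein_nm3 = vp,
      mw_kDa = if (is.null(calibration)) NA_real_
               else as.numeric(volume_to_mw(vp, calibration))))
  }
  structure(rows, n_molecules = length(contours))
}
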