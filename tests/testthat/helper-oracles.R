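# Independent oracles and fixture builders used across the suite.

# naive double-loop MSD, independent of the package implementation
msd_oracle <- function(x, n) {
  N <- length(x)
  d <- vapply(seq_len(N - n), function(i) (x[i + n] - x[i])^2, numeric(1))
  d <- d[is.finite(d)]
  if (length(d) == 0) return(NA_real_)
  mean(d)
}

# deterministic zig-zag segment: range `amp`, alternating endpoints
zigzag <- function(n, amp = 200, base = 0) base + rep(c(0, amp), length.out = n)

# exhaustive rule checker for phase segmentation (trajectories small
# enough to scan every window). Verifies, against the declared rules:
#  - phases tile the frame range with no gaps/overlaps
#  - per-mode displacement bounds (paused <= motile thr, long > long thr)
#  - paused phases respect the minimum duration (leading exception)
#  - no qualifying pause window (>= min_phase, range <= motile thr) lies
#    fully inside a motile phase
#  - no qualifying short window lies fully inside a long phase
check_segmentation <- function(traj, phases, cfg) {
  x <- traj$position_nm
  n <- length(x)
  dt <- attr(traj, "frame_interval_s")
  rng <- function(a, b) {
    v <- x[a:b]; v <- v[is.finite(v)]
    if (length(v) < 2) 0 else diff(range(v))
  }
  # tiling
  if (phases$start[1] != 1) return("does not start at frame 1")
  if (phases$end[nrow(phases)] != n + 1) return("does not end at last frame")
  if (nrow(phases) > 1 &&
      any(phases$start[-1] != phases$end[-nrow(phases)]))
    return("gap or overlap between phases")
  for (i in seq_len(nrow(phases))) {
    a <- phases$start[i]; b <- phases$end[i] - 1L
    r <- rng(a, b)
    dur <- (b - a + 1L) * dt
    if (phases$mode[i] == "paused") {
      if (r > cfg$motile_threshold_nm) return("paused phase exceeds range bound")
      need <- if (a == 1L) cfg$lead_min_phase_s else cfg$min_phase_s
      if (dur < need) return("paused phase too short")
    }
    if (phases$mode[i] == "long" && r <= cfg$long_threshold_nm)
      return("long phase within short range")
    if (phases$mode[i] == "short" && r > cfg$long_threshold_nm)
      return("short phase exceeds range bound")
  }
  k_min <- ceiling(cfg$min_phase_s / dt)
  inside <- function(a, b, mode) {
    any(phases$mode == mode & phases$start <= a & phases$end > b)
  }
  for (a in seq_len(n - k_min + 1L)) for (b in (a + k_min - 1L):n) {
    if ((b - a + 1L) * dt < cfg$min_phase_s) next
    r <- rng(a, b)
    if (r <= cfg$motile_threshold_nm &&
        (inside(a, b, "short") || inside(a, b, "long")))
      return("missed pause window inside a motile phase")
    if (r <= cfg$long_threshold_nm && inside(a, b, "long"))
      return("missed short window inside a long phase")
    if (r > cfg$long_threshold_nm) break   # larger windows only grow
  }
  TRUE
}

# random piecewise test trajectory for the segmentation oracle:
# alternating bouts of pausing and diffusion with random durations
random_piecewise_traj <- function(n_frames, dt = 0.5, seed = 1) {
  set.seed(seed)
  x <- numeric(0); pos <- 0
  while (length(x) < n_frames) {
    kind <- sample(c("pause", "walk", "jump"), 1, prob = c(0.4, 0.4, 0.2))
    len <- sample(3:20, 1)
    if (kind == "pause") {
      x <- c(x, pos + rnorm(len, 0, 10))
    } else if (kind == "walk") {
      x <- c(x, pos + cumsum(rnorm(len, 0, 60))); pos <- x[length(x)]
    } else {
      pos <- pos + sample(c(-1, 1), 1) * runif(1, 200, 1500)
      x <- c(x, pos + rnorm(len, 0, 10))
    }
  }
  trajectory(x[seq_len(n_frames)], frame_interval_s = dt)
}
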