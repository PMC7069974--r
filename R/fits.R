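#' Square-root histogram binning rule
#'
#' Number of histogram bins for a sample of size `n`, taken as the square
#' root of the sample size rounded to the nearest integer (base `round`,
#' i.e. ties round to even). With n = 1451, sqrt(n) = 38.09 gives 38 bins.
#'
#' @param n Sample size, integer >= 1.
#' @return Positive integer bin count.
#' @export
sqrt_bins <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a single integer >= 1")
  max(1L, as.integer(round(sqrt(n))))
}

# Histogram with a fixed bin count spanning the data range.
# Returns mids, counts and bin width; used by all histogram-based fits.
.histo <- function(values, bins) {
  rng <- range(values)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- graphics::hist(values, breaks = brk, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(mids = h$mids, counts = h$counts, width = diff(brk)[1])
}

.r_squared <- function(obs, fitted) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - fitted)^2) / ss_tot
}

#' Fit a Gaussian to a histogram of values
#'
#' Bins the data (square-root rule by default) and fits
#' `amplitude * exp(-(x - mean)^2 / (2 sd^2))` to the bin counts by
#' unweighted nonlinear least squares, initialised at the sample mean,
#' sample sd and maximum count, with sd bounded away from zero.
#'
#' @param values Numeric vector, length >= 10.
#' @param bins Number of bins (>= 3). Default `sqrt_bins(length(values))`.
#' @return Object of class `gaussian_fit`: list with `mean`, `sd`,
#'   `amplitude`, `r_squared`, `n`, `converged`. On degenerate input
#'   (e.g. all values identical) a non-converged fit with `NA` parameters
#'   is returned rather than an error.
#' @export
fit_gaussian <- function(values, bins = sqrt_bins(length(values))) {
  stopifnot(is.numeric(values))
  values <- values[is.finite(values)]
  if (length(values) < 10) stop("need at least 10 values")
  if (bins < 3) stop("need at least 3 bins")
  failed <- structure(list(mean = NA_real_, sd = NA_real_,
                           amplitude = NA_real_, r_squared = NA_real_,
                           n = length(values), converged = FALSE),
                      class = "gaussian_fit")
  if (stats::sd(values) == 0) return(failed)
  h <- .histo(values, bins)
  df <- data.frame(x = h$mids, y = h$counts)
  # a perfectly symmetric start can sit on a degenerate direction of the
  # LM step; retry from a slightly offset start before giving up
  fit <- NULL
  for (jit in c(0, 0.5, -0.5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-(x - m)^2 / (2 * s^2)), data = df,
                        start = list(a = max(df$y),
                                     m = mean(values) + jit * h$width,
                                     s = stats::sd(values) * (1 + jit / 5)),
                        # sd floored at a quarter bin width: narrower
                        # components are unresolvable and underflow the
                        # model gradient
                        lower = c(a = 1e-12, m = -Inf, s = h$width / 4),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(failed)
  p <- stats::coef(fit)
  structure(list(mean = unname(p["m"]), sd = abs(unname(p["s"])),
                 amplitude = unname(p["a"]),
                 r_squared = .r_squared(df$y, stats::fitted(fit)),
                 n = length(values), converged = TRUE),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (!x$converged) cat("Gaussian fit: not converged\n")
  else cat(sprintf("Gaussian fit: mean %.3g +/- %.3g (sd), R^2 = %.3f, n = %d\n",
                   x$mean, x$sd, x$r_squared, x$n))
  invisible(x)
}

# Initial centres for a two-component fit: the two tallest histogram peaks
# separated by at least a quarter of the data range (falls back to the
# 25%/75% quantiles when fewer than two such peaks exist).
.two_peak_starts <- function(values, h) {
  y <- h$counts; x <- h$mids
  loc <- which(y >= c(-Inf, y[-length(y)]) & y >= c(y[-1], Inf) & y > 0)
  sep <- diff(range(values)) / 4
  loc <- loc[order(y[loc], decreasing = TRUE)]
  picks <- c()
  for (i in loc) {
    if (all(abs(x[i] - x[picks]) >= sep) || length(picks) == 0)
      picks <- c(picks, i)
    if (length(picks) == 2) break
  }
  if (length(picks) < 2)
    return(stats::quantile(values, c(0.25, 0.75), names = FALSE))
  sort(x[picks])
}

#' Fit a two-component Gaussian mixture to a histogram of values
#'
#' Fits the sum of two Gaussians to the binned counts by nonlinear least
#' squares, initialised from the two largest separated histogram peaks.
#' Components are reported sorted by ascending mean; component weights are
#' the estimated counts (`amplitude * sd * sqrt(2*pi) / bin width`).
#'
#' @param values Numeric vector, length >= 30.
#' @param bins Number of bins. Default `sqrt_bins(length(values))`.
#' @return Object of class `double_gaussian_fit`: list with `components`
#'   (data.frame mean, sd, amplitude, weight), `r_squared`, `n`,
#'   `converged`.
#' @export
fit_double_gaussian <- function(values, bins = sqrt_bins(length(values))) {
  stopifnot(is.numeric(values))
  values <- values[is.finite(values)]
  if (length(values) < 30) stop("need at least 30 values")
  failed <- structure(list(components = NULL, r_squared = NA_real_,
                           n = length(values), converged = FALSE),
                      class = "double_gaussian_fit")
  if (stats::sd(values) == 0) return(failed)
  h <- .histo(values, max(bins, 5L))
  df <- data.frame(x = h$mids, y = h$counts)
  ctr <- .two_peak_starts(values, h)
  fit <- NULL
  for (s0 in c(max(stats::sd(values) / 2, diff(range(values)) / 20),
               diff(range(values)) / 20, 2 * h$width, h$width / 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
            a2 * exp(-(x - m2)^2 / (2 * s2^2)),
        data = df,
        start = list(a1 = max(df$y), m1 = ctr[1], s1 = s0,
                     a2 = max(df$y), m2 = ctr[2], s2 = s0),
        lower = c(a1 = 0, m1 = -Inf, s1 = h$width / 4,
                  a2 = 0, m2 = -Inf, s2 = h$width / 4),
        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(failed)
  p <- stats::coef(fit)
  comp <- data.frame(mean = c(p["m1"], p["m2"]),
                     sd = abs(c(p["s1"], p["s2"])),
                     amplitude = c(p["a1"], p["a2"]))
  comp$weight <- comp$amplitude * comp$sd * sqrt(2 * pi) / h$width
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp,
                 r_squared = .r_squared(df$y, stats::fitted(fit)),
                 n = length(values), converged = TRUE),
            class = "double_gaussian_fit")
}

#' @export
print.double_gaussian_fit <- function(x, ...) {
  if (!x$converged) { cat("Double-Gaussian fit: not converged\n"); return(invisible(x)) }
  cat(sprintf("Double-Gaussian fit (R^2 = %.3f, n = %d):\n", x$r_squared, x$n))
  print(x$components)
  invisible(x)
}

#' Fit a single-exponential lifetime to phase durations
#'
#' Fits `S(t) = exp(-k t)` to the empirical survival function (one minus
#' the cumulative distribution) of the durations by nonlinear least
#' squares. Fitting the survival curve rather than binned counts avoids
#' binning artefacts in small samples. Right-censoring by the observation
#' window is ignored. Mean lifetime is `tau = 1/k`.
#'
#' @param durations Non-negative durations in seconds, length >= 20.
#' @return Object of class `exponential_fit`: list with `k` (1/s), `se_k`,
#'   `tau` (s), `r_squared`, `n`, `converged`. Identical durations give a
#'   positive `k` flagged by a poor `r_squared`.
#' @export
fit_exponential_lifetime <- function(durations) {
  stopifnot(is.numeric(durations))
  durations <- durations[is.finite(durations)]
  if (length(durations) < 20) stop("need at least 20 durations")
  if (any(durations < 0)) stop("durations must be non-negative")
  if (all(durations == 0)) stop("all durations are zero")
  t_sorted <- sort(durations)
  n <- length(t_sorted)
  surv <- 1 - seq_len(n) / n           # S(t) just after each observation
  df <- data.frame(t = t_sorted, s = surv)
  k0 <- 1 / max(mean(durations), .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ exp(-k * t), data = df, start = list(k = k0),
                      lower = c(k = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(k = k0, se_k = NA_real_, tau = 1 / k0,
                          r_squared = NA_real_, n = n, converged = FALSE),
                     class = "exponential_fit"))
  k <- unname(stats::coef(fit)["k"])
  se <- tryCatch(unname(sqrt(diag(stats::vcov(fit))["k"])),
                 error = function(e) NA_real_)
  structure(list(k = k, se_k = se, tau = 1 / k,
                 r_squared = .r_squared(df$s, stats::fitted(fit)),
                 n = n, converged = TRUE),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Exponential lifetime fit: k = %.4g 1/s (se %.2g), tau = %.3g s, R^2 = %.3f\n",
              x$k, x$se_k, x$tau, x$r_squared))
  invisible(x)
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson chi-squared test of independence without continuity correction
#' (the convention needed to reproduce end-versus-internal binding
#' comparisons), df = (r-1)(c-1), upper-tail p value.
#'
#' @param table Matrix of non-negative integer counts (r x c, r,c >= 2).
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has a zero marginal")
  ht <- stats::chisq.test(table, correct = FALSE)
  if (any(ht$expected <= 0)) stop("expected counts must be positive")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected)
}

#' Two-sample Student's t test
#'
#' Classical (equal-variance) Student's t test, two-tailed. In the
#' diffusion pipeline this is applied to log10 diffusion coefficients.
#'
#' @param a,b Numeric vectors, each of length >= 3.
#' @return List with `t`, `df`, `p_value`.
#' @export
two_sample_t_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("each group needs >= 3 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("zero variance in both groups")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
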