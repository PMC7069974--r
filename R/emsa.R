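#' Construct a binding isotherm
#'
#' A titration of total protein concentration against the percentage of
#' DNA bound, at fixed total DNA concentration.
#'
#' @param protein_nM Strictly increasing protein concentrations (nM).
#' @param fraction_bound_pct Percent DNA bound, in \[0, 100\].
#' @param dna_nM Total DNA concentration (nM), > 0. Default 8.
#' @return Object of class `binding_isotherm` (data.frame with attribute
#'   `dna_nM`).
#' @export
binding_isotherm <- function(protein_nM, fraction_bound_pct, dna_nM = 8) {
  stopifnot(length(protein_nM) == length(fraction_bound_pct), dna_nM > 0)
  if (is.unsorted(protein_nM, strictly = TRUE))
    stop("protein_nM must be strictly increasing")
  if (any(fraction_bound_pct < 0 | fraction_bound_pct > 100))
    stop("fraction_bound_pct must lie in [0, 100]")
  structure(data.frame(protein_nM = protein_nM,
                       fraction_bound_pct = fraction_bound_pct),
            dna_nM = dna_nM, class = c("binding_isotherm", "data.frame"))
}

#' Single-site depletion binding model
#'
#' Percent DNA bound at total protein `P`, total DNA `D` and dissociation
#' constant `K_D` (all nM), from the closed-form solution of the single
#' binding-site equilibrium with ligand depletion:
#' `100 * ((P + D + K_D) - sqrt((P + D + K_D)^2 - 4 P D)) / (2 D)`.
#' Used instead of the hyperbolic isotherm because the assay's DNA
#' concentration is of the same order as the K_D.
#'
#' @param P Total protein concentration, nM (vectorised).
#' @param D Total DNA concentration, nM (scalar > 0).
#' @param K_D Dissociation constant, nM (>= 0).
#' @return Percent bound in \[0, 100\].
#' @export
fraction_bound <- function(P, D, K_D) {
  stopifnot(all(P >= 0), length(D) == 1L, D > 0, K_D >= 0)
  s <- P + D + K_D
  disc <- pmax(s^2 - 4 * P * D, 0)     # guard against tiny negative rounding
  pmin(pmax(100 * (s - sqrt(disc)) / (2 * D), 0), 100)
}

#' Fit an apparent K_D to a binding isotherm
#'
#' Nonlinear least squares of the single-site depletion model with K_D as
#' the only free parameter; the DNA concentration is fixed at its known
#' value and the bound plateau is constrained to 100%.
#'
#' @param iso A [binding_isotherm()] with at least 5 points.
#' @return Object of class `kd_fit`: list with `K_D` (nM), `se` (nM),
#'   `r_squared`, `converged`.
#' @export
fit_kd <- function(iso) {
  stopifnot(inherits(iso, "binding_isotherm"))
  if (nrow(iso) < 5) stop("need at least 5 titration points")
  D <- attr(iso, "dna_nM")
  df <- data.frame(P = iso$protein_nM, y = iso$fraction_bound_pct)
  if (stats::sd(df$y) == 0)
    return(structure(list(K_D = NA_real_, se = NA_real_,
                          r_squared = NA_real_, converged = FALSE),
                     class = "kd_fit"))
  # start near the protein concentration at half-maximal binding
  k0 <- stats::approx(df$y, df$P, xout = max(df$y) / 2, ties = mean)$y
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(df$P)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fraction_bound(P, D, K), data = df,
                      start = list(K = k0), lower = c(K = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) ||
      .r_squared(df$y, stats::fitted(fit)) < 0.2 || is.na(.r_squared(df$y, stats::fitted(fit))))
    return(structure(list(K_D = if (is.null(fit)) NA_real_ else unname(stats::coef(fit)["K"]),
                          se = NA_real_, r_squared = NA_real_,
                          converged = FALSE), class = "kd_fit"))
  K <- unname(stats::coef(fit)["K"])
  se <- tryCatch(unname(sqrt(diag(stats::vcov(fit))["K"])),
                 error = function(e) NA_real_)
  structure(list(K_D = K, se = se,
                 r_squared = .r_squared(df$y, stats::fitted(fit)),
                 converged = TRUE), class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  if (!x$converged) cat("K_D fit: not converged\n")
  else cat(sprintf("K_D = %.4g +/- %.2g nM (R^2 = %.3f)\n", x$K_D, x$se, x$r_squared))
  invisible(x)
}

#' Site-corrected specificity from a pair of apparent K_Ds
#'
#' The raw affinity ratio between a non-specific and a lesion-containing
#' substrate understates the per-site preference when the specific
#' substrate also offers non-specific sites: on an n-bp duplex with a
#' single lesion, the ratio is multiplied by n to express specificity per
#' site. E.g. (253 / 109) x 37 gives ~86-fold.
#'
#' @param kd_nonspecific Apparent K_D on the non-damaged substrate (nM).
#' @param kd_specific Apparent K_D on the lesion substrate (nM).
#' @param n_sites Number of sites on the substrate (e.g. 37 for a 37-bp
#'   duplex with one lesion).
#' @return Object of class `specificity_result`: list with `fold`,
#'   `method = "site_corrected_emsa"`, `n_nonspecific_sites`, `raw_ratio`.
#' @export
site_corrected_specificity <- function(kd_nonspecific, kd_specific, n_sites) {
  if (kd_nonspecific <= 0 || kd_specific <= 0) stop("K_D values must be positive")
  if (n_sites < 1) stop("n_sites must be >= 1")
  structure(list(fold = (kd_nonspecific / kd_specific) * n_sites,
                 raw_ratio = kd_nonspecific / kd_specific,
                 method = "site_corrected_emsa",
                 n_nonspecific_sites = as.integer(n_sites)),
            class = "specificity_result")
}

#' Position-distribution specificity for internally bound proteins
#'
#' Per-site occupancy ratio from the distribution of binding positions
#' along a DNA fragment, with end-binders excluded. Positions are folded
#' distances to the closest end as a percentage of contour length, so they
#' lie in (0, 50\]. Because positions are folded, a window `(w1, w2)`
#' collects binders from both mirror arms of the molecule; the candidate
#' specific region is therefore treated as one composite region of
#' `2 * (w2 - w1) / 100 * n_bp` base pairs, and the non-specific region
#' is the remaining internal DNA (the excluded end zones are counted in
#' neither). The specificity is the per-site occupancy ratio
#'
#' `S = (fraction inside window / bp inside) / (fraction outside / bp outside)`
#'
#' which equals 1 in expectation for uniformly distributed positions and
#' grows with enrichment at the lesion window.
#'
#' @param positions Folded binding positions, percent in \[0, 50\].
#' @param window Numeric length-2, specific window in percent of contour
#'   length, inside (0, 50). Default `c(20, 40)`.
#' @param n_bp Length of the fragment in bp. Default 538.
#' @param end_threshold_pct Positions at or below this are treated as
#'   end-binders and excluded. Default 2.5.
#' @return Object of class `specificity_result`: list with `fold` (Inf with
#'   `capped = TRUE` when no binder lies outside the window), `method`,
#'   `n_internal`, `n_in_window`.
#' @export
position_distribution_specificity <- function(positions, window = c(20, 40),
                                              n_bp = 538,
                                              end_threshold_pct = 2.5) {
  stopifnot(all(positions >= 0 & positions <= 50), length(window) == 2,
            window[1] < window[2], window[1] > 0, window[2] < 50, n_bp >= 10)
  internal <- positions[positions > end_threshold_pct]
  if (length(internal) == 0) stop("no internal binders after end exclusion")
  width <- window[2] - window[1]
  n_spec <- 2 * width / 100 * n_bp       # both mirror arms fold into the window
  # internal non-specific sites: everything between the end zones and
  # outside the window, again counting both arms
  n_nonspec <- 2 * (50 - end_threshold_pct - width) / 100 * n_bp
  if (n_nonspec <= 0) stop("window leaves no non-specific region")
  in_w <- internal >= window[1] & internal <= window[2]
  f_in <- mean(in_w)
  f_out <- 1 - f_in
  capped <- f_out == 0
  fold <- if (capped) Inf else (f_in / n_spec) / (f_out / n_nonspec)
  structure(list(fold = fold, method = "position_distribution",
                 n_nonspecific_sites = as.integer(round(n_nonspec)),
                 n_internal = length(internal),
                 n_in_window = sum(in_w), capped = capped),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("Specificity (%s): %.3g-fold\n", x$method, x$fold))
  invisible(x)
}
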