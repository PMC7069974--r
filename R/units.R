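#' Convert base pairs to nanometres of B-form DNA
#'
#' Uses the canonical helical rise of B-form DNA (0.34 nm per base pair),
#' e.g. a 2030 bp fragment corresponds to about 690 nm of contour length.
#'
#' @param bp Base pairs (non-negative numeric vector).
#' @param rise_nm Helical rise per base pair in nm. Default 0.34.
#' @return Length in nm.
#' @examples
#' bp_to_nm(2030)   # ~690 nm
#' @export
bp_to_nm <- function(bp, rise_nm = 0.34) {
  stopifnot(is.numeric(bp), is.numeric(rise_nm), rise_nm > 0)
  if (any(bp < 0)) stop("bp must be non-negative")
  bp * rise_nm
}

#' Convert nanometres of B-form DNA to base pairs
#'
#' @param nm Length in nm (non-negative numeric vector).
#' @inheritParams bp_to_nm
#' @return Base pairs (real valued; not rounded).
#' @examples
#' nm_to_bp(130)   # ~382 bp
#' @export
nm_to_bp <- function(nm, rise_nm = 0.34) {
  stopifnot(is.numeric(nm), is.numeric(rise_nm), rise_nm > 0)
  if (any(nm < 0)) stop("nm must be non-negative")
  nm / rise_nm
}

#' Scale a UV photoproduct density with dose
#'
#' UV-C photoproduct formation is linear in fluence at these doses, so the
#' mean spacing between lesions scales inversely with dose: if 20 J/m^2
#' yields one photoproduct per 2.2 kbp, 80 J/m^2 yields one per 550 bp.
#'
#' @param dose_J_m2 Dose of interest (J/m^2), > 0.
#' @param ref_dose_J_m2 Reference dose (J/m^2). Default 20.
#' @param ref_spacing_bp Mean bp between lesions at the reference dose.
#'   Default 2200.
#' @return Mean spacing in bp between photoproducts at `dose_J_m2`.
#' @export
uv_lesion_spacing <- function(dose_J_m2, ref_dose_J_m2 = 20,
                              ref_spacing_bp = 2200) {
  stopifnot(dose_J_m2 > 0, ref_dose_J_m2 > 0, ref_spacing_bp > 0)
  ref_spacing_bp * ref_dose_J_m2 / dose_J_m2
}
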