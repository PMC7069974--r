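---
title: "Models and methods behind dnatracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dnatracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnatracks)
```

`dnatracks` quantifies how a DNA-repair protein finds damage, across three
experimental modalities: ensemble binding (EMSA titrations), static
single-molecule geometry (AFM height maps), and single-molecule dynamics
(DNA tightrope recordings). This vignette documents the models, the
tunable parameters with their defaults, the synthetic-data generators that
stand in for raw recordings, and the numerical choices made where the
procedures were genuinely open.

## Binding isotherms and specificity

When the assay DNA concentration is comparable to the dissociation
constant, the hyperbolic isotherm is invalid and the closed-form solution
of the single-site equilibrium with ligand depletion must be used:

$$\%\,\mathrm{bound} = 100 \cdot
\frac{(P + D + K_D) - \sqrt{(P + D + K_D)^2 - 4 P D}}{2 D},$$

with $P$ the total protein, $D$ the total DNA (8 nM by assay design) and
$K_D$ the apparent dissociation constant. `fit_kd()` fits $K_D$ as the
only free parameter, with $D$ fixed and the saturation plateau constrained
to 100% — freeing an amplitude is supported conceptually but off by
default, because a sub-100% plateau is indistinguishable from active-
fraction artefacts at the sample sizes involved.

An apparent affinity ratio between a non-damaged and a single-lesion
substrate understates per-site preference: an n-bp duplex with one lesion
still offers n non-specific sites. `site_corrected_specificity()`
multiplies the ratio by n (37 for a 37-bp duplex).

`position_distribution_specificity()` estimates specificity from imaged
binding positions instead, avoiding end-binder confounds. Positions are
folded distances to the closest end in (0, 50] percent of contour length,
so a window $(w_1, w_2)$ collects binders from both mirror arms of the
molecule. The accounting used here treats the window as one composite
specific region of $2(w_2-w_1)/100 \cdot n_{bp}$ sites and the remaining
internal DNA (end zones excluded on both sides) as the non-specific
region; the reported fold is the ratio of per-site occupancies inside
versus outside. This makes a uniform position distribution score exactly
1 in expectation, which we treat as the defining calibration of the
method; with all binders inside the window the ratio is infinite and is
reported as such with a flag.

## AFM volumetrics and DNA geometry

Particle volumes follow the footprint formula $V = A(H - B)$: area of the
thresholded 4-connected footprint times mean height above the image
background. The background $B$ is the mode of the height distribution
(the substrate plane dominates the image); background noise is estimated
robustly from the sub-background residuals, $\hat\sigma =
\mathrm{median}(|h - B|\,;\, h < B)/0.6745$, because pixels below the
plane carry only noise. The default detection threshold is $B + 3\sigma$.
Thresholding truncates the sub-threshold skirt of a particle; for the
blob shapes produced by the generator this loses ~10–13% of the volume,
which is why volume recovery is validated at the 15% level and why
molecular weights are obtained through an empirical calibration line
(`fit_calibration()`, ordinary least squares of volume on known MW)
rather than from absolute volumes. Tip convolution is likewise absorbed
by the calibration, not deconvolved.

DNA molecules are traced by thresholding at $2\sigma$, thinning each
connected ridge to a skeleton (Zhang–Suen), and ordering the skeleton by
a farthest-endpoint double BFS with lowest-pixel-index tie-breaks, so
tracing is deterministic. Molecules touching the image border are
rejected, as are skeletons whose main end-to-end path leaves more than
10% of skeleton pixels farther than one pixel away (true branches —
crossed or overlapping molecules — fail this; the staircase pixels that
thinning leaves on diagonals do not). The polyline is smoothed with a
±1-point moving average before arclength measurement: the raw 8-connected
chain code overestimates length by several percent on diagonals, while
wider windows cut genuine worm-like-chain curvature; ±1 balances the two
at about −2% on rendered 538-bp chains (we verified −2 to −5% across
smoothing windows 0–4 points). Accepted molecules must lie within ±10% of
the expected contour length.

Binding position is the arclength from the nearest contour point to the
protein centroid, divided by total length and folded to the closest end
(range 0–50%); positions within 2.5% of a terminus (~13 bp) count as
end-bound, a cutoff we chose since none is established.

Bend angles are the supplement of the interior angle at the vertex,
measured between chords drawn to points a tangent window away on each
side. The default window is 15 nm: rendering a ridge of ~2 nm half-width
and thinning it rounds any kink over roughly the ridge width, so 10 nm
chords sit partly inside the rounded corner and read a 60° kink ~7° low,
while 15 nm chords recover it within ~2° (sensitivity measured on
rendered ensembles: mean 52.6° at 10 nm, 57.0–58.5° at 15 nm, at an
ensemble sd of ~25°, which matches what is seen on real molecules).
Within `measure_complexes()` the vertex is taken as the angle-maximizing
point within ±5 nm of the binding site, since kink localization from the
image is uncertain by a few nm.

The volume of a protein bound to DNA is measured by flanking-DNA
subtraction, $V_{prot} = V_{complex} - (V_{DNA1}+V_{DNA2})/2$, with the
complex span defined by projecting the footprint onto the contour and
flanks of equal arclength immediately adjacent (relocated elsewhere on
the molecule when the protein sits near an end). All three regions are
integrated over tubes of 8 nm radius around the contour; pixels are
assigned to a region by the arclength of their nearest contour point, so
the tubes tile the molecule without double counting — an end-capped
capsule would leak complex volume into the flanks.

## Tightrope tracking

Kymographs are built by sampling each movie frame along the tightrope
axis with a width-one nearest-pixel slice (rows = position at 43.3 nm/px,
columns = frames at 0.1 s). The bandpass filter operates per column in
the frequency domain with Gaussian-edged cutoffs passing structure
between 3 and 40 px and zero gain at spatial DC, which removes frame-wide
constant offsets (the vertical-stripe component); the filter is linear.

Per-frame localization fits a 1D Gaussian with offset. Frames are marked
invalid when the fitted width leaves [0.5, 6] px, the amplitude is below
twice the residual sd, or the profile R² is below 0.5. These gates are
declared configuration, not reconstructions of any published criteria;
note that the R² gate is conservative on long profiles, where even a
well-fit dim spot explains little of the total (mostly background)
variance.

## Episodic-motion analysis

A particle is *motile* when the range of its valid positions exceeds
130 nm (three pixels, ~3.6× the 36 nm positional uncertainty) and
*dissociated* when the signal disappears for ≥200 frames through the end
of the recording; an interior gap of that length truncates analysis at
the gap, since re-appearances cannot be relinked to the same molecule
with confidence.

Motile trajectories are segmented into paused / short-range / long-range
phases by positional range with thresholds 130 and 690 nm (690 nm = 2030
bp, the lesion spacing of the defined-lesion array substrate). The rules
are: a shorter-range mode interrupts a longer-range one only if it
persists ≥5 s; "displacement" within a window means positional range
(max − min), not net displacement, so a drifting pause cannot pass as
paused. The implementation is a deterministic greedy left-to-right scan:
maximal pause windows are extracted first (earliest start, longest
extension), the remaining runs are labelled by their own range, and runs
exceeding 690 nm are split once by embedded ≥5 s short-range windows
(single-pass, not recursive — we found no evidence that nested
re-splitting is meaningful at these sample sizes). A particle already
paused when recording starts may yield a leading paused phase shorter
than 5 s; because *every* trajectory trivially begins inside some small
window, the leading exception needs a floor, and we require at least
`min_phase/2` = 2.5 s (configurable). An exhaustive window-scanning
oracle in the test suite verifies every declared rule on small
trajectories.

Pause sites are mean positions of paused phases merged by single linkage
within 130 nm (the motility threshold; no merge radius is established,
and 130 nm ≈ 3.6× the positional uncertainty is the natural scale).

Per-phase diffusion coefficients come from the time-averaged MSD,
$\mathrm{MSD}(n\Delta t) = \frac{1}{N-n}\sum_i (x_{i+n}-x_i)^2$,
evaluated over valid frame pairs (lags with fewer than 5 pairs dropped),
fitted by OLS to $2D\,n\Delta t + y$ over the first 25% of lags (common
practice; at least 3 usable lags), with the intercept $y$ absorbing
static localization error. Fits with $R^2 < 0.8$, using <10% of the MSD
curve, or with non-positive slope are not accepted.

Two theoretical quantities close the analysis. The rotation-coupled
sliding limit

$$D_{lim} = \frac{k_B T}{6\pi\eta a + \left(\frac{2\pi}{\mathrm{pitch}}\right)^2
(8\pi\eta a^3 + 6\pi\eta a R_{OC}^2)}$$

with defaults T = 298 K, η = 1 mPa·s, pitch 10.5 bp × 0.34 nm, particle
radius a = 12 nm (protein plus quantum-dot label) and off-centre distance
$R_{OC} = a + 1$ nm, gives 0.016 µm²/s; the defaults are our documented
choices consistent with the ~0.015 µm²/s scale of such labels, and the
expression reduces to Stokes–Einstein as pitch → ∞. The energy-landscape
roughness uses $\sigma = \sqrt{\ln(D_{ref}/D_{obs})}\,k_BT$; the default
reference is the long-range (hopping) coefficient, the convention that
reproduces the ~1.6 $k_BT$ scale from the two measured modes —
$\sqrt{\ln(D_{lim}/D_{obs})}$ is also computable with `d_limit()` as the
reference.

## Synthetic data: what it emulates, and what it does not

`simulate_trajectory()` draws a continuous-time three-state Markov chain
(paused / short / long) with exponential dwells of mean 14 s per mode —
matching the near-equal measured lifetimes (14.4 / 13.1 / 14.0 s) — and
integrates 1D Brownian motion at 3.2×10⁻³ or 3.7×10⁻² µm²/s in the
motile modes, reflected at the tightrope ends. Lesions multiply the
pause-entry weight (default ×3, configurable; the true value is not
identifiable from printed summaries) within a 200 nm capture radius, and
a pause entered near a lesion snaps to it, emulating returns to preferred
sites. Observed positions add positional noise with 36 nm stationary sd
modelled as an Ornstein–Uhlenbeck process with a 2 s correlation time:
the dominant uncertainty sources (stage drift, DNA and tightrope
fluctuation) vary on the seconds scale, and frame-independent noise of
the same amplitude would make the 130 nm / 5 s pause rules unusable —
the range of 50 white-noise frames at 36 nm already exceeds 130 nm.
Blinking is i.i.d. per frame; dissociation is a single exponential time
after which frames are dark. Dwells harvested from 300 s windows are
slightly short (the dwell straddling the end is dropped — an
inspection-paradox truncation of ~8%), so the generator's dwell self-test
uses long recordings; 10 fps, 300 s, 43.3 nm/px are the recording
conditions emulated.

`simulate_afm_field()` renders 1 × 1 µm, 512 × 512 px fields of 538 bp
worm-like chains sampled at 50 nm persistence length (2D equilibrated
convention, tangent-angle variance ds/ℓp per step), with an optional
in-plane bend of defined angle at 30% of the contour, protein blobs as
Gaussian caps of defined integrated volume (default Normal(30, 13) nm³,
σ = 2 nm — a realistic tip-broadened footprint whose 3σ-threshold
truncation stays near 13%), ridges 0.3 nm tall (typical for dsDNA in
air), and Gaussian surface roughness of 0.05 nm. Ridges are stamped by
maximum (no double-counting along the chain), blobs additively (DNA runs
beneath the protein). `simulate_emsa()` adds truncated Gaussian noise to
the depletion isotherm.

What the generators do **not** emulate: photophysics beyond Poisson shot
noise and i.i.d. blinking, 3D DNA mechanics and tip–sample convolution,
multi-particle fields per kymograph, sequence-dependent structure, or
camera artefacts. Passing recovery tests therefore demonstrates that the
analysis code is a correct and well-calibrated implementation of the
stated procedures on data matching its assumptions — not that those
procedures are robust to every artefact of real recordings.

## Numerical choices and degenerate inputs

Histogram fits use bins = round(√n) spanning the data range; Gaussian
and double-Gaussian fits are unweighted least squares on bin counts
(weighting is not established for this use), initialized at sample
moments or at the two largest separated histogram peaks, with component
sd floored at a quarter bin width (narrower components are unresolvable
and underflow the model gradient) and a perturbed-start retry for
symmetric degeneracies. Double-Gaussian components are always reported
sorted by ascending mean. Exponential lifetimes are fitted on the
empirical survival function rather than binned counts (robust to
binning; right-censoring by the recording window is ignored, consistent
with how such lifetimes are customarily reported). The χ² test applies
no continuity correction. Degenerate inputs (constant samples, flat
titrations, all-invalid frames, empty fields) return explicit
non-converged / empty results rather than errors wherever a result
object is expected.

Problem sizes in the test suite (ensembles of 20–30 fields, 200 phases,
500 dwells, 60-frame oracle trajectories) were chosen so that each
statistical recovery check has comfortable power at its stated tolerance
while the whole suite runs in minutes.

## Known limitations

Threshold-rule segmentation is the method being reproduced, not the
state of the art; HMM or Bayesian changepoint methods would classify
ambiguous phases more gracefully. Contour tracing rejects crossed or
self-overlapping molecules rather than resolving them. The tube-based
complex volumes assume well-separated molecules. The position-
distribution specificity depends on the documented site accounting;
with other conventions its absolute scale changes, so comparisons should
use one convention throughout.
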