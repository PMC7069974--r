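# dnatracks

Single-molecule analysis of how DNA-repair proteins bind, bend and scan
DNA, for researchers quantifying damage search with EMSA, atomic force
microscopy (AFM) and DNA tightrope / kymograph experiments.

The package implements three connected analyses:

1. **Binding and specificity.** Titrations are fitted with the
   closed-form single-site depletion isotherm (required when the DNA
   concentration is of the same order as K_D),

   ```
   % bound = 100 · [(P + D + K_D) − √((P + D + K_D)² − 4PD)] / (2D),
   ```

   and lesion specificity is derived either by the non-specific-site
   correction (K_D ratio × n sites) or from imaged binding-position
   distributions (per-site occupancy ratio, end-binders excluded).

2. **AFM volumetrics and DNA geometry.** Particle volumes V = A(H − B)
   from thresholded footprints, a least-squares calibration line
   converting AFM volume to molecular weight, DNA contour tracing
   (skeletonization + deterministic path ordering, ±10% length filter),
   binding position by the closest-end convention, bend angles θ
   (supplement of the interior angle at the site), and bound-protein
   volumes by flanking-DNA subtraction
   V_protein = V_complex − (V_DNA1 + V_DNA2)/2.

3. **Tightrope tracking and episodic diffusion.** Kymograph
   construction, FFT bandpass filtering (3–40 px, vertical-stripe
   suppression), per-frame 1D Gaussian localization, segmentation of
   motile trajectories into paused / short-range / long-range phases
   (130 nm and 690 nm range thresholds, 5 s interruption rule), pause
   sites, phase-lifetime exponential fits on the survival function,
   per-phase diffusion coefficients from MSD(nΔt) = 2D·nΔt + y (R² ≥
   0.8, ≥10% of lags), the rotation-coupled sliding limit D_lim, and
   the energy-landscape roughness σ = √ln(D_ref/D_obs) in k_BT.

Since raw recordings for such studies are rarely deposited, the package
ships seeded synthetic-data generators (worm-like-chain AFM fields,
three-state switching-diffusion tightrope movies, EMSA titrations) that
emit ground-truth sidecars; every analysis stage is validated by
recovery against them.

## Worked example

```r
library(dnatracks)

# --- EMSA: recover K_D from a noisy titration and compute specificity
iso <- simulate_emsa(K_D = 109, D = 8, noise_sd_pct = 3, seed = 7)
fit_kd(iso)
#> K_D = 119.9 +/- 7.2 nM (R^2 = 0.994)
site_corrected_specificity(253, 109, 37)
#> Specificity (site_corrected_emsa): 85.9-fold

# --- tightropes: simulate, classify, segment, measure
rep1 <- run_tightrope_pipeline(n_particles = 6, seed = 42)
round(rep1$mode_fractions, 3)
#> paused  short   long
#>  0.318  0.596  0.086
rep1$pause_site_counts
#> [1] 4 4 3 2 5 5
tapply(rep1$diffusion$D_um2_s, rep1$diffusion$mode, median)
#>        long       short
#> 0.055446270 0.009665358
energy_barrier(3.2e-3, 3.7e-2)
#> [1] 1.564534
```

The K_D fit lands within the titration noise of the generating 109 nM;
the site-corrected fold is the K_D ratio scaled by the 37 bp of
non-specific sites on the duplex. In the tightrope report, the mode
fractions sum to one over the motile particles, each entry of
`pause_site_counts` is the number of distinct pause sites one particle
revisited, and the per-phase diffusion coefficients separate the two
motile modes by an order of magnitude (phases are short, so individual
estimates scatter around their mode's coefficient). The final number is
the roughness of the binding-energy landscape implied by that
separation, in units of k_BT.

AFM analysis runs the same way from `run_afm_pipeline()` /
`measure_complexes()`; see the vignette in `vignettes/` for the models,
parameter defaults, and generator assumptions.

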