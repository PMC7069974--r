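Package: dnatracks
Title: Single-Molecule Analysis of Protein-DNA Binding, Bending and Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for single-molecule studies of DNA repair
    proteins searching DNA for damage. Fits electrophoretic mobility shift
    titrations with the closed-form single-site depletion isotherm and derives
    lesion specificity; quantifies atomic force microscopy height maps
    (particle volumes, volume-to-molecular-weight calibration, DNA contour
    tracing, binding position and induced bend angles); builds and filters
    fluorescence kymographs from DNA tightrope movies, localizes particles by
    one-dimensional Gaussian fitting, segments trajectories into paused,
    short-range and long-range diffusion phases, and estimates per-phase
    diffusion coefficients by mean-squared-displacement analysis together
    with rotation-coupled sliding limits and energy-landscape roughness.
    Includes seeded synthetic-data generators (worm-like-chain AFM fields,
    switching-diffusion tightrope movies, titration tables) with ground-truth
    sidecars for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
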