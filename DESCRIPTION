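Package: rnpsaxs
Title: Contrast-Variation SAXS Analysis of Protein-RNA Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for small-angle X-ray scattering (SAXS) analysis of
    two-phase ribonucleoprotein particles in solution. Implements Guinier,
    Kratky and Porod-Debye diagnostics, mid-q power-law shape classification,
    triaxial ellipsoid form-factor fitting, smoothness-regularized indirect
    Fourier transform to the pair-distance distribution P(r), sucrose-based
    contrast variation with Stuhrmann analysis, ab initio two-phase bead-model
    shape restoration by simulated annealing with NSD-based alignment and
    averaging, and bead-model hydrodynamics (Kirkwood friction, sedimentation
    coefficients, Svedberg mass, Perrin axial ratios). A synthetic-data module
    generates two-phase bead phantoms and computes their exact scattering by
    the Debye formula, providing ground truth for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
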