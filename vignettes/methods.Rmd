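---
title: "Contrast-variation SAXS analysis of two-phase ribonucleoproteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-variation SAXS analysis of two-phase ribonucleoproteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnpsaxs)
```

# The problem

A protein–RNA complex in dilute solution scatters X-rays according to the
spatial arrangement of *all* its electron density in excess of the solvent.
For a hybrid particle the two components contribute very differently: RNA
(~0.55 e⁻/Å³) carries roughly twice the contrast of protein (~0.425 e⁻/Å³)
against water (~0.334 e⁻/Å³). By raising the solvent electron density with
sucrose, the protein contribution can be dialled down — and near ~63 % w/w
sucrose extinguished — while the RNA remains visible. The trend of the
apparent radius of gyration across such a contrast series reveals *where*
each component sits relative to the centre of mass, and a multi-phase bead
reconstruction against several contrasts recovers a low-resolution
three-dimensional arrangement of both phases.

`rnpsaxs` implements this entire chain for a 2:1 protein–RNA particle of the
kind formed by a group II intron lariat (~902 nt, ~292 kD) bound to a dimer
of its maturase protein (~2 × 70 kD): model-free profile analysis, P(r)
inversion, Stuhrmann analysis, two-phase annealing reconstruction with
NSD-based averaging, and forward hydrodynamics from bead models. Because no
raw scattering data are deposited for this system, the package carries a
first-class synthetic-data module: two-phase bead phantoms whose exact
scattering at any sucrose contrast follows from the Debye formula, so every
analysis stage can be validated against known ground truth.

# Synthetic data: what the phantoms emulate

`build_phantom()` fills analytic shapes with beads on a hexagonal
close-packed lattice (one site per $a^3/\sqrt2$). The `two-phase-RNP` kind
emulates the target particle: an oblate envelope (244 × 244 × 79 Å by
default) with a central protein region holding a configurable share of the
particle volume (default 0.33 — a 140 kD dimer at $\bar v$ 0.73 cm³/g inside
a 432 kD particle) and a nucleic envelope thinned at the waist into two
lobes joined by a neck ("bow-tie"). The waist geometry (`waist = 0.45`,
`neck = 0.30`, fractions of the semi-axes) is a package constant: only the
qualitative arrangement — two large peripheral RNA lobes bridged past a
central protein — is constrained by the science. `RNP-plus-lobe` appends a
tRNA-sized 60 Å nucleic sphere on the long axis at 140 Å from the centre,
the landmark construct used to orient the envelope.

`simulate_profile()` evaluates
$$I(q) = \Phi(q r_b)^2 \sum_{ij} \Delta\rho_i \Delta\rho_j\, v_i v_j\,
\frac{\sin q r_{ij}}{q r_{ij}},$$
with $\Phi$ the sphere form-factor amplitude of one bead. Pair distances are
binned at $r_b/2$ (an exact pairwise mode backs oracle tests); $I(0)$ equals
$(\sum_i \Delta\rho_i v_i)^2$ identically. Solvent electron density follows
a quadratic fit to 20 °C sucrose solution density tables combined with the
electrons-per-gram mixture rule; contrasts are computed at 20 °C (the
temperature dependence of contrast is second order for this purpose).
Hydration shells are not modelled — the same two-phase vacuum-in-solvent
simplification the reconstruction itself makes.

Simulated noise is Gaussian with
$\sigma(q) = f\, I(q)\,(1 + (q/q_{max})^p)$ (defaults $f = 0.02$, $p = 2$),
seeded and reproducible. For noiseless validation series the same $\sigma$
band can be attached without perturbing intensities
(`noise_spec(perturb = FALSE)`): chi-square values then measure model error
against a defined 1 % uncertainty scale. The default measurement grid is 150
log-spaced points over 0.006–0.32 Å⁻¹, and the default contrast series is
0, 16.5, 32.5, 48.8 and 65 % w/w sucrose.

What passing tests on these phantoms do *not* show: real data carry
inter-particle interference, radiation damage, buffer-subtraction errors,
hydration-layer contrast and RNA conformational heterogeneity. The phantoms
validate the *estimators*, not the experiment.

# Model-free profile analysis

**Guinier.** `guinier_fit()` iterates a weighted linear fit of $\ln I$ vs
$q^2$ to a fixed-point window $0.4 \le qR_g \le 1.3$ (the conventional
globular window), reporting $R_g$, $I(0)$ and their standard errors. On
noiseless globular data the plain two-parameter fit is biased high by 1–2 %
even within the conventional window, because the $q^4$ term of $\ln I$ is
not negligible there; `curvature = TRUE` adds that term and reduces the bias
to ~0.2 %. The package's phantom-recovery work uses the curvature fit; the
plain fit remains the default because on noisy experimental data the extra
term mostly absorbs noise.

**Power-law exponent.** `powerlaw_exponent()` fits $\log I$ vs $\log q$ over
a stated window: ~2 for thin flat particles, ~1 for long rods, 4 in the
Porod regime of globular particles (measured through the envelope of the
oscillation maxima of $q^4 I$, `envelope = TRUE`). The asymptotic regimes
are narrow: the package's validation windows run from $1.5\cdot 2\pi/a$
(long axis $a$) up to $0.6\sqrt{12}/T$ for a flat particle of thickness $T$
(where the thickness factor $e^{-q^2T^2/12}$ starts to bite) or $0.7/r$ for
a rod of cross-section semi-axis $r$. Windows touching the form-factor
shoulder on one side or the thickness decay on the other produce steeper
apparent exponents — a 220 × 220 × 34 Å oblate fitted across its whole
mid-q range decays like $q^{-2.6}$, not $q^{-2}$, which is worth remembering
when comparing against measured slopes.

**Kratky / Porod–Debye.** `kratky_porod()` calls a profile compact when
$q^2I$ falls back below 80 % of its peak and $q^4I$ reaches a plateau
(relative trend < 0.3 over the last third of the range), flexible in the
opposite pattern, indeterminate otherwise.

**Ellipsoid form factor.** `ellipsoid_form_fit()` fits the
orientation-averaged triaxial ellipsoid intensity (32 × 32 Gauss–Legendre
quadrature over one octant) for axes and scale, multi-started from sphere,
3:3:1 oblate and 1:1:3 prolate seeds at the apparent $R_g$, and classifies
by axis ratios (oblate if $a/c \ge 2$ and $a/b < 1.5$; prolate if
$a/b \ge 2$ and $b/c < 1.5$; else sphere-like).

**Composition arithmetic.** `flory_rg()` ($R_g = 5.5\,\mathrm{Å}\cdot
n^{1/3}$, the compact-RNA prefactor), `theoretical_mass()` (default mean
ribonucleotide residue mass 323.7 Da, chosen so 2 × 70 kD + 902 nt gives a
432 kD particle consistent with the printed composition; override for a
known sequence) and `mass_averaged_dndc()` (mass-fraction-weighted mean;
component dn/dc values are inputs, since published mass-averaged values can
be reproduced by more than one choice of components).

# P(r) inversion

`pr_transform()` solves the regularized indirect Fourier transform
$$\min_p \left\|\frac{I - Ap}{\sigma}\right\|^2 + \alpha\|D^2 p\|^2,\qquad
p(0) = p(D_{max}) = 0,$$
on 101 knots, with $A$ the $4\pi\,\mathrm{sinc}(qr)$ kernel under trapezoid
quadrature and $D^2$ the second-difference operator. Nonnegativity (on by
default — dilute particles) is imposed by non-negative least squares.
$\alpha$ defaults to an L-curve corner choice over a log-spaced grid; real
and reciprocal space moments give `rg_real` and `i0_real`.

`dmax_scan()` runs the inversion (positivity off, so an oversized $D_{max}$
betrays itself through negative tail oscillations) over a candidate grid and
reports chi, terminal slope and negative-lobe fraction per candidate. The
selection rule is the smallest candidate on the chi plateau (within 3× of
the best chi): chi falls by orders of magnitude once $D_{max}$ reaches the
true extent and is flat beyond it, so an argmin over any composite of these
diagnostics cannot reject oversized candidates — a larger $D_{max}$ fits
exactly as well with a flat tail. Boundary selections raise a warning.

`model_pr()` computes P(r) directly from a bead model: contrast-weighted
centre-distance histogram, the exact intra-bead single-sphere term, and
Gaussian broadening of the cross terms at $r_b/2$.

# Stuhrmann analysis

With $x = 1/\bar{\Delta\rho}$ (volume-weighted mean contrast from
`mean_contrast()`), `stuhrmann_fit()` fits
$$R_g^2 = R_c^2 + \alpha x - \beta x^2$$
by weighted least squares (weights from propagated Guinier uncertainties),
solving exactly for three points. $\alpha > 0$ means the denser phase lies
peripheral — the sign that, for this particle, places the protein dimer near
the centre of mass; $\beta > 0$ flags displacement of the density centre
from the shape centre. Because three to five contrasts rarely constrain all
three terms tightly, the full fit is always accompanied by a $\beta = 0$
restricted fit and an F-test, and sign-level conclusions should be drawn
only when the corresponding term clears its uncertainty. Match-point entries
(undefined $x$) are excluded with a warning. On bead phantoms the lattice is
not exactly centrosymmetric, so "$\beta$ consistent with zero" is asserted
at the scale of the experiment ($|\beta| x_{max}^2 < 2\,\%$ of $R_c^2$)
rather than against its (noiseless, tiny) standard error.

# Two-phase reconstruction

`anneal()` restores shape by assigning one of {solvent, protein, nucleic} to
every bead of an HCP search sphere, scoring
$$\sum_{\text{profiles}} \chi^2_{red} \;+\; w_L L + w_D C + w_V V$$
where $\chi^2_{red}$ uses the same Debye engine with per-condition contrasts
and an analytic per-profile scale, $L$ is the fraction of non-solvent beads
with fewer than six non-solvent lattice neighbours, $C$ counts connected
components beyond one per material phase, and $V$ the squared relative
phase-volume deviations. Moves flip one random bead to one random other
phase under a Metropolis rule; temperature falls by 0.95 per level of
$10N$ moves; the score is recomputed exactly at every level to bound
incremental drift; and a zero-temperature quench runs after cooling so the
returned state is a local optimum. Everything is reproducible from the seed.

Three numerical choices deserve explanation:

* **Penalty weights** (defaults $w_L = 2$, $w_D = 5$, $w_V = 30$) were
  calibrated on ground-truth recovery. Because each profile carries a free
  scale factor, bead-level porosity is an almost flat direction of the
  chi-square landscape: a half-empty envelope of the right outer shape fits
  the data nearly as well as the compact particle. The volume term must
  therefore act as a near-constraint — which matches how multi-phase
  practice treats the phase volumes (they are inputs, not fit parameters).
* **Initial temperature** defaults to the spread of 100 random-move score
  changes, capped at 10 score units: at a random start that spread is
  dominated by the enormous misfit and would otherwise park the whole
  schedule far above the ordering regime.
* **Fit range**: only $q \le$ `q_max_fit` (default 0.15 Å⁻¹) is fitted —
  the bead model carries no internal structure, so higher angles would only
  import systematic error.

`nsd()` implements the normalized spatial discrepancy between bead sets
(0 for identical models, ≲1 for similar ones), phase-blind with per-phase
variants attached. `align()` moves models to principal axes and picks the
best of the four proper axis flips against the reference; mirror search is
opt-in because small-angle scattering cannot determine chirality.
`average_filter()` accumulates per-site phase occupancies across aligned
replicates (snap-to-grid on the reference lattice) and keeps each phase's
most-occupied sites up to its expected volume.

**Which contrasts localize the core?** Validation uses a protein-core
phantom measured at 0, 32.5 and 65 % sucrose — a spread reaching toward the
protein match point. With a narrow low-sucrose series (0/16.5/32.5 %) the
protein centroid is recovered only unreliably (errors comparable to the
2-bead-radius criterion), because the protein phase then modulates the
profiles weakly; this is precisely the physical argument for pushing
contrast series as wide as the sample tolerates. The validation study uses
a ~1300-bead search grid commensurate with the phantom lattice, so the
exact solution is representable; with incommensurate bead sizes the
bead-form mismatch adds a systematic floor that biases recovered volumes.

# Hydrodynamics

`kirkwood_friction()` evaluates the first-order Kirkwood–Bloomfield double
sum
$$f = \frac{6\pi\eta N\sigma}{1 + (\sigma/N)\sum_{i\ne j} r_{ij}^{-1}}.$$
Friction is a boundary property: summed over a *filled* ball the expression
converges to $(5/6)R$, so lattice models are reduced to their surface shell
(beads with incomplete neighbour shells) by default, which restores the
sphere limit to ~4 %. On flat particles the first-order approximation still
underestimates friction (the bow-tie phantom computes $f/f_0 \approx 1.7$
where the Perrin factor of the matching oblate implies ~2.0), so calculated
frictional ratios should be read as ordering information — compact
($\approx 1$) versus strongly anisotropic ($\gtrsim 1.5$) — rather than to
the second decimal. Hydration is excluded throughout (anhydrous bead
surfaces); this is the main systematic offset against experimental $R_s$.

The scalar relations — `sedimentation_coefficient()` ($s = M(1-\bar v\rho)/
(N_A f)$), `s20w_correction()` (pinned 20 °C water constants: 0.99823 g/cm³,
0.010020 poise), `svedberg_mass()` (root of the implicit Svedberg relation
at a given $f/f_0$), `perrin_axial_ratio()` (inverting
$F(p)=\sqrt{p^2-1}/(p^{1/3}\ln(p+\sqrt{p^2-1}))$ for prolate and the
arctangent analogue for oblate ellipsoids of revolution, $p \ge 1$) and
`volume_from_mass()` — take $\bar v$ explicitly everywhere; the package
never hard-codes a partial specific volume. Perrin conventions differ
between sources for oblate ellipsoids; the formulas above are the ones
used, and axial ratios quoted from other conventions can differ by tens of
percent at large anisotropy. A compact 432 kD particle of this composition
($\bar v$ 0.63) at $f/f_0 = 1.2$ computes to ~24.7 S by these relations.

# Pipeline and problem sizes

`run_pipeline()` chains the stages in the order primary analysis → P(r) →
Stuhrmann → reconstruction ensemble → averaging → hydrodynamics, with
failures in optional stages recorded and skipped past, and writes profiles,
the final model and a JSON summary when an output directory is given.
Replicates default to 10; the bundled validation and tests run 2–5
replicates on ~500–1300-bead grids with 50–150-point q grids, sizes chosen
so the full suite completes on a desk machine while leaving the estimators'
error bands (1–6 %) comfortably resolvable. `compare_shapes()` overlays two
models' P(r) (scaled onto each other over the shared body), reports NSD
after alignment, and localizes where the curves diverge — the machinery
used to place the tRNA landmark lobe at the particle's distal end.

# Known limitations

* Chirality is undetermined; averaged envelopes inherit the enantiomorph of
  the reference replicate.
* The annealer's single-bead moves cannot hop beads across the particle;
  convergence relies on the volume near-constraint and the quench. Runs
  from different seeds should always be compared (NSD) before averaging.
* P(r) regularization constants (101 knots, L-curve corner) are package
  choices; other defensible choices shift $D_{max}$ estimates by a few
  percent.
* The sucrose density fit is a 20 °C quadratic; below ~5 °C the absolute
  contrast scale shifts slightly, though contrast *differences* across a
  series are barely affected.
* No hydration layer, no interparticle structure factor, no absolute-scale
  molecular weight calibration.
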