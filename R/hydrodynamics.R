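# Forward hydrodynamics from bead models and compositions: Kirkwood
# friction, Stokes radius, sedimentation coefficients with s20,w
# standardization, Svedberg mass arithmetic and Perrin axial ratios.

.NAV <- 6.02214076e23
.CM_PER_A <- 1e-8
# water at 20 C, the s20,w reference state
.WATER20 <- list(density = 0.99823, viscosity = 0.010020, temperature = 20)

#' Solvent specification
#'
#' @param density solvent density (g/cm^3).
#' @param viscosity solvent viscosity (poise).
#' @param temperature temperature (deg C), bookkeeping only.
#' @return Object of class `solvent_spec`.
#' @export
solvent_spec <- function(density = 0.99823, viscosity = 0.010020,
                         temperature = 20) {
  if (density <= 0 || viscosity <= 0) stop("solvent properties must be positive")
  structure(list(density = density, viscosity = viscosity,
                 temperature = temperature), class = "solvent_spec")
}

#' Kirkwood friction of a bead model
#'
#' First-order Kirkwood-Bloomfield estimate of the translational friction of
#' N equal beads of radius \eqn{\sigma}:
#' \deqn{f = \frac{6\pi\eta N\sigma}{1 + (\sigma/N)\sum_{i\ne j} 1/r_{ij}}}
#' summed over the non-solvent bead centres. Exact for N = 1 (Stokes law);
#' for a fine-bead solid sphere it recovers the Stokes radius to within about
#' 6 % (the documented accuracy of the first-order approximation).
#'
#' Friction is a boundary property: for volume-filled models the plain
#' double sum converges to (5/6)R for a solid ball, so by default the model
#' is first reduced to its surface shell (beads with an incomplete lattice
#' neighbour shell), which restores the correct sphere limit. Free
#' (off-lattice) models are used as given.
#'
#' @param model a [bead_model()].
#' @param solvent a [solvent_spec()].
#' @param surface_only reduce lattice models to their surface shell
#'   (default `TRUE`).
#' @return Friction coefficient in g/s.
#' @export
kirkwood_friction <- function(model, solvent = solvent_spec(),
                              surface_only = TRUE) {
  stopifnot(inherits(model, "bead_model"))
  ns <- nonsolvent(model)
  if (surface_only && !identical(ns$lattice, "free") &&
      nrow(ns$centers) > 20L) {
    surf <- surface_beads(ns)
    if (nrow(surf$centers) >= 12L) ns <- surf
  }
  n <- nrow(ns$centers)
  sig <- ns$bead_radius * .CM_PER_A
  if (n == 1L) return(6 * pi * solvent$viscosity * sig)
  inv_sum <- cpp_inv_dist_sum(ns$centers)   # in A^-1
  if (inv_sum < 0) stop("geometry error: overlapping identical bead centres")
  inv_sum <- inv_sum / .CM_PER_A            # -> cm^-1
  6 * pi * solvent$viscosity * n * sig / (1 + (sig / n) * inv_sum)
}

#' Surface shell of a lattice bead model
#'
#' Keeps the beads whose first lattice-neighbour shell is incomplete
#' (fewer than 12 occupied neighbours within 1.2 x spacing).
#'
#' @param model a [bead_model()] on a lattice (non-solvent beads only).
#' @return A [bead_model()] containing the surface beads.
#' @export
surface_beads <- function(model) {
  X <- model$centers
  sp <- .lattice_spacing(model)
  n <- nrow(X)
  thr2 <- (1.2 * sp)^2
  nn <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (X[, 1] - X[i, 1])^2 + (X[, 2] - X[i, 2])^2 + (X[, 3] - X[i, 3])^2
    nn[i] <- sum(d2 <= thr2) - 1L
  }
  keep <- nn < 12L
  bead_model(X[keep, , drop = FALSE], model$bead_radius, model$phases[keep],
             model$lattice, occupancy = model$occupancy[keep])
}

#' Stokes radius from a friction coefficient
#'
#' @param friction friction in g/s.
#' @param solvent a [solvent_spec()].
#' @return Stokes radius in \eqn{\mathrm{\AA}}.
#' @export
stokes_radius <- function(friction, solvent = solvent_spec()) {
  friction / (6 * pi * solvent$viscosity) / .CM_PER_A
}

#' Sedimentation coefficient from mass and friction
#'
#' Svedberg relation \eqn{s = M(1-\bar v\rho)/(N_A f)}, reported in Svedberg
#' units (1 S = 1e-13 s).
#'
#' @param friction friction in g/s.
#' @param mass particle mass in kD.
#' @param vbar partial specific volume (cm^3/g).
#' @param solvent a [solvent_spec()].
#' @return Sedimentation coefficient in S.
#' @export
sedimentation_coefficient <- function(friction, mass, vbar,
                                      solvent = solvent_spec()) {
  buoy <- 1 - vbar * solvent$density
  if (abs(buoy) < 1e-12) stop("domain error: neutral buoyancy (vbar*rho = 1)")
  s_sec <- mass * 1000 * buoy / (.NAV * friction)
  s_sec / 1e-13
}

#' Standardize a sedimentation coefficient to water at 20 C
#'
#' \deqn{s_{20,w} = s_{T,b}\,\frac{\eta_{T,b}}{\eta_{20,w}}\,
#'   \frac{1-\bar v\rho_{20,w}}{1-\bar v\rho_{T,b}}}
#' with the 20 C water constants pinned at \eqn{\rho} = 0.99823 g/cm^3,
#' \eqn{\eta} = 0.010020 poise.
#'
#' @param s_buffer measured coefficient in S.
#' @param solvent buffer [solvent_spec()].
#' @param vbar partial specific volume (cm^3/g).
#' @return s20,w in S.
#' @export
s20w_correction <- function(s_buffer, solvent, vbar) {
  w <- .WATER20
  s_buffer * (solvent$viscosity / w$viscosity) *
    (1 - vbar * w$density) / (1 - vbar * solvent$density)
}

#' Mass from sedimentation parameters (Svedberg arithmetic)
#'
#' Solves the implicit relation
#' \deqn{M(1-\bar v\rho) = N_A\,s\,6\pi\eta\,(f/f_0)\,(3M\bar v/(4\pi N_A))^{1/3}}
#' for M by bracketed root-finding: the friction is that of the equal-volume
#' (anhydrous) sphere of the unknown mass, scaled by the frictional ratio.
#'
#' @param s sedimentation coefficient in S.
#' @param f_over_f0 frictional ratio (>= 1).
#' @param vbar partial specific volume (cm^3/g).
#' @param solvent a [solvent_spec()].
#' @return Mass in kD.
#' @export
svedberg_mass <- function(s, f_over_f0, vbar, solvent = solvent_spec()) {
  if (f_over_f0 < 1) stop("domain error: f/f0 must be >= 1")
  if (s <= 0 || vbar <= 0) stop("inputs must be positive")
  buoy <- 1 - vbar * solvent$density
  if (buoy <= 0) stop("domain error: no positive root (non-sedimenting particle)")
  s_sec <- s * 1e-13
  g <- function(m_g) {  # m in g/mol
    r0 <- (3 * m_g * vbar / (4 * pi * .NAV))^(1 / 3)  # cm
    m_g * buoy - .NAV * s_sec * 6 * pi * solvent$viscosity * f_over_f0 * r0
  }
  lo <- 1; hi <- 1e12
  if (g(lo) > 0 || g(hi) < 0) stop("domain error: no positive root bracketed")
  uniroot(g, c(lo, hi), tol = 1e-9)$root / 1000
}

# Perrin translational friction factors for ellipsoids of revolution with
# axial ratio p = (long axis)/(short axis) >= 1.
perrin_f <- function(p, shape_class = c("prolate", "oblate")) {
  shape_class <- match.arg(shape_class)
  if (any(p < 1)) stop("axial ratio must be >= 1")
  xi <- sqrt(pmax(p^2 - 1, 0))
  out <- ifelse(p == 1, 1,
                if (shape_class == "prolate")
                  xi / (p^(1 / 3) * log(p + xi))
                else
                  xi / (p^(2 / 3) * atan(xi)))
  out
}

#' Perrin axial ratio from a frictional ratio
#'
#' Numeric inversion of the Perrin translational friction factor for
#' ellipsoids of revolution. Convention used here (axial ratio
#' \eqn{p \ge 1}): prolate
#' \eqn{F(p)=\sqrt{p^2-1}/(p^{1/3}\ln(p+\sqrt{p^2-1}))}; oblate
#' \eqn{F(p)=\sqrt{p^2-1}/(p^{2/3}\arctan\sqrt{p^2-1})}.
#'
#' @param f_over_f0 frictional ratio (> 1).
#' @param shape_class `"prolate"` or `"oblate"`.
#' @return Axial ratio p >= 1.
#' @export
perrin_axial_ratio <- function(f_over_f0, shape_class = c("prolate", "oblate")) {
  shape_class <- match.arg(shape_class)
  if (f_over_f0 <= 1) stop("domain error: f/f0 must exceed 1")
  g <- function(p) perrin_f(p, shape_class) - f_over_f0
  if (g(1e4) < 0)
    stop("range error: no axial ratio below 10^4 reproduces f/f0 = ", f_over_f0)
  uniroot(g, c(1 + 1e-9, 1e4), tol = 1e-10)$root
}

#' Anhydrous particle volume from mass
#'
#' \eqn{V = M\bar v/N_A}, converted to \eqn{\mathrm{\AA}^3}.
#'
#' @param mass mass in kD.
#' @param vbar partial specific volume (cm^3/g).
#' @return Volume in \eqn{\mathrm{\AA}^3}.
#' @examples
#' volume_from_mass(432, 0.63)  # ~451,900 A^3
#' @export
volume_from_mass <- function(mass, vbar) {
  if (mass <= 0 || vbar <= 0) stop("inputs must be positive")
  mass * 1000 * vbar / .NAV * 1e24
}

#' Hydrodynamic summary of a bead model
#'
#' Kirkwood friction, Stokes radius, sedimentation coefficient in the given
#' buffer, its s20,w standardization, and the frictional ratio against the
#' equal-volume anhydrous sphere of the supplied mass.
#'
#' @param model a [bead_model()].
#' @param mass particle mass (kD).
#' @param vbar partial specific volume (cm^3/g).
#' @param solvent measurement buffer [solvent_spec()].
#' @return Object of class `hydro_result`.
#' @export
hydro_calc <- function(model, mass, vbar, solvent = solvent_spec()) {
  f <- kirkwood_friction(model, solvent)
  rs <- stokes_radius(f, solvent)
  s_b <- sedimentation_coefficient(f, mass, vbar, solvent)
  s20 <- s20w_correction(s_b, solvent, vbar)
  r0 <- (3 * mass * 1000 * vbar / (4 * pi * .NAV))^(1 / 3) / .CM_PER_A  # A
  f0 <- 6 * pi * solvent$viscosity * r0 * .CM_PER_A
  structure(list(friction = f, stokes_radius = rs, s_buffer = s_b,
                 s20w = s20, f_over_f0 = f / f0, mass_used = mass,
                 vbar_used = vbar, solvent = solvent),
            class = "hydro_result")
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf(
    "hydro: f %.3e g/s, Rs %.1f A, s %.2f S (s20,w %.2f S), f/f0 %.2f\n",
    x$friction, x$stokes_radius, x$s_buffer, x$s20w, x$f_over_f0))
  invisible(x)
}
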