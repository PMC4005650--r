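# Contrast-variation bookkeeping and the Stuhrmann decomposition
# Rg^2(1/mean-contrast) = Rc^2 + alpha/dr - beta/dr^2, which locates the
# low-density phase relative to the particle's centre of mass.

#' Contrast series
#'
#' Bundles matched (condition, profile, Guinier) triples measured across a
#' sucrose series, plus the two phase volumes needed to form mean contrasts.
#'
#' @param conditions list of [contrast_condition()].
#' @param profiles list of [scattering_profile()].
#' @param volumes numeric(2): protein and nucleic phase volumes
#'   (\eqn{\mathrm{\AA}^3}).
#' @param guinier optional list of precomputed `guinier_result`s; computed
#'   from the profiles when omitted.
#' @param guinier_args list of extra arguments passed to [guinier_fit()]
#'   when the Guinier results are computed here (e.g.
#'   `list(curvature = TRUE)` for noiseless synthetic series).
#' @return Object of class `contrast_series`.
#' @export
contrast_series <- function(conditions, profiles, volumes, guinier = NULL,
                            guinier_args = list()) {
  stopifnot(length(conditions) == length(profiles))
  if (length(volumes) != 2L || any(volumes <= 0))
    stop("volumes must be two positive phase volumes (protein, nucleic)")
  sw <- vapply(conditions, `[[`, 1, "sucrose_w")
  if (anyDuplicated(sw)) stop("conditions must be mutually distinct in sucrose_w")
  if (is.null(guinier))
    guinier <- lapply(profiles, function(p)
      tryCatch(do.call(guinier_fit, c(list(p), guinier_args)),
               error = function(e) NULL))
  entries <- Map(function(cn, pf, g) list(condition = cn, profile = pf,
                                          guinier = g),
                 conditions, profiles, guinier)
  structure(list(entries = entries,
                 volumes = c(protein = volumes[1], nucleic = volumes[2])),
            class = "contrast_series")
}

#' @export
print.contrast_series <- function(x, ...) {
  cat(sprintf("contrast_series: %d conditions, volumes P %.3g / N %.3g A^3\n",
              length(x$entries), x$volumes[1], x$volumes[2]))
  invisible(x)
}

#' Volume-weighted mean contrast of a two-phase particle
#'
#' \eqn{\bar{\Delta\rho} = (V_p \Delta\rho_p + V_n \Delta\rho_n)/(V_p+V_n)}.
#' A zero value (whole-particle match point) is returned with an attached
#' `match_point` attribute rather than as an error.
#'
#' @param condition a [contrast_condition()].
#' @param volumes numeric(2): protein and nucleic phase volumes.
#' @return Mean contrast in e-/\eqn{\mathrm{\AA}^3}.
#' @export
mean_contrast <- function(condition, volumes) {
  if (any(volumes <= 0)) stop("volumes must be positive")
  dbar <- (volumes[1] * condition$delta_protein +
           volumes[2] * condition$delta_nucleic) / sum(volumes)
  if (abs(dbar) < 1e-12) attr(dbar, "match_point") <- TRUE
  dbar
}

#' Stuhrmann fit
#'
#' Weighted least squares of \eqn{R_g^2 = R_c^2 + \alpha x - \beta x^2} in
#' \eqn{x = 1/\bar{\Delta\rho}}, with weights from the propagated Guinier Rg
#' uncertainties (equal weights where absent). With exactly three usable
#' points the system is solved exactly. Entries at the whole-particle match
#' point are excluded with a warning. A positive `alpha_s` means the denser
#' phase lies toward the periphery (Rg grows as the mean contrast falls);
#' `beta_s > 0` indicates a displacement of the scattering-density centre
#' from the centre of mass.
#'
#' @param series a [contrast_series()].
#' @param constrain_beta force `beta_s = 0` (quadratic reduced to linear).
#' @return Object of class `stuhrmann_fit` with `rc`, `alpha_s`, `beta_s`,
#'   `covariance`, `n_points`, plus the restricted (`beta = 0`) fit and an
#'   F-test comparing the two when the full fit was requested.
#' @export
stuhrmann_fit <- function(series, constrain_beta = FALSE) {
  stopifnot(inherits(series, "contrast_series"))
  xs <- c(); ys <- c(); ws <- c()
  for (e in series$entries) {
    if (is.null(e$guinier)) next
    dbar <- mean_contrast(e$condition, series$volumes)
    if (isTRUE(attr(dbar, "match_point"))) {
      warning("entry at the whole-particle match point excluded from fit")
      next
    }
    xs <- c(xs, 1 / as.numeric(dbar))
    ys <- c(ys, e$guinier$rg^2)
    se <- e$guinier$rg_se
    ws <- c(ws, if (is.finite(se) && se > 0) 1 / (2 * e$guinier$rg * se)^2 else NA)
  }
  if (length(xs) < 3L) stop("fit error: fewer than 3 usable contrast points")
  if (anyNA(ws)) ws <- rep(1, length(xs))
  solve_wls <- function(X) {
    W <- diag(ws, nrow = length(ws))
    XtWX <- t(X) %*% W %*% X
    cf <- unname(solve(XtWX, t(X) %*% W %*% ys))
    resid <- ys - X %*% cf
    dof <- length(ys) - ncol(X)
    s2 <- if (dof > 0) sum(ws * resid^2) / dof else NA_real_
    list(coef = drop(cf), cov = if (is.na(s2)) solve(XtWX) else s2 * solve(XtWX),
         rss = sum(ws * resid^2), dof = dof)
  }
  Xfull <- cbind(1, xs, -xs^2)
  Xlin <- cbind(1, xs)
  lin <- solve_wls(Xlin)
  restricted <- list(rc = sqrt(max(0, lin$coef[1])), alpha_s = lin$coef[2],
                     beta_s = 0)
  if (constrain_beta) {
    cov3 <- matrix(0, 3, 3); cov3[1:2, 1:2] <- lin$cov
    out <- list(rc = restricted$rc, alpha_s = restricted$alpha_s, beta_s = 0,
                covariance = cov3, n_points = length(xs),
                restricted = restricted, f_test = NULL)
  } else {
    full <- solve_wls(Xfull)
    f_test <- if (full$dof > 0 && full$rss > 0) {
      Fstat <- (lin$rss - full$rss) / (full$rss / full$dof)
      list(F = Fstat, p = stats::pf(Fstat, 1, full$dof, lower.tail = FALSE))
    } else NULL
    out <- list(rc = sqrt(max(0, full$coef[1])), alpha_s = full$coef[2],
                beta_s = full$coef[3], covariance = full$cov,
                n_points = length(xs), restricted = restricted,
                f_test = f_test)
  }
  out$x <- xs; out$rg2 <- ys
  structure(out, class = "stuhrmann_fit")
}

#' @export
print.stuhrmann_fit <- function(x, ...) {
  cat(sprintf(
    "Stuhrmann fit (%d pts): Rc %.2f A, alpha %.4g, beta %.4g\n",
    x$n_points, x$rc, x$alpha_s, x$beta_s))
  if (!is.null(x$f_test))
    cat(sprintf("  beta=0 restricted: Rc %.2f, alpha %.4g (F %.2f, p %.3f)\n",
                x$restricted$rc, x$restricted$alpha_s, x$f_test$F, x$f_test$p))
  invisible(x)
}

#' Predict Rg at a given mean contrast
#'
#' \eqn{R_g = \sqrt{R_c^2 + \alpha/\bar{\Delta\rho} -
#' \beta/\bar{\Delta\rho}^2}}.
#'
#' @param fit a [stuhrmann_fit()].
#' @param delta_rho_bar mean contrast (nonzero).
#' @return Predicted Rg in \eqn{\mathrm{\AA}}.
#' @export
predict_rg <- function(fit, delta_rho_bar) {
  stopifnot(inherits(fit, "stuhrmann_fit"))
  if (any(delta_rho_bar == 0)) stop("mean contrast must be nonzero")
  x <- 1 / delta_rho_bar
  rg2 <- fit$rc^2 + fit$alpha_s * x - fit$beta_s * x^2
  if (any(rg2 <= 0))
    stop("domain error: negative Rg^2 predicted (extrapolation outside validity)")
  sqrt(rg2)
}
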