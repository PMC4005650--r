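# Ab initio two-phase shape restoration: phases {solvent, protein, nucleic}
# are assigned to beads on an HCP search grid by simulated annealing against
# one or more contrast profiles, and replicate reconstructions are compared
# (NSD), aligned, averaged and filtered.

#' Annealing configuration
#'
#' @param search_diameter diameter of the spherical search volume
#'   (\eqn{\mathrm{\AA}}); must cover the target's Dmax.
#' @param bead_radius grid bead radius (\eqn{\mathrm{\AA}}); default
#'   `search_diameter/30`.
#' @param t_initial initial temperature in score units, or `NULL` to set it
#'   from the spread of 100 random-move score changes.
#' @param cooling_factor multiplicative cooling per temperature level.
#' @param moves_per_temperature moves per level; default 10 x bead count
#'   (resolved at run time when `NULL`).
#' @param t_min_factor stop when T falls below `t_initial * t_min_factor`.
#' @param weights penalty weights: `looseness`, `disconnect`, `phase_volume`.
#'   Defaults were calibrated on ground-truth phantom recovery: the
#'   per-profile scale factors make bead-level porosity an almost flat
#'   direction of the chi-square landscape, so the volume term must act as a
#'   near-constraint (as multi-phase practice treats the phase volumes) for
#'   annealing to reach compact, correct-volume solutions.
#' @param expected_volumes numeric(2), target protein and nucleic phase
#'   volumes (\eqn{\mathrm{\AA}^3}).
#' @param seed integer RNG seed.
#' @param q_max_fit fit only data below this q (low-q regime; the bead model
#'   carries no internal structure).
#' @return Object of class `anneal_config`.
#' @export
anneal_config <- function(search_diameter, bead_radius = search_diameter / 30,
                          t_initial = NULL, cooling_factor = 0.95,
                          moves_per_temperature = NULL, t_min_factor = 1e-4,
                          weights = c(looseness = 2, disconnect = 5,
                                      phase_volume = 30),
                          expected_volumes, seed = 1L, q_max_fit = 0.15) {
  if (cooling_factor <= 0 || cooling_factor >= 1)
    stop("cooling_factor must lie in (0,1)")
  if (any(weights < 0)) stop("penalty weights must be >= 0")
  if (length(expected_volumes) != 2L || any(expected_volumes <= 0))
    stop("expected_volumes must be two positive volumes (protein, nucleic)")
  structure(list(search_diameter = search_diameter, bead_radius = bead_radius,
                 t_initial = t_initial, cooling_factor = cooling_factor,
                 moves_per_temperature = moves_per_temperature,
                 t_min_factor = t_min_factor,
                 weights = c(looseness = unname(weights[1]),
                             disconnect = unname(weights[2]),
                             phase_volume = unname(weights[3])),
                 expected_volumes = c(protein = unname(expected_volumes[1]),
                                      nucleic = unname(expected_volumes[2])),
                 seed = as.integer(seed), q_max_fit = q_max_fit),
            class = "anneal_config")
}

#' Initialize the search grid
#'
#' Hexagonal-close-packed beads filling a sphere of `search_diameter`, with
#' phases assigned at random (seeded) in proportion to the expected phase
#' volumes, remainder solvent.
#'
#' @param search_diameter search sphere diameter (\eqn{\mathrm{\AA}}).
#' @param bead_radius bead radius (\eqn{\mathrm{\AA}}); the lattice spacing is
#'   twice this. `search_diameter/bead_radius` must be at least 12.
#' @param expected_volumes numeric(2) phase volumes (\eqn{\mathrm{\AA}^3});
#'   when `NULL` all beads start as solvent.
#' @param seed RNG seed for the random initial assignment.
#' @return A [bead_model()].
#' @export
init_grid <- function(search_diameter, bead_radius,
                      expected_volumes = NULL, seed = 1L) {
  if (search_diameter / bead_radius < 12)
    stop("resolution error: search_diameter/bead_radius must be >= 12")
  a <- 2 * bead_radius
  pts <- hcp_lattice(search_diameter / 2 + a, a)
  keep <- rowSums(pts^2) <= (search_diameter / 2)^2
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  phases <- rep("solvent", n)
  if (!is.null(expected_volumes)) {
    vc <- a^3 / sqrt(2)
    np <- min(n, round(expected_volumes[1] / vc))
    nn <- min(n - np, round(expected_volumes[2] / vc))
    phases <- withr_seed(seed, {
      idx <- sample.int(n, np + nn)
      ph <- rep("solvent", n)
      ph[idx[seq_len(np)]] <- "protein"
      ph[idx[np + seq_len(nn)]] <- "nucleic"
      ph
    })
  }
  bead_model(pts, bead_radius, phases,
             lattice = list(spacing = a, packing = "hcp"))
}

# map an R-side series + config to the flat arguments of the C++ engine
.recon_args <- function(model, series, config) {
  q_ref <- NULL
  for (e in series$entries) {
    qf <- e$profile$q[e$profile$q <= config$q_max_fit]
    if (is.null(q_ref)) q_ref <- qf
    else if (length(qf) != length(q_ref) || any(abs(qf - q_ref) > 1e-9))
      stop("all profiles must share one q grid below q_max_fit")
  }
  if (length(q_ref) < 5L) stop("too few points below q_max_fit")
  ncond <- length(series$entries)
  Iobs <- matrix(0, length(q_ref), ncond)
  Sig <- matrix(0, length(q_ref), ncond)
  contrasts <- matrix(0, ncond, 3)
  for (i in seq_len(ncond)) {
    e <- series$entries[[i]]
    sel <- e$profile$q <= config$q_max_fit
    Iobs[, i] <- e$profile$intensity[sel]
    Sig[, i] <- profile_sigma(e$profile)[sel]
    contrasts[i, ] <- phase_contrasts(e$condition)
  }
  vc <- cell_volume(model)
  nexp <- config$expected_volumes / vc   # expected bead counts
  list(q = q_ref, Iobs = Iobs, Sig = Sig, contrasts = contrasts,
       nexp = nexp, vbead = bead_volume(model))
}

#' Score a bead model against a contrast series
#'
#' Total score = sum of per-profile reduced \eqn{\chi^2} (Debye intensity with
#' an analytic per-profile scale factor) plus weighted penalties: looseness
#' (fraction of non-solvent beads with fewer than 6 non-solvent lattice
#' neighbours), disconnection (connected components beyond one per phase) and
#' phase-volume deviation.
#'
#' @param model a [bead_model()] on an HCP grid.
#' @param series a [contrast_series()].
#' @param config an [anneal_config()].
#' @return List with `total`, `chi` (per profile), `penalties`.
#' @export
model_score <- function(model, series, config) {
  stopifnot(inherits(model, "bead_model"), inherits(series, "contrast_series"),
            inherits(config, "anneal_config"))
  arg <- .recon_args(model, series, config)
  ph <- match(model$phases, .PHASES) - 1L
  if (all(ph == 0L))
    return(list(total = Inf, chi = rep(Inf, ncol(arg$Iobs)),
                penalties = list(looseness = NA, disconnect = NA,
                                 phase_volume = NA)))
  cpp_model_score(model$centers, ph, arg$vbead, arg$contrasts, arg$q,
                  arg$Iobs, arg$Sig, model$bead_radius,
                  model$bead_radius / 2, model$lattice$spacing,
                  config$weights[["looseness"]],
                  config$weights[["disconnect"]],
                  config$weights[["phase_volume"]], arg$nexp)
}

#' Multi-phase simulated annealing reconstruction
#'
#' Metropolis annealing over single-bead phase-change moves (uniform random
#' bead, uniform random new phase): downhill moves are always accepted, uphill
#' moves with probability \eqn{\exp(-\Delta/T)}; T is multiplied by
#' `cooling_factor` after each level of `moves_per_temperature` moves; the
#' run stops when T falls below `t_initial * t_min_factor` or when an entire
#' level accepts nothing. The score is recomputed exactly at every level to
#' bound incremental drift. Fully reproducible from `config$seed`.
#'
#' @param series a [contrast_series()].
#' @param config an [anneal_config()].
#' @param greedy zero-temperature mode: accept only downhill moves.
#' @return Object of class `recon_result`: `model`, `chi_per_profile`,
#'   `penalty_terms`, `accepted_moves`, `seed`, `divergence`, `trace`.
#' @export
anneal <- function(series, config, greedy = FALSE) {
  stopifnot(inherits(series, "contrast_series"),
            inherits(config, "anneal_config"))
  grid <- init_grid(config$search_diameter, config$bead_radius,
                    config$expected_volumes, seed = config$seed)
  arg <- .recon_args(grid, series, config)
  snr <- apply(abs(arg$Iobs) / arg$Sig, 2, max)
  if (all(snr < 5))
    warning("annealing divergence risk: all profiles are consistent with ",
            "zero signal (whole-particle match point?); no shape information")
  ph0 <- match(grid$phases, .PHASES) - 1L
  mpt <- config$moves_per_temperature %||% (10L * nrow(grid$centers))
  res <- withr_seed(config$seed,
    cpp_anneal(grid$centers, ph0, arg$vbead, arg$contrasts, arg$q, arg$Iobs,
               arg$Sig, grid$bead_radius, grid$bead_radius / 2,
               grid$lattice$spacing,
               config$weights[["looseness"]], config$weights[["disconnect"]],
               config$weights[["phase_volume"]], arg$nexp,
               config$t_initial %||% -1, config$cooling_factor, mpt,
               config$t_min_factor, greedy, 2000L))
  if (res$divergence)
    warning("annealing divergence: no accepted moves at high chi ",
            "(profiles may carry no shape information)")
  model <- bead_model(grid$centers, grid$bead_radius,
                      .PHASES[res$phases + 1L], grid$lattice)
  structure(list(model = model, chi_per_profile = res$chi,
                 penalty_terms = list(total = res$total),
                 accepted_moves = res$accepted, levels = res$levels,
                 t_initial = res$t_initial, trace = res$trace,
                 seed = config$seed, divergence = res$divergence),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf(
    "recon_result: chi %s after %d levels (%g accepted moves, seed %d)\n",
    paste(sprintf("%.2f", x$chi_per_profile), collapse = "/"), x$levels,
    x$accepted_moves, x$seed))
  invisible(x)
}

#' Normalized spatial discrepancy between two bead models
#'
#' \deqn{NSD^2 = \frac12\left[\frac{1}{N_a d_b^2}\sum_i \min_j \|x_i-y_j\|^2
#'   + \frac{1}{N_b d_a^2}\sum_j \min_i \|y_j-x_i\|^2\right]}
#' computed over the non-solvent beads, with d the lattice spacing of each
#' model. 0 for identical models, around 1 or below for similar ones. The
#' phase-blind value is returned; per-phase values are attached as an
#' attribute when both models carry both material phases.
#'
#' @param model_a,model_b bead models.
#' @return Dimensionless NSD (attribute `per_phase` when available).
#' @export
nsd <- function(model_a, model_b) {
  A <- nonsolvent(model_a); B <- nonsolvent(model_b)
  val <- .nsd_xyz(A$centers, B$centers,
                  .lattice_spacing(A), .lattice_spacing(B))
  pp <- c(protein = NA_real_, nucleic = NA_real_)
  for (phase in c("protein", "nucleic")) {
    sa <- A$phases == phase; sb <- B$phases == phase
    if (any(sa) && any(sb))
      pp[phase] <- .nsd_xyz(A$centers[sa, , drop = FALSE],
                            B$centers[sb, , drop = FALSE],
                            .lattice_spacing(A), .lattice_spacing(B))
  }
  attr(val, "per_phase") <- pp
  val
}

.lattice_spacing <- function(model) {
  if (identical(model$lattice, "free")) {
    if (nrow(model$centers) < 2L) return(2 * model$bead_radius)
    cpp_min_pair_dist(model$centers)
  } else model$lattice$spacing
}

.nsd_xyz <- function(A, B, da, db) {
  sab <- cpp_nsd_sum(A, B) / (nrow(A) * db^2)
  sba <- cpp_nsd_sum(B, A) / (nrow(B) * da^2)
  sqrt(0.5 * (sab + sba))
}

#' Align bead models for averaging
#'
#' Each model is translated to its (non-solvent) centroid and rotated to its
#' principal axes; of the four proper axis-flip combinations (optionally also
#' their mirror images) the one minimizing the NSD against the first model is
#' kept. Deterministic. A near-degenerate inertia tensor triggers an
#' ambiguous-alignment warning and the identity rotation is kept; a
#' mirror-image pair with mirror search disabled retains its chirality and a
#' note is attached.
#'
#' @param models list of bead models (>= 2).
#' @param mirror also search improper (mirror) transforms; off by default
#'   because SAXS cannot determine chirality.
#' @return List of aligned bead models (attribute `nsd_to_reference`).
#' @export
align <- function(models, mirror = FALSE) {
  stopifnot(length(models) >= 2L)
  canon <- function(model) {
    ns <- nonsolvent(model)
    ctr <- colMeans(ns$centers)
    X <- sweep(model$centers, 2, ctr)
    Xns <- sweep(ns$centers, 2, ctr)
    C <- crossprod(Xns) / nrow(Xns)
    ev <- eigen(C, symmetric = TRUE)
    if (min(abs(diff(ev$values))) < 2.5e-2 * max(ev$values)) {
      warning("ambiguous alignment: near-degenerate inertia tensor; identity kept")
      return(list(X = X, R = diag(3)))
    }
    R <- ev$vectors
    if (det(R) < 0) R[, 3] <- -R[, 3]
    list(X = X %*% R, R = R)
  }
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  if (mirror) flips <- c(flips, lapply(flips, function(f) -f))
  ref <- canon(models[[1]])
  out <- vector("list", length(models))
  m1 <- models[[1]]; m1$centers <- ref$X
  out[[1]] <- m1
  refns <- nonsolvent(m1)
  nsds <- c(0, numeric(length(models) - 1))
  for (i in seq_along(models)[-1]) {
    ci <- canon(models[[i]])
    best <- NULL
    for (f in flips) {
      Xf <- sweep(ci$X, 2, f, "*")
      mi <- models[[i]]; mi$centers <- Xf
      v <- nsd(refns, nonsolvent(mi))
      if (is.null(best) || v < best$v) best <- list(v = v, X = Xf)
    }
    mi <- models[[i]]; mi$centers <- best$X
    out[[i]] <- mi
    nsds[i] <- best$v
  }
  if (!mirror)
    attr(out, "note") <- "mirror search disabled; enantiomorph not resolved"
  attr(out, "nsd_to_reference") <- nsds
  out
}

#' Average and filter aligned reconstructions
#'
#' Beads of each aligned model are snapped to the nearest site of the first
#' model's grid (tolerance half a lattice spacing; beads further away still
#' snap to their nearest site). Per-site per-phase occupancies are
#' accumulated, and the filtered model keeps each phase's most-occupied sites
#' until the phase's expected volume is reached, tie-broken by distance to
#' the phase occupancy centroid. Pairwise NSD statistics over the ensemble
#' are reported.
#'
#' @param models list of pre-aligned bead models sharing one grid geometry.
#' @param occupancy_fraction minimum occupancy fraction a site needs to be
#'   eligible for the filtered model (default 0.2).
#' @param expected_volumes numeric(2) target phase volumes
#'   (\eqn{\mathrm{\AA}^3}); defaults to the mean per-phase volume across
#'   the ensemble.
#' @return Object of class `average_model`: `reference`, `occupancy`,
#'   `filtered`, `nsd_matrix`, `nsd_mean_sd`.
#' @export
average_filter <- function(models, occupancy_fraction = 0.2,
                           expected_volumes = NULL) {
  stopifnot(length(models) >= 2L)
  sp <- vapply(models, .lattice_spacing, 1)
  if (max(sp) - min(sp) > 1e-6 * mean(sp))
    stop("grid error: inconsistent lattice spacings across models")
  ref <- models[[1]]
  grid <- ref$centers
  nsite <- nrow(grid)
  vc <- cell_volume(ref)
  occ <- matrix(0, nsite, 2, dimnames = list(NULL, c("protein", "nucleic")))
  nm <- length(models)
  for (m in models) {
    ns <- nonsolvent(m)
    # nearest reference site for every bead
    idx <- integer(nrow(ns$centers))
    for (i in seq_len(nrow(ns$centers))) {
      d2 <- colSums((t(grid) - ns$centers[i, ])^2)
      idx[i] <- which.min(d2)
    }
    for (phase in c("protein", "nucleic")) {
      sel <- ns$phases == phase
      if (any(sel)) {
        tab <- table(idx[sel])
        occ[as.integer(names(tab)), phase] <-
          occ[as.integer(names(tab)), phase] + pmin(as.integer(tab), 1L)
      }
    }
  }
  occ <- occ / nm
  if (is.null(expected_volumes)) {
    nb <- vapply(models, function(m)
      c(sum(m$phases == "protein"), sum(m$phases == "nucleic")), numeric(2))
    expected_volumes <- rowMeans(nb) * vc
  }
  phases <- rep("solvent", nsite)
  for (phase in c("protein", "nucleic")) {
    target <- round(expected_volumes[[match(phase, c("protein", "nucleic"))]] / vc)
    elig <- which(occ[, phase] >= occupancy_fraction & phases == "solvent")
    if (length(elig) == 0L) next
    ctr <- colSums(grid[elig, , drop = FALSE] * occ[elig, phase]) /
      sum(occ[elig, phase])
    d2 <- colSums((t(grid[elig, , drop = FALSE]) - ctr)^2)
    ord <- elig[order(-occ[elig, phase], d2)]
    phases[head(ord, target)] <- phase
  }
  keep <- phases != "solvent"
  filtered <- bead_model(grid[keep, , drop = FALSE], ref$bead_radius,
                         phases[keep], ref$lattice,
                         occupancy = ifelse(phases[keep] == "protein",
                                            occ[keep, "protein"],
                                            occ[keep, "nucleic"]))
  M <- matrix(0, nm, nm)
  for (i in seq_len(nm - 1)) for (j in (i + 1):nm) {
    M[i, j] <- M[j, i] <- as.numeric(nsd(models[[i]], models[[j]]))
  }
  pair <- M[upper.tri(M)]
  structure(list(reference = ref, occupancy = occ, filtered = filtered,
                 nsd_matrix = M,
                 nsd_mean_sd = c(mean = mean(pair), sd = sd(pair))),
            class = "average_model")
}

#' @export
print.average_model <- function(x, ...) {
  cat(sprintf(
    "average_model: %d filtered beads, ensemble NSD %.2f +/- %.2f\n",
    nrow(x$filtered$centers), x$nsd_mean_sd[["mean"]],
    if (is.na(x$nsd_mean_sd[["sd"]])) 0 else x$nsd_mean_sd[["sd"]]))
  invisible(x)
}
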