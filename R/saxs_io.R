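#' @useDynLib rnpsaxs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm optimize quantile rnorm runif sd setNames uniroot
#'   var weighted.mean
#' @importFrom utils head tail
NULL

# Allowed bead phases. "solvent" marks unoccupied search-grid sites during
# reconstruction; phantom and filtered models normally carry only the two
# material phases.
.PHASES <- c("solvent", "protein", "nucleic")

# default phase <-> PDB residue-name map
.DEFAULT_RESMAP <- c(solvent = "SOL", protein = "PRO", nucleic = "RNA")

#' One-dimensional scattering profile
#'
#' Container for a buffer-subtracted SAXS curve: momentum transfer `q`
#' (\eqn{\mathrm{\AA}^{-1}}, strictly increasing, positive), intensity in
#' arbitrary units and optional 1-sigma uncertainties.
#'
#' @param q numeric vector of momentum transfer values (\eqn{\mathrm{\AA}^{-1}}).
#' @param intensity numeric vector of scattered intensities (arbitrary units).
#' @param sigma optional numeric vector of 1-sigma uncertainties; `NULL` if the
#'   curve carries no error estimates.
#' @param label free-text label.
#' @param condition optional [contrast_condition()] the curve was measured at.
#' @return An object of class `scattering_profile`.
#' @export
scattering_profile <- function(q, intensity, sigma = NULL, label = "",
                               condition = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("q and intensity must have equal length")
  if (length(q) < 8L)
    stop("a scattering profile needs at least 8 points")
  if (any(q <= 0)) stop("all q values must be positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length mismatch")
    if (any(sigma <= 0)) stop("all sigma values must be positive")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 label = as.character(label), condition = condition),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("scattering_profile '%s': %d points, q %.4g-%.4g A^-1, sigma %s\n",
              x$label, length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "absent" else "present"))
  invisible(x)
}

# sigma fallback for curves read without an error column: Poisson-like
# k*sqrt(max(I,0)+c). Used wherever a chi^2 needs weights and none exist.
placeholder_sigma <- function(intensity, k = 1, c = 0) {
  k * sqrt(pmax(intensity, 0) + c)
}

# sigma to use in weighted fits: real if present, else placeholder.
# Zero/non-finite entries (e.g. at high-q oscillation troughs) are floored at
# the smallest positive value so weights stay finite.
profile_sigma <- function(profile, k = 1, c = 0) {
  s <- if (!is.null(profile$sigma)) profile$sigma
       else placeholder_sigma(profile$intensity, k, c)
  bad <- !is.finite(s) | s <= 0
  if (any(bad)) s[bad] <- if (any(!bad)) min(s[!bad]) else 1
  s
}

#' Bead model
#'
#' Set of equal-radius beads on (or off) a lattice with per-bead phase labels.
#' The universal shape representation used for phantoms, reconstructions and
#' averaged envelopes.
#'
#' @param centers numeric matrix (n x 3) of bead centres (\eqn{\mathrm{\AA}}).
#' @param bead_radius positive bead radius (\eqn{\mathrm{\AA}}).
#' @param phases character vector of per-bead phase labels, each one of
#'   `"solvent"`, `"protein"`, `"nucleic"`.
#' @param lattice list with elements `spacing` and `packing` describing the
#'   generating grid, or the string `"free"`.
#' @param occupancy optional per-bead occupancy (used by averaged models).
#' @return An object of class `bead_model`.
#' @export
bead_model <- function(centers, bead_radius, phases,
                       lattice = list(spacing = 2 * bead_radius, packing = "hcp"),
                       occupancy = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L) stop("centers must be an n x 3 matrix")
  storage.mode(centers) <- "double"
  n <- nrow(centers)
  if (n < 1L) stop("a bead model needs at least one bead")
  if (!is.numeric(bead_radius) || bead_radius <= 0)
    stop("bead_radius must be positive")
  phases <- as.character(phases)
  if (length(phases) == 1L) phases <- rep(phases, n)
  if (length(phases) != n) stop("phases length mismatch")
  bad <- setdiff(unique(phases), .PHASES)
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  if (!identical(lattice, "free")) {
    sp <- lattice$spacing
    if (n > 1L && is.numeric(sp)) {
      dmin <- cpp_min_pair_dist(centers)
      if (dmin < sp * (1 - 1e-3))  # tolerance covers PDB 3-decimal rounding
        stop(sprintf("beads closer (%.3f A) than lattice spacing (%.3f A)",
                     dmin, sp))
    }
  }
  structure(list(centers = centers, bead_radius = as.numeric(bead_radius),
                 phases = phases, lattice = lattice, occupancy = occupancy),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  tab <- table(factor(x$phases, levels = .PHASES))
  cat(sprintf("bead_model: %d beads (radius %.2f A; %s)\n", nrow(x$centers),
              x$bead_radius,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# volume of one bead (sphere) and of one lattice cell (space-filling share)
bead_volume <- function(model) (4 / 3) * pi * model$bead_radius^3
cell_volume <- function(model) {
  sp <- if (identical(model$lattice, "free")) 2 * model$bead_radius
        else model$lattice$spacing
  sp^3 / sqrt(2)  # HCP: one site per a^3/sqrt(2)
}

# drop solvent beads, keep everything else
nonsolvent <- function(model) {
  keep <- model$phases != "solvent"
  if (!any(keep)) stop("model has no non-solvent beads")
  bead_model(model$centers[keep, , drop = FALSE], model$bead_radius,
             model$phases[keep], model$lattice,
             occupancy = model$occupancy[keep])
}

#' Read a scattering profile from 3-column text
#'
#' Parses whitespace-delimited `q I [sigma]` files. Lines whose first token is
#' not numeric are treated as headers/comments and skipped. Two-column files
#' are read with `sigma` absent (a warning is emitted); chi-square computations
#' then fall back to a documented Poisson-like placeholder.
#'
#' @param path file path.
#' @param q_unit `"A^-1"` (default) or `"nm^-1"`; nm^-1 input is divided by 10.
#' @param label profile label; defaults to the file name.
#' @return A [scattering_profile()].
#' @export
read_profile <- function(path, q_unit = c("A^-1", "nm^-1"), label = NULL) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("cannot read profile: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) < 2L) next
    vals <- suppressWarnings(as.numeric(toks))
    if (is.na(vals[1]) || is.na(vals[2])) next  # header / comment
    rows[[length(rows) + 1L]] <- vals[seq_len(min(3L, length(vals)))]
  }
  if (length(rows) < 8L)
    stop("profile format error: fewer than 8 parseable data rows in ", path)
  ncols <- vapply(rows, length, 1L)
  has_sigma <- all(ncols >= 3L)
  m <- do.call(rbind, lapply(rows, function(r) c(r, NA_real_)[1:3]))
  q <- m[, 1]; I <- m[, 2]; s <- if (has_sigma) m[, 3] else NULL
  if (q_unit == "nm^-1") q <- q / 10
  if (any(q <= 0)) stop("profile format error: non-positive q in ", path)
  if (any(diff(q) <= 0)) stop("profile format error: q not strictly increasing in ", path)
  if (!has_sigma)
    warning("no sigma column in ", basename(path),
            "; uncertainties set absent (placeholder used in fits)")
  scattering_profile(q, I, s, label = label %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scattering profile as 3-column text
#'
#' Writes `# q I sigma` plus data rows in scientific notation (7 significant
#' digits). A profile without uncertainties gets the Poisson-like placeholder
#' sigma `k*sqrt(max(I,0)+c)` and the header is flagged accordingly.
#'
#' @param profile a [scattering_profile()].
#' @param path output path.
#' @param sigma_k,sigma_c placeholder-sigma constants used when the profile
#'   carries no uncertainties.
#' @export
write_profile <- function(profile, path, sigma_k = 1, sigma_c = 0) {
  if (!inherits(profile, "scattering_profile")) stop("not a scattering_profile")
  flagged <- is.null(profile$sigma)
  s <- profile_sigma(profile, sigma_k, sigma_c)
  hdr <- if (flagged)
    sprintf("# q I sigma (sigma is placeholder %g*sqrt(max(I,0)+%g))", sigma_k, sigma_c)
  else "# q I sigma"
  body <- sprintf("%.7e %.7e %.7e", profile$q, profile$intensity, s)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a bead model from a PDB-dialect file
#'
#' One ATOM/HETATM record per bead; the residue name encodes the phase via
#' `resmap`; `REMARK 265 BEAD RADIUS` / `LATTICE SPACING` lines carry the
#' model metadata. A missing radius REMARK is tolerated: the radius is then
#' inferred as half the minimum centre-centre distance (with a warning).
#'
#' @param path file path.
#' @param resmap named character vector mapping phase name to residue name.
#' @return A [bead_model()].
#' @export
read_bead_model <- function(path, resmap = .DEFAULT_RESMAP) {
  if (!file.exists(path)) stop("cannot read bead model: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0L) stop("bead model format error: no ATOM/HETATM records in ", path)
  resn <- trimws(substr(rec, 18, 20))
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  occ <- suppressWarnings(as.numeric(substr(rec, 55, 60)))
  inv <- setNames(names(resmap), resmap)
  if (any(!resn %in% names(inv))) {
    off <- setdiff(unique(resn), names(inv))
    stop("bead model format error: unmapped residue name(s): ",
         paste(off, collapse = ", "))
  }
  phases <- unname(inv[resn])
  rad <- .remark265(lines, "BEAD RADIUS")
  spac <- .remark265(lines, "LATTICE SPACING")
  centers <- cbind(x, y, z)
  if (is.na(rad)) {
    if (nrow(centers) < 2L)
      stop("bead model format error: no radius REMARK and a single bead")
    rad <- cpp_min_pair_dist(centers) / 2
    warning("no REMARK 265 BEAD RADIUS; inferred radius ", signif(rad, 4),
            " A from minimum centre spacing")
  }
  lattice <- if (is.na(spac)) "free" else list(spacing = spac, packing = "hcp")
  bead_model(centers, rad, phases, lattice,
             occupancy = if (all(is.finite(occ))) occ else NULL)
}

.remark265 <- function(lines, key) {
  pat <- paste0("^REMARK 265 ", key, "\\s*:?\\s*([0-9.eE+-]+)")
  hit <- regmatches(lines, regexec(pat, lines))
  hit <- Filter(function(h) length(h) == 2L, hit)
  if (length(hit) == 0L) return(NA_real_)
  as.numeric(hit[[1]][2])
}

#' Write a bead model as a PDB-dialect file
#'
#' Fixed-width ATOM records, one per bead; phases are mapped to residue names
#' and to distinct chain identifiers (A = protein, B = nucleic, S = solvent)
#' so standard viewers colour them apart. Bead radius and lattice spacing go
#' into REMARK 265 lines; per-bead occupancy (averaged models) is written in
#' the occupancy column.
#'
#' @param model a [bead_model()].
#' @param path output path.
#' @param resmap named character vector mapping phase name to residue name.
#' @export
write_bead_model <- function(model, path, resmap = .DEFAULT_RESMAP) {
  if (!inherits(model, "bead_model")) stop("not a bead_model")
  xyz <- model$centers
  if (any(abs(xyz) >= 10000))
    stop("coordinates exceed the PDB fixed-width range (|x| >= 10000 A)")
  chain <- c(solvent = "S", protein = "A", nucleic = "B")[model$phases]
  resn <- resmap[model$phases]
  occ <- model$occupancy %||% rep(1, nrow(xyz))
  sp <- if (identical(model$lattice, "free")) 2 * model$bead_radius
        else model$lattice$spacing
  hdr <- c(sprintf("REMARK 265 BEAD RADIUS : %.4f", model$bead_radius),
           sprintf("REMARK 265 LATTICE SPACING : %.4f", sp))
  i <- seq_len(nrow(xyz))
  rec <- sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                 (i - 1L) %% 99999L + 1L, resn, chain, (i - 1L) %% 9999L + 1L,
                 xyz[, 1], xyz[, 2], xyz[, 3], occ, 0)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(hdr, rec, "END"), con)
  invisible(path)
}
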