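# Solvent-accessible surface area (Shrake-Rupley point quadrature).
#
# The probe center is rolled over the van der Waals surface: each atom is
# expanded by the probe radius, covered with a deterministic golden-spiral
# point set, and the fraction of points outside every neighbor's expanded
# sphere gives the exposed fraction of 4*pi*(r+probe)^2.

#' Default van der Waals radii (Angstrom)
#'
#' Protein-atom radii in the NACCESS style (C 1.87, N 1.65, O 1.40, S 1.85),
#' keyed by element; fully overridable through [sasa_params()].
#'
#' @format Named numeric vector.
#' @export
DEFAULT_VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
                       SE = 1.90)

#' SASA calculation parameters
#'
#' @param probe_radius Probe radius in Angstrom; 1.4 corresponds to a water
#'   molecule.
#' @param n_sphere_points Number of quadrature points per atom; the analytic
#'   single-sphere area is reproduced within 2% at the default 960.
#' @param radii Named vector of van der Waals radii by element.
#' @return A list of class `bp_sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960L,
                        radii = DEFAULT_VDW_RADII) {
  stopifnot(probe_radius > 0, n_sphere_points >= 60, all(radii > 0))
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii = radii),
            class = "bp_sasa_params")
}

# Deterministic, seed-free quasi-uniform points on the unit sphere
# (golden-spiral layout), so SASA values are reproducible bit-for-bit.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  theta <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Per-atom Shrake-Rupley areas for bare coordinates
#'
#' Low-level engine used by [compute_sasa()]; exposed for testing geometric
#' properties directly (analytic spheres, symmetric pairs, caged atoms).
#'
#' @param coords n x 3 matrix of atom centers (Angstrom).
#' @param elements Character vector of element symbols, length n.
#' @param params A [sasa_params()] object.
#' @return Numeric vector of per-atom areas (Angstrom^2).
#' @export
sasa_atom_areas <- function(coords, elements, params = sasa_params()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(elements) == n, all(is.finite(coords)))
  unknown <- setdiff(unique(elements), names(params$radii))
  if (length(unknown))
    stop("no van der Waals radius configured for element(s): ",
         paste(unknown, collapse = ", "))
  r <- unname(params$radii[elements]) + params$probe_radius
  pts <- golden_spiral_points(params$n_sphere_points)
  areas <- numeric(n)
  if (n == 1) return(4 * pi * r^2)
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (!length(nb)) {
      areas[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i]
    p <- sweep(p, 2, coords[i, ], "+")
    exposed <- rep(TRUE, nrow(p))
    for (j in nb) {
      dx <- p[, 1] - coords[j, 1]
      dy <- p[, 2] - coords[j, 2]
      dz <- p[, 3] - coords[j, 3]
      exposed <- exposed & (dx * dx + dy * dy + dz * dz >= r[j]^2)
      if (!any(exposed)) break
    }
    areas[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  areas
}

#' Compute the per-residue surface table of a structure
#'
#' Runs the Shrake-Rupley engine on the polymer atoms only — ligands and
#' waters are removed before the calculation, as for a surface definition
#' that asks how exposed each residue is on the unliganded protein. Per-atom
#' areas are summed into the residue's side-chain (`abs_side`) and backbone
#' (`abs_main`) absolute areas using [classify_atom_role()], so glycine's CA
#' area counts toward `abs_side`. The effective areas `eff_side`/`eff_main`
#' equal the absolute ones except for glycine, where the larger of the two is
#' used for both classes (the glycine max rule).
#'
#' @param s A normalized `bp_structure`.
#' @param params A [sasa_params()] object.
#' @return A `bp_surface` object: list with `residues` (chain, resno, icode,
#'   resname, abs_side, abs_main, abs_total, eff_side, eff_main) and `atoms`
#'   (per-atom areas).
#' @export
compute_sasa <- function(s, params = sasa_params()) {
  stopifnot(inherits(s, "bp_structure"))
  if (!isTRUE(s$normalized))
    warning("structure '", s$structure_id, "' has not been normalized")
  a <- s$atoms[s$atoms$partition == "polymer", , drop = FALSE]
  if (!nrow(a)) stop("structure has no polymer atoms")
  a$area <- sasa_atom_areas(cbind(a$x, a$y, a$z), a$element, params)
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  first <- !duplicated(key)
  side <- tapply(a$area * (a$role == "sidechain"), key, sum)
  main <- tapply(a$area * (a$role == "backbone"), key, sum)
  ord <- key[first]
  res <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    icode = a$icode[first], resname = a$resname[first],
                    abs_side = as.numeric(side[ord]),
                    abs_main = as.numeric(main[ord]),
                    stringsAsFactors = FALSE)
  res$abs_total <- res$abs_side + res$abs_main
  gly <- res$resname == "GLY"
  res$eff_side <- res$abs_side
  res$eff_main <- res$abs_main
  res$eff_side[gly] <- pmax(res$abs_side[gly], res$abs_main[gly])
  res$eff_main[gly] <- pmax(res$abs_side[gly], res$abs_main[gly])
  structure(list(structure_id = s$structure_id, residues = res, atoms = a,
                 params = params),
            class = "bp_surface")
}

#' Select surface residues by SASA cutoff
#'
#' A residue is a "surface" residue for the side-chain class when its
#' `eff_side` is at least `cutoff` (inclusive), and for the main-chain class
#' when its `eff_main` is; the glycine max rule is already folded into the
#' effective areas. Common cutoffs are 5.0 and 0.5 Angstrom^2.
#'
#' @param surface A `bp_surface` from [compute_sasa()].
#' @param cutoff SASA cutoff in Angstrom^2 (inclusive); must be >= 0.
#' @param atom_class `"sidechain"` or `"mainchain"`.
#' @return Data frame of the qualifying residues.
#' @export
surface_residues <- function(surface, cutoff = 5.0,
                             atom_class = c("sidechain", "mainchain")) {
  atom_class <- match.arg(atom_class)
  if (cutoff < 0) stop("cutoff must be non-negative")
  res <- surface$residues
  eff <- if (atom_class == "sidechain") res$eff_side else res$eff_main
  res[eff >= cutoff, , drop = FALSE]
}
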