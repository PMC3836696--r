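# Synthetic data with known ground truth.
#
# Two generators: (a) abstract composition datasets — per-protein surface
# counts and per-site residue counts drawn from multinomials with known
# enrichment, for testing the statistics; (b) toy protein-ligand complexes in
# PDB format with enumerable contacts and burial states, for testing the
# geometry end to end. Neither pretends to physical realism; the composition
# generator bypasses geometry entirely to keep statistical tests fast.

#' Specification for a synthetic composition dataset
#'
#' Defaults echo the scale of a curated biounit corpus: every protein carries
#' at least one valid site, valid sites are about five times larger than
#' invalid ones (11.4 vs 3.6 residues on average), and there are roughly 2.3
#' valid and 1.5 invalid sites per structure. The background is a
#' surface-like, charged/polar-heavy frequency profile.
#'
#' The per-residue enrichment vectors multiply the background inside sites.
#' They are renormalized internally so that the asymptotic pooled propensity
#' equals the stored ground-truth vector exactly (see
#' [generate_composition_dataset()]).
#'
#' @param n_proteins Number of synthetic proteins.
#' @param surface_mean,surface_sd Surface residues per protein
#'   (truncated-normal, minimum 20).
#' @param valid_sites_mean Mean valid sites per protein (each protein gets
#'   `1 + Poisson(mean - 1)`, so every protein has a valid site).
#' @param invalid_sites_mean Mean invalid sites per protein (Poisson).
#' @param valid_site_size_mean,valid_site_size_sd Residues per valid site
#'   (truncated-normal, minimum 3).
#' @param invalid_site_size_mean,invalid_site_size_sd Residues per invalid
#'   site (truncated-normal, minimum 1).
#' @param background Named background frequencies over [AA3]; normalized.
#' @param enrichment_valid,enrichment_invalid Named positive multiplicative
#'   enrichment per residue (default all 1).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   spec.
#' @return A `bp_composition_spec` list.
#' @export
composition_spec <- function(n_proteins = 400,
                             surface_mean = 350, surface_sd = 60,
                             valid_sites_mean = 2.34,
                             invalid_sites_mean = 1.49,
                             valid_site_size_mean = 11.4,
                             valid_site_size_sd = 4,
                             invalid_site_size_mean = 3.6,
                             invalid_site_size_sd = 1.8,
                             background = SURFACE_BACKGROUND,
                             enrichment_valid = NULL,
                             enrichment_invalid = NULL,
                             seed = 1L) {
  background <- background[AA3]
  stopifnot(all(background > 0), n_proteins >= 1,
            valid_sites_mean >= 1, invalid_sites_mean >= 0)
  background <- background / sum(background)
  one <- stats::setNames(rep(1, 20), AA3)
  if (is.null(enrichment_valid)) enrichment_valid <- one
  if (is.null(enrichment_invalid)) enrichment_invalid <- one
  stopifnot(all(enrichment_valid > 0), all(enrichment_invalid > 0))
  structure(list(n_proteins = as.integer(n_proteins),
                 surface_mean = surface_mean, surface_sd = surface_sd,
                 valid_sites_mean = valid_sites_mean,
                 invalid_sites_mean = invalid_sites_mean,
                 valid_site_size_mean = valid_site_size_mean,
                 valid_site_size_sd = valid_site_size_sd,
                 invalid_site_size_mean = invalid_site_size_mean,
                 invalid_site_size_sd = invalid_site_size_sd,
                 background = background,
                 enrichment_valid = enrichment_valid[AA3],
                 enrichment_invalid = enrichment_invalid[AA3],
                 seed = as.integer(seed)),
            class = "bp_composition_spec")
}

# Normalize an enrichment vector k so that sum(background * k) == 1; then
# the binding-site frequency is background * k and the asymptotic pooled
# propensity equals k itself.
normalize_enrichment <- function(k, background) {
  k / sum(background * k)
}

#' Generate a synthetic composition dataset with ground truth
#'
#' Per protein, surface residue counts are multinomial draws from the
#' background profile. Per site, residue counts are multinomial draws from
#' `background * enrichment`, renormalized. The enrichment vector is itself
#' renormalized so that the true asymptotic propensity of residue i equals
#' the stored `truth$propensity_*[i]` exactly; synthetic HET codes with a
#' skewed rank-frequency profile are attached so ligand-exclusion analyses
#' can be exercised.
#'
#' @param spec A [composition_spec()].
#' @return A `bp_composition`: list with `surface_counts` (proteins x 20),
#'   `site_counts` (sites x 20), `site_info` (protein index, validity, HET
#'   code, size), and `truth` (background, normalized enrichment =
#'   asymptotic propensity per class, and the spec).
#' @export
generate_composition_dataset <- function(spec) {
  stopifnot(inherits(spec, "bp_composition_spec"))
  set.seed(spec$seed)
  P <- spec$n_proteins
  bg <- spec$background
  kv <- normalize_enrichment(spec$enrichment_valid, bg)
  ki <- normalize_enrichment(spec$enrichment_invalid, bg)
  pv <- bg * kv
  pi_ <- bg * ki

  n_surf <- pmax(20L, round(stats::rnorm(P, spec$surface_mean,
                                         spec$surface_sd)))
  surface_counts <- t(vapply(n_surf, function(n)
    as.numeric(stats::rmultinom(1, n, bg)), numeric(20)))
  colnames(surface_counts) <- AA3

  n_valid <- 1L + stats::rpois(P, max(0, spec$valid_sites_mean - 1))
  n_invalid <- stats::rpois(P, spec$invalid_sites_mean)
  protein <- c(rep(seq_len(P), n_valid), rep(seq_len(P), n_invalid))
  validity <- c(rep("valid", sum(n_valid)), rep("invalid", sum(n_invalid)))
  J <- length(protein)
  size <- integer(J)
  v <- validity == "valid"
  size[v] <- pmax(3L, round(stats::rnorm(sum(v), spec$valid_site_size_mean,
                                         spec$valid_site_size_sd)))
  size[!v] <- pmax(1L, round(stats::rnorm(sum(!v),
                                          spec$invalid_site_size_mean,
                                          spec$invalid_site_size_sd)))
  site_counts <- matrix(0, J, 20, dimnames = list(NULL, AA3))
  for (j in seq_len(J)) {
    p <- if (v[j]) pv else pi_
    site_counts[j, ] <- as.numeric(stats::rmultinom(1, size[j], p))
  }

  # Synthetic HET codes: rank-frequency skew (steeper for invalids, where a
  # few buffer-like ligands dominate real corpora).
  het_v <- sprintf("V%02d", 1:30)
  het_i <- sprintf("I%02d", 1:15)
  het <- character(J)
  het[v] <- sample(het_v, sum(v), replace = TRUE,
                   prob = (1 / seq_along(het_v))^1.0)
  het[!v] <- sample(het_i, sum(!v), replace = TRUE,
                    prob = (1 / seq_along(het_i))^1.6)

  structure(list(
    surface_counts = surface_counts,
    site_counts = site_counts,
    site_info = data.frame(protein = protein, validity = validity,
                           het_code = het, size = size,
                           stringsAsFactors = FALSE),
    truth = list(background = bg,
                 propensity_valid = kv, propensity_invalid = ki,
                 site_freq_valid = pv, site_freq_invalid = pi_,
                 spec = spec)
  ), class = "bp_composition")
}

#' @export
print.bp_composition <- function(x, ...) {
  cat("<bp_composition>", nrow(x$surface_counts), "proteins,",
      nrow(x$site_counts), "sites (",
      sum(x$site_info$validity == "valid"), "valid /",
      sum(x$site_info$validity == "invalid"), "invalid )\n")
  invisible(x)
}

#' Label a composition dataset with an enzyme/non-enzyme split
#'
#' Assigns each protein to the subgroup (enzyme) or background class and
#' re-draws the subgroup's valid-site counts with an extra multiplicative
#' enrichment, recording the updated ground truth. With enrichment all 1 the
#' subgroup is statistically indistinguishable from a random subset.
#'
#' @param dataset A `bp_composition`.
#' @param fraction_enzyme Fraction of proteins labeled as subgroup members.
#' @param subgroup_enrichment Named positive enrichment over [AA3] applied on
#'   top of the dataset's valid-site frequencies (default all 1).
#' @param seed Integer seed.
#' @return The dataset with `enzyme` (logical per protein) and updated
#'   `truth$propensity_subgroup`.
#' @export
generate_enzyme_split <- function(dataset, fraction_enzyme = 0.5,
                                  subgroup_enrichment = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "bp_composition"),
            fraction_enzyme > 0, fraction_enzyme <= 1)
  set.seed(seed)
  P <- nrow(dataset$surface_counts)
  one <- stats::setNames(rep(1, 20), AA3)
  if (is.null(subgroup_enrichment)) subgroup_enrichment <- one
  subgroup_enrichment <- subgroup_enrichment[AA3]
  n_sub <- max(1L, round(fraction_enzyme * P))
  members <- sort(sample.int(P, n_sub))
  enzyme <- seq_len(P) %in% members
  bg <- dataset$truth$background
  p_sub <- dataset$truth$site_freq_valid * subgroup_enrichment
  p_sub <- p_sub / sum(p_sub)
  redraw <- which(dataset$site_info$validity == "valid" &
                    dataset$site_info$protein %in% members)
  if (!all(subgroup_enrichment == 1)) {
    for (j in redraw)
      dataset$site_counts[j, ] <-
        as.numeric(stats::rmultinom(1, dataset$site_info$size[j], p_sub))
  }
  dataset$enzyme <- enzyme
  dataset$truth$propensity_subgroup <- p_sub / bg
  dataset$truth$subgroup_enrichment <- subgroup_enrichment
  dataset
}

#' Specification for a toy protein-ligand complex
#'
#' @param n_shell_residues Number of single-contact residues placed on a
#'   shell around the ligand, at distances straddling the hydrogen-bond
#'   (3.5 A) and site (4.0 A) cutoffs.
#' @param ligand_elements Elements of the ligand's heavy atoms (placed on a
#'   small sphere around the origin).
#' @param distance_range Range of anchor-atom distances (A) from their
#'   reference ligand atom.
#' @param include_boundary Place four extra residues at exactly 3.5 and 4.0 A
#'   (axis-aligned, binary-exact coordinates) to pin the inclusive cutoffs.
#' @param buried_decoy_count Number of fully caged decoy residues with
#'   expected SASA 0, placed far from the ligand.
#' @param jitter Radial jitter (A) applied to shell distances.
#' @param het_code,validity HET code and validity label of the toy ligand.
#' @param seed Integer seed.
#' @return A `bp_toy_spec` list.
#' @export
toy_complex_spec <- function(n_shell_residues = 60,
                             ligand_elements = c("C", "O", "N", "O", "C",
                                                 "P"),
                             distance_range = c(3.2, 4.4),
                             include_boundary = TRUE,
                             buried_decoy_count = 1,
                             jitter = 0.05,
                             het_code = "LIG", validity = "valid",
                             seed = 1L) {
  stopifnot(n_shell_residues >= 1, length(ligand_elements) >= 1,
            jitter >= 0, diff(distance_range) > 0)
  structure(list(n_shell_residues = as.integer(n_shell_residues),
                 ligand_elements = toupper(ligand_elements),
                 distance_range = distance_range,
                 include_boundary = isTRUE(include_boundary),
                 buried_decoy_count = as.integer(buried_decoy_count),
                 jitter = jitter, het_code = het_code, validity = validity,
                 seed = as.integer(seed)),
            class = "bp_toy_spec")
}

# Residue templates for shell residues: anchor atom (the one placed at the
# scripted distance) plus trailing atoms pushed outward, chosen to exercise
# every typing rule (backbone vs side-chain anchors, carbon vs non-carbon
# elements, glycine CA).
SHELL_TEMPLATES <- list(
  list(resname = "SER", anchor = "OG",  anchor_el = "O",
       rest = c(CB = "C", CA = "C", N = "N", C = "C", O = "O")),
  list(resname = "CYS", anchor = "SG",  anchor_el = "S",
       rest = c(CB = "C", CA = "C", N = "N", C = "C", O = "O")),
  list(resname = "ALA", anchor = "CB",  anchor_el = "C",
       rest = c(CA = "C", N = "N", C = "C", O = "O")),
  list(resname = "LYS", anchor = "NZ",  anchor_el = "N",
       rest = c(CA = "C", N = "N", C = "C", O = "O", CB = "C")),
  list(resname = "THR", anchor = "N",   anchor_el = "N",
       rest = c(CA = "C", C = "C", O = "O", CB = "C")),
  list(resname = "LEU", anchor = "O",   anchor_el = "O",
       rest = c(C = "C", CA = "C", N = "N", CB = "C")),
  list(resname = "GLY", anchor = "CA",  anchor_el = "C",
       rest = c(N = "N", C = "C", O = "O")),
  list(resname = "PHE", anchor = "CA",  anchor_el = "C",
       rest = c(N = "N", C = "C", O = "O", CB = "C"))
)

#' Generate a toy protein-ligand complex in PDB format
#'
#' Places a small ligand near the origin and `n_shell_residues` residues
#' around it, each anchored at a scripted distance from a ligand atom so
#' that contact presence, hydrogen-bond/van-der-Waals type and SC/BB-only
#' category are enumerable. Optional buried decoy residues are enclosed in a
#' dense carbon cage so their expected SASA is zero (verified inside the
#' generator by an independent random-direction probe test). All coordinates
#' are rounded to PDB precision (0.001 A) *before* the ground truth is
#' computed, so the truth refers to exactly the structure written out.
#'
#' The ground-truth contact list is computed by a deliberately naive
#' all-pairs distance scan, independent of the package's contact code.
#'
#' @param spec A [toy_complex_spec()].
#' @return List with `pdb` (character vector of PDB lines), `atoms` (the atom
#'   table), and `truth`: contact records (residue, atom, type, category),
#'   per-residue expected categories, and buried-residue identities.
#' @export
generate_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "bp_toy_spec"))
  set.seed(spec$seed)
  atoms <- list()
  add_atom <- function(name, el, resname, chain, resno, xyz, record) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      name = name, element = el, resname = resname, chain = chain,
      resno = resno, x = round(xyz[1], 3), y = round(xyz[2], 3),
      z = round(xyz[3], 3), record = record, stringsAsFactors = FALSE)
  }

  # Ligand atoms on a small sphere (radius 0.8 A) around the origin.
  nlig <- length(spec$ligand_elements)
  lig_pos <- if (nlig == 1) matrix(0, 1, 3) else
    golden_spiral_points(nlig) * 0.8
  for (i in seq_len(nlig))
    add_atom(paste0(spec$ligand_elements[i], i), spec$ligand_elements[i],
             spec$het_code, "L", 501L, lig_pos[i, ], "HETATM")
  if (spec$include_boundary) {
    # Dedicated non-carbon reference atom at clean coordinates, offset from
    # the ligand body so the axis-aligned boundary residues sit at
    # binary-exact 3.5/4.0 A distances from it and out of reach of the rest.
    bref <- c(3.0, 0, 0)
    add_atom("O99", "O", spec$het_code, "L", 501L, bref, "HETATM")
  }

  # Shell residues: anchor at scripted distance from a scripted ligand atom,
  # remaining atoms pushed radially outward.
  n <- spec$n_shell_residues
  dirs <- golden_spiral_points(max(n, 2))
  d_lo <- spec$distance_range[1]; d_hi <- spec$distance_range[2]
  dists <- d_lo + (seq_len(n) - 1) / max(1, n - 1) * (d_hi - d_lo)
  dists <- dists + stats::runif(n, -spec$jitter, spec$jitter)
  for (i in seq_len(n)) {
    tmpl <- SHELL_TEMPLATES[[(i - 1) %% length(SHELL_TEMPLATES) + 1]]
    ref <- (i - 1) %% nlig + 1
    u <- dirs[i, ]
    anchor <- lig_pos[ref, ] + u * dists[i]
    add_atom(tmpl$anchor, tmpl$anchor_el, tmpl$resname, "A", i, anchor,
             "ATOM")
    rest <- tmpl$rest
    for (j in seq_along(rest))
      add_atom(names(rest)[j], rest[[j]], tmpl$resname, "A", i,
               anchor + u * (1.6 * j), "ATOM")
  }

  if (spec$include_boundary) {
    # Axis-aligned boundary residues with binary-exact offsets from the
    # reference atom, pinning the inclusive <=3.5 and <=4.0 comparisons.
    bx <- bref
    bnd <- list(
      list(resname = "SER", anchor = "OG", el = "O", d = 3.5,
           u = c(0, 0, 1)),   # hbond exactly at 3.5
      list(resname = "ALA", anchor = "CB", el = "C", d = 3.5,
           u = c(0, 0, -1)),  # carbon at 3.5 -> vdw
      list(resname = "LYS", anchor = "NZ", el = "N", d = 4.0,
           u = c(0, 1, 0)),   # in range exactly at 4.0 -> vdw
      list(resname = "THR", anchor = "N",  el = "N", d = 4.5,
           u = c(0, -1, 0))   # beyond cutoff -> no contact
    )
    for (b in seq_along(bnd)) {
      bb <- bnd[[b]]
      anchor <- bx + bb$u * bb$d
      resno <- 400L + b
      add_atom(bb$anchor, bb$el, bb$resname, "A", resno, anchor, "ATOM")
      add_atom("CA", "C", bb$resname, "A", resno, anchor + bb$u * 1.6,
               "ATOM")
      add_atom("C", "C", bb$resname, "A", resno, anchor + bb$u * 3.2,
               "ATOM")
      add_atom("O", "O", bb$resname, "A", resno, anchor + bb$u * 4.0,
               "ATOM")
    }
  }

  buried <- data.frame(chain = character(), resno = integer(),
                       stringsAsFactors = FALSE)
  if (spec$buried_decoy_count > 0) {
    cage_resno <- 1L
    for (dcy in seq_len(spec$buried_decoy_count)) {
      center <- c(40 + 20 * dcy, 0, 0)
      tet <- rbind(c(0.3, 0.3, 0.3), c(-0.3, -0.3, 0.3),
                   c(-0.3, 0.3, -0.3), c(0.3, -0.3, -0.3))
      nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
      for (j in 1:4)
        add_atom(nm[j], el[j], "GLY", "B", dcy, center + tet[j, ], "ATOM")
      cage <- golden_spiral_points(180) * 4.2
      for (j in seq_len(nrow(cage))) {
        # distinct atom names within each 4-atom cage residue
        add_atom(paste0("CW", (j - 1) %% 4 + 1), "C", "GLY", "D",
                 cage_resno, center + cage[j, ], "ATOM")
        if (j %% 4 == 0) cage_resno <- cage_resno + 1L
      }
      buried <- rbind(buried, data.frame(chain = "B", resno = dcy,
                                         stringsAsFactors = FALSE))
    }
  }

  at <- do.call(rbind, atoms)
  at$serial <- seq_len(nrow(at))
  at$icode <- ""

  # ---- ground truth: naive all-pairs scan on the rounded coordinates ----
  pol <- at[at$record == "ATOM", , drop = FALSE]
  lig <- at[at$record == "HETATM", , drop = FALSE]
  truth_rows <- list()
  for (i in seq_len(nrow(pol))) {
    for (j in seq_len(nrow(lig))) {
      dd <- sqrt((pol$x[i] - lig$x[j])^2 + (pol$y[i] - lig$y[j])^2 +
                   (pol$z[i] - lig$z[j])^2)
      if (dd <= 4.0) {
        role <- if (pol$name[i] %in% BACKBONE_ATOMS &&
                    !(pol$resname[i] == "GLY" && pol$name[i] == "CA"))
          "backbone" else "sidechain"
        type <- if (dd <= 3.5 && pol$element[i] != "C" &&
                    lig$element[j] != "C") "hbond" else "vdw"
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          chain = pol$chain[i], resno = pol$resno[i],
          resname = pol$resname[i], protein_atom = pol$name[i],
          protein_role = role, ligand_atom = lig$name[j],
          distance = dd, interaction = type, stringsAsFactors = FALSE)
      }
    }
  }
  contacts <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(chain = character(), resno = integer(), resname = character(),
               protein_atom = character(), protein_role = character(),
               ligand_atom = character(), distance = numeric(),
               interaction = character(), stringsAsFactors = FALSE)
  categories <- NULL
  if (nrow(contacts)) {
    sp <- split(contacts, paste(contacts$chain, contacts$resno))
    categories <- do.call(rbind, lapply(sp, function(g) data.frame(
      chain = g$chain[1], resno = g$resno[1], resname = g$resname[1],
      category = if (any(g$protein_role == "sidechain")) "SC" else "BB_only",
      n_contacts = nrow(g), n_hbond = sum(g$interaction == "hbond"),
      n_vdw = sum(g$interaction == "vdw"), stringsAsFactors = FALSE)))
    rownames(categories) <- NULL
  }

  # Verify decoy burial with an independent random-direction probe test.
  if (nrow(buried)) {
    radii <- DEFAULT_VDW_RADII
    probe <- 1.4
    for (b in seq_len(nrow(buried))) {
      da <- pol[pol$chain == buried$chain[b] &
                  pol$resno == buried$resno[b], , drop = FALSE]
      others <- pol[!(pol$chain == buried$chain[b] &
                        pol$resno == buried$resno[b]), , drop = FALSE]
      for (i in seq_len(nrow(da))) {
        u <- matrix(stats::rnorm(3 * 400), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        ri <- radii[[da$element[i]]] + probe
        pts <- sweep(u * ri, 2, c(da$x[i], da$y[i], da$z[i]), "+")
        cand <- rbind(others, da[-i, , drop = FALSE])
        rj <- radii[unlist(cand$element)] + probe
        covered <- rep(FALSE, nrow(pts))
        for (j in seq_len(nrow(cand))) {
          d2 <- (pts[, 1] - cand$x[j])^2 + (pts[, 2] - cand$y[j])^2 +
            (pts[, 3] - cand$z[j])^2
          covered <- covered | (d2 < rj[j]^2)
          if (all(covered)) break
        }
        if (!all(covered))
          stop("cage construction failed: decoy atom not fully buried")
      }
    }
  }

  list(pdb = write_pdb_lines(at), atoms = at,
       truth = list(contacts = contacts, categories = categories,
                    buried = buried, het_code = spec$het_code,
                    validity = spec$validity))
}

# Emit fixed-width PDB ATOM/HETATM records for a toy atom table.
write_pdb_lines <- function(at) {
  name4 <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
                  formatC(paste0(" ", at$name), width = -4))
  lines <- sprintf(
    "%-6s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$record, at$serial, name4, at$resname, at$chain, at$resno,
    ifelse(at$icode == "", " ", at$icode), at$x, at$y, at$z, 1.0, 0.0,
    formatC(at$element, width = 2))
  c(lines, "END")
}
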