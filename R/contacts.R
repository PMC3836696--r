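# Ligand-protein heavy-atom contact detection and interaction typing.
#
# A contact is any (protein heavy atom, ligand heavy atom) pair within the
# site cutoff (4.0 A, inclusive). Typing is purely geometric: pairs of
# non-carbon atoms within 3.5 A are hydrogen bonds; everything else in range
# is a van der Waals contact. No angle criterion or donor/acceptor typing is
# applied.

#' Find heavy-atom contacts between a ligand instance and the protein
#'
#' Every polymer heavy atom within `cutoff` of any heavy atom of the ligand
#' instance yields one contact record. Residues from any chain of the biounit
#' may contribute; a residue near two ligands appears independently in each
#' ligand's contact set. Waters never mediate contacts (they are excluded
#' from the polymer partition upstream).
#'
#' @param s A normalized `bp_structure`.
#' @param lig One row of `s$ligands` (or its row index).
#' @param cutoff Contact distance cutoff in Angstrom (inclusive), default 4.0.
#' @param hbond_cutoff Hydrogen-bond distance cutoff (inclusive), default 3.5.
#' @return Data frame of contact records: residue identity, protein atom name
#'   / role / element, ligand identity and atom, distance, and interaction
#'   type (`hbond`/`vdw`).
#' @export
find_contacts <- function(s, lig, cutoff = 4.0, hbond_cutoff = 3.5) {
  stopifnot(inherits(s, "bp_structure"), cutoff > 0,
            hbond_cutoff <= cutoff)
  if (is.numeric(lig)) lig <- s$ligands[lig, , drop = FALSE]
  la <- ligand_atoms(s, lig)
  if (!nrow(la)) stop("ligand ", lig$het_code, " has no heavy atoms")
  pa <- s$atoms[s$atoms$partition == "polymer", , drop = FALSE]
  if (!nrow(pa)) return(empty_contacts())

  # All-pairs squared distances (protein x ligand).
  dx <- outer(pa$x, la$x, "-")
  dy <- outer(pa$y, la$y, "-")
  dz <- outer(pa$z, la$z, "-")
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty_contacts())
  pi_ <- hit[, 1]; li <- hit[, 2]
  dist <- d[hit]
  data.frame(
    chain = pa$chain[pi_], resno = pa$resno[pi_], icode = pa$icode[pi_],
    resname = pa$resname[pi_],
    protein_atom = pa$name[pi_], protein_role = pa$role[pi_],
    protein_element = pa$element[pi_],
    het_code = rep(lig$het_code, length(pi_)),
    lig_chain = rep(lig$chain, length(pi_)),
    lig_resno = rep(lig$resno, length(pi_)),
    lig_icode = rep(lig$icode, length(pi_)),
    ligand_atom = la$name[li], ligand_element = la$element[li],
    distance = dist,
    interaction = classify_contact_type(pa$element[pi_], la$element[li],
                                        dist, hbond_cutoff),
    stringsAsFactors = FALSE
  )
}

empty_contacts <- function() {
  data.frame(chain = character(), resno = integer(), icode = character(),
             resname = character(), protein_atom = character(),
             protein_role = character(), protein_element = character(),
             het_code = character(), lig_chain = character(),
             lig_resno = integer(), lig_icode = character(),
             ligand_atom = character(), ligand_element = character(),
             distance = numeric(), interaction = character(),
             stringsAsFactors = FALSE)
}

#' Classify a contact as hydrogen bond or van der Waals
#'
#' Distance rules only, applied by element class: within the hydrogen-bond
#' cutoff (3.5 A, inclusive) a pair of non-carbon atoms (N, O, S, P, ...)
#' counts as a hydrogen bond; any pair involving a carbon, or any pair beyond
#' 3.5 A, counts as van der Waals.
#'
#' @param protein_element,ligand_element Element symbols (vectorized).
#' @param distance Distances in Angstrom (must be within the site cutoff).
#' @param hbond_cutoff Hydrogen-bond distance cutoff, default 3.5.
#' @return Character vector, `"hbond"` or `"vdw"`.
#' @export
classify_contact_type <- function(protein_element, ligand_element, distance,
                                  hbond_cutoff = 3.5) {
  ifelse(distance <= hbond_cutoff &
           protein_element != "C" & ligand_element != "C",
         "hbond", "vdw")
}

#' Classify one residue-ligand interaction as SC or BB-only
#'
#' A residue is side chain (SC) when at least one of its contacting protein
#' atoms is a side-chain atom (glycine's CA counts as side chain), whether or
#' not backbone atoms also contact; it is backbone-only (BB-only) when every
#' contacting atom is backbone.
#'
#' @param contacts Contact records for a single residue-ligand pair.
#' @return One-row data frame: residue identity, `category` (`"SC"` or
#'   `"BB_only"`), contact counts split by interaction type, and hydrogen
#'   bonds split into backbone N, backbone O and side-chain atoms.
#' @export
classify_residue_interaction <- function(contacts) {
  if (!nrow(contacts)) stop("empty contact collection")
  key <- unique(paste(contacts$chain, contacts$resno, contacts$icode,
                      contacts$het_code, contacts$lig_chain,
                      contacts$lig_resno, contacts$lig_icode))
  if (length(key) != 1)
    stop("contacts must belong to a single residue-ligand pair")
  hb <- contacts$interaction == "hbond"
  data.frame(
    chain = contacts$chain[1], resno = contacts$resno[1],
    icode = contacts$icode[1], resname = contacts$resname[1],
    het_code = contacts$het_code[1], lig_chain = contacts$lig_chain[1],
    lig_resno = contacts$lig_resno[1], lig_icode = contacts$lig_icode[1],
    category = if (any(contacts$protein_role == "sidechain")) "SC"
               else "BB_only",
    n_contacts = nrow(contacts),
    n_hbond = sum(hb),
    n_vdw = sum(!hb),
    n_hb_bbN = sum(hb & contacts$protein_atom == "N"),
    n_hb_bbO = sum(hb & contacts$protein_atom %in% c("O", "OXT")),
    n_hb_sc = sum(hb & contacts$protein_role == "sidechain"),
    stringsAsFactors = FALSE
  )
}

# Internal: split a contact table into residue-ligand interaction rows.
residue_interactions <- function(contacts) {
  if (!nrow(contacts)) {
    return(classify_residue_interaction(contacts)[0, ])
  }
  key <- paste(contacts$chain, contacts$resno, contacts$icode,
               contacts$het_code, contacts$lig_chain, contacts$lig_resno,
               contacts$lig_icode, sep = "\r")
  parts <- split(seq_len(nrow(contacts)), key)
  out <- lapply(parts, function(ix)
    classify_residue_interaction(contacts[ix, , drop = FALSE]))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-amino-acid contact summary over a set of binding sites
#'
#' Pools the residue interactions of a collection of binding sites and
#' reports, per amino acid and validity class: the share of binding-site
#' residues (`pct_site`), mean contacts per residue, mean contacts per heavy
#' atom of the residue type, and mean hydrogen bonds per residue split into
#' backbone N, backbone O and side-chain contributions. With a
#' `surface_cutoff`, only residues passing the SASA cutoff for their category
#' (SC on side-chain area, BB-only on backbone area, glycine on the max) are
#' counted.
#'
#' @param sites List of `bp_site` objects (see [build_binding_site()]).
#' @param surface_cutoff Optional SASA cutoff in Angstrom^2.
#' @return Data frame keyed by (`validity`, `resname`).
#' @export
summarize_contacts <- function(sites, surface_cutoff = NULL) {
  if (!length(sites)) stop("empty site collection")
  rows <- lapply(sites, function(st) {
    r <- st$residues
    if (!is.null(surface_cutoff)) r <- r[r$eff_area >= surface_cutoff, ,
                                         drop = FALSE]
    if (nrow(r)) r$validity <- st$validity
    r
  })
  r <- do.call(rbind, rows[vapply(rows, nrow, 1L) > 0])
  if (is.null(r) || !nrow(r)) stop("no residues left to summarize")
  out <- do.call(rbind, lapply(split(r, r$validity), function(g) {
    f <- factor(g$resname, levels = AA3)
    n <- as.numeric(table(f))
    data.frame(validity = g$validity[1], resname = AA3, n_residues = n,
               pct_site = 100 * n / nrow(g),
               contacts_per_res = as.numeric(tapply(g$n_contacts, f, mean)),
               contacts_per_ha =
                 as.numeric(tapply(g$n_contacts, f, mean)) /
                 unname(AA_HEAVY_ATOMS),
               hb_per_res = as.numeric(tapply(g$n_hbond, f, mean)),
               hb_bbN_per_res = as.numeric(tapply(g$n_hb_bbN, f, mean)),
               hb_bbO_per_res = as.numeric(tapply(g$n_hb_bbO, f, mean)),
               hb_sc_per_res = as.numeric(tapply(g$n_hb_sc, f, mean)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
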