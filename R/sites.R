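# Binding-site assembly, surface filtering, per-biounit deduplication and
# dataset summaries.

#' Assemble a binding site from a ligand's contacts
#'
#' Groups the contact records of one ligand instance into per-residue
#' interactions, attaches effective SASA values from the surface table, and
#' computes the surface-filtered residue subset and the site SASA. Each
#' residue's effective area is class-appropriate: SC residues use the
#' side-chain area, BB-only residues the backbone area, glycine the larger
#' of the two. The site SASA is the sum of these effective areas over the
#' contacting residues. Sites whose residues are all buried (below the
#' cutoff) are flagged `empty_surface` and are excluded from frequency pools
#' downstream, while remaining available for raw-contact summaries.
#'
#' @param s A normalized `bp_structure`.
#' @param lig One row of `s$ligands` (or its row index).
#' @param contacts Contact records from [find_contacts()] for this ligand.
#' @param surface A `bp_surface` from [compute_sasa()].
#' @param cutoff SASA surface cutoff in Angstrom^2 (inclusive), default 5.0.
#' @return A `bp_site`: list with ligand identity and validity, `residues`
#'   (per-residue interaction rows with `category`, contact counts,
#'   `eff_area` and `on_surface`), residue-type `counts` (over [AA3]),
#'   `site_sasa`, and bookkeeping flags.
#' @export
build_binding_site <- function(s, lig, contacts, surface, cutoff = 5.0) {
  if (is.numeric(lig)) lig <- s$ligands[lig, , drop = FALSE]
  res <- residue_interactions(contacts)
  if (nrow(res)) {
    key_r <- paste(res$chain, res$resno, res$icode, sep = "\r")
    key_s <- paste(surface$residues$chain, surface$residues$resno,
                   surface$residues$icode, sep = "\r")
    ix <- match(key_r, key_s)
    res$eff_side <- surface$residues$eff_side[ix]
    res$eff_main <- surface$residues$eff_main[ix]
    res$eff_area <- ifelse(res$category == "SC", res$eff_side, res$eff_main)
    res$eff_area[is.na(res$eff_area)] <- 0
    res$on_surface <- res$eff_area >= cutoff
  } else {
    res$eff_side <- res$eff_main <- res$eff_area <- numeric(0)
    res$on_surface <- logical(0)
  }
  structure(list(
    structure_id = s$structure_id,
    het_code = lig$het_code, chain = lig$chain, resno = lig$resno,
    icode = lig$icode,
    validity = lig$validity,
    residues = res,
    counts = count_aa(res$resname),
    n_residues = nrow(res),
    site_sasa = sum(res$eff_area),
    surface_cutoff = cutoff,
    empty_surface = !any(res$on_surface)
  ), class = "bp_site")
}

#' Build all binding sites of a structure
#'
#' Convenience wrapper: contacts and sites for every ligand instance.
#'
#' @inheritParams build_binding_site
#' @param contact_cutoff,hbond_cutoff Distance cutoffs in Angstrom.
#' @return List of `bp_site` objects (possibly empty sites included).
#' @export
build_all_sites <- function(s, surface, cutoff = 5.0, contact_cutoff = 4.0,
                            hbond_cutoff = 3.5) {
  lapply(seq_len(nrow(s$ligands)), function(i) {
    lig <- s$ligands[i, , drop = FALSE]
    contacts <- find_contacts(s, lig, contact_cutoff, hbond_cutoff)
    build_binding_site(s, lig, contacts, surface, cutoff)
  })
}

#' Deduplicate symmetry-equivalent sites within one biounit
#'
#' Multimeric biounits often carry the same ligand in several equivalent
#' pockets. For each HET code, sites with identical residue-type count
#' vectors collapse to one (the first in ligand-instance order); sites of the
#' same ligand with differing count vectors are all retained, representing
#' genuine variability of the binding. Deduplication never crosses HET codes
#' and never crosses structures.
#'
#' @param sites List of `bp_site` objects from one structure.
#' @return Filtered list of `bp_site` objects.
#' @export
deduplicate_sites <- function(sites) {
  if (!length(sites)) return(sites)
  ids <- unique(vapply(sites, function(x) x$structure_id, ""))
  if (length(ids) > 1)
    stop("deduplicate_sites expects sites from a single structure")
  key <- vapply(sites, function(x)
    paste(x$het_code, paste(x$counts, collapse = ","), sep = "|"), "")
  sites[!duplicated(key)]
}

#' Summarize a site collection in the style of a dataset table
#'
#' Per validity class and per interaction category (SC / BB-only): total
#' sites, non-redundant sites (after per-structure deduplication), and for
#' the non-redundant sites with at least one surface residue of that
#' category, the mean/median surface residues per site and mean/median site
#' SASA. If per-structure surface tables are supplied, the protein:site
#' residue ratio (total protein surface residues of that class over total
#' site residues) is included.
#'
#' @param sites List of `bp_site` objects (any number of structures).
#' @param surfaces Optional named list of `bp_surface` objects keyed by
#'   `structure_id`, for the protein:site ratio.
#' @param cutoff SASA cutoff used for the surface filtering (must match the
#'   sites' cutoff).
#' @return Data frame, one row per (validity, category).
#' @export
dataset_summary <- function(sites, surfaces = NULL, cutoff = 5.0) {
  sites <- sites[vapply(sites, function(x) x$n_residues, 1L) > 0]
  by_struct <- split(sites, vapply(sites, function(x) x$structure_id, ""))
  nr_sites <- unlist(lapply(by_struct, deduplicate_sites), recursive = FALSE)
  validities <- vapply(sites, function(x) x$validity, "")
  rows <- list()
  for (v in unique(validities)) {
    tot <- sum(validities == v)
    nr <- nr_sites[vapply(nr_sites, function(x) x$validity, "") == v]
    for (cls in c("SC", "BB_only")) {
      nres <- vapply(nr, function(st) {
        r <- st$residues
        sum(r$category == cls & r$on_surface)
      }, 1L)
      sasa <- vapply(nr, function(st) {
        r <- st$residues
        sum(r$eff_area[r$category == cls & r$on_surface])
      }, 1)
      keep <- nres > 0
      ratio <- NA_real_
      if (!is.null(surfaces) && sum(nres[keep]) > 0) {
        ps <- sum(vapply(surfaces, function(sf) {
          nrow(surface_residues(sf, cutoff,
                                if (cls == "SC") "sidechain" else "mainchain"))
        }, 1))
        ratio <- ps / sum(nres[keep])
      }
      rows[[length(rows) + 1]] <- data.frame(
        validity = v, category = cls, n_sites = tot,
        n_nonredundant = length(nr), n_class_sites = sum(keep),
        mean_res_per_site = if (any(keep)) mean(nres[keep]) else NA_real_,
        median_res_per_site = if (any(keep)) stats::median(nres[keep])
                              else NA_real_,
        mean_sasa_per_site = if (any(keep)) mean(sasa[keep]) else NA_real_,
        median_sasa_per_site = if (any(keep)) stats::median(sasa[keep])
                               else NA_real_,
        protein_site_ratio = ratio,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
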