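# Pooled residue frequencies and binding-site propensities.
#
# The propensity of amino acid i is the ratio of its frequency pooled over
# binding-site surfaces to its frequency pooled over whole protein surfaces.
# Counts are summed across sites/structures BEFORE division: a mean of
# per-protein propensities would be dominated by division-by-zero and
# small-denominator artifacts for rare residues.

#' Pool residue counts into a frequency table
#'
#' Sums residue counts across a collection of items (binding-site residue
#' sets, or protein surface residue sets) and normalizes once at the end.
#' This is pooling, not a mean of per-item frequencies.
#'
#' @param items A list whose elements are either character vectors of residue
#'   names or named count vectors over [AA3]; or a single matrix with 20
#'   columns (rows are items).
#' @param region `"binding_site"` or `"protein_surface"`.
#' @param class Interaction class the counts refer to (`"SC"`, `"BB_only"`,
#'   or `"all"`).
#' @param validity `"valid"`, `"invalid"`, or `"all"`.
#' @param n_structures,n_sites Optional bookkeeping counts.
#' @return A `bp_freq_table`: list with `counts`, `frequencies` (both named
#'   over [AA3]), `total` and the configuration metadata.
#' @export
accumulate_frequencies <- function(items,
                                   region = c("binding_site",
                                              "protein_surface"),
                                   class = "SC", validity = "all",
                                   n_structures = NA_integer_,
                                   n_sites = NA_integer_) {
  region <- match.arg(region)
  if (is.matrix(items)) {
    counts <- colSums(items)
    names(counts) <- AA3
  } else {
    counts <- empty_aa_counts()
    for (it in items) {
      if (is.character(it)) counts <- counts + count_aa(it)
      else counts <- counts + it[AA3]
    }
  }
  total <- sum(counts)
  if (total <= 0)
    stop("zero total residue count for configuration (", region, ", ",
         class, ", ", validity, ")")
  structure(list(region = region, class = class, validity = validity,
                 counts = counts, frequencies = counts / total,
                 total = total, n_structures = n_structures,
                 n_sites = n_sites),
            class = "bp_freq_table")
}

#' Compute per-residue propensities from pooled frequencies
#'
#' `P_i = F_i(binding site) / F_i(protein surface)`. A residue whose surface
#' frequency is zero gets an undefined (NA) propensity with `undefined =
#' TRUE`, never infinity. Propensities equal 1 exactly when the two
#' frequencies coincide.
#'
#' @param bs Binding-site `bp_freq_table`.
#' @param ps Protein-surface `bp_freq_table` with the same class.
#' @return A `bp_propensity`: data frame per amino acid with counts,
#'   frequencies, `propensity` and `undefined`; configuration in attributes.
#' @export
compute_propensity <- function(bs, ps) {
  stopifnot(inherits(bs, "bp_freq_table"), inherits(ps, "bp_freq_table"))
  if (bs$region != "binding_site" || ps$region != "protein_surface")
    stop("expected a binding_site table and a protein_surface table")
  if (!identical(bs$class, ps$class))
    stop("mismatched class: '", bs$class, "' vs '", ps$class, "'")
  undef <- ps$frequencies == 0
  prop <- ifelse(undef, NA_real_, bs$frequencies / ps$frequencies)
  out <- data.frame(resname = AA3,
                    count_bs = unname(bs$counts),
                    freq_bs = unname(bs$frequencies),
                    count_ps = unname(ps$counts),
                    freq_ps = unname(ps$frequencies),
                    propensity = unname(prop),
                    undefined = unname(undef),
                    stringsAsFactors = FALSE)
  attr(out, "class_") <- bs$class
  attr(out, "validity") <- bs$validity
  class(out) <- c("bp_propensity", "data.frame")
  out
}

#' Valid/invalid propensity ratio per residue
#'
#' `ratio_i = P_i(valid) / P_i(invalid)`; undefined propensities propagate to
#' an undefined ratio. Ratios above 1 mark residues biased toward
#' biologically relevant sites, below 1 toward spurious (additive) sites.
#'
#' @param valid,invalid `bp_propensity` objects of the same class.
#' @return Data frame per amino acid with both propensities and their ratio.
#' @export
propensity_ratio <- function(valid, invalid) {
  if (!identical(attr(valid, "class_"), attr(invalid, "class_")))
    stop("mismatched interaction class between valid and invalid tables")
  data.frame(resname = AA3,
             propensity_valid = valid$propensity,
             propensity_invalid = invalid$propensity,
             ratio = valid$propensity / invalid$propensity,
             stringsAsFactors = FALSE)
}

#' Exclude sites of the most frequent ligands
#'
#' Removes every site whose HET code ranks among the `k` most frequent
#' ligands of its validity class (frequency = number of sites; ties broken
#' lexicographically by HET code). Used to measure how much the most common
#' ligands (nucleotides among valids, buffer components among invalids) bias
#' the pooled propensities.
#'
#' @param sites List of `bp_site` objects, or a data frame with `het_code`
#'   and `validity` columns.
#' @param k Number of top ligands to exclude per validity class (>= 0).
#' @return Filtered collection of the same type.
#' @export
exclude_top_ligands <- function(sites, k) {
  stopifnot(k >= 0)
  if (k == 0) return(sites)
  if (is.data.frame(sites)) {
    het <- sites$het_code; val <- sites$validity
  } else {
    het <- vapply(sites, function(x) x$het_code, "")
    val <- vapply(sites, function(x) x$validity, "")
  }
  drop <- rep(FALSE, length(het))
  for (v in unique(val)) {
    tab <- table(het[val == v])
    ranked <- names(tab)[order(-as.numeric(tab), names(tab))]
    top <- ranked[seq_len(min(k, length(ranked)))]
    drop <- drop | (val == v & het %in% top)
  }
  if (is.data.frame(sites)) sites[!drop, , drop = FALSE] else sites[!drop]
}

#' Pooled propensities from a geometry-world site collection
#'
#' Builds the binding-site and protein-surface frequency tables for one
#' (class, validity) configuration and returns the propensities. Only
#' structures that contain at least one non-empty site of that configuration
#' enter the protein-surface denominator, and only surface residues (at the
#' sites' SASA cutoff) are counted on either side.
#'
#' @param sites List of deduplicated `bp_site` objects.
#' @param surfaces Named list of `bp_surface` objects keyed by structure id.
#' @param class `"SC"` or `"BB_only"`.
#' @param validity `"valid"` or `"invalid"`.
#' @param cutoff SASA cutoff (Angstrom^2).
#' @return A `bp_propensity` data frame.
#' @export
site_propensity <- function(sites, surfaces, class = "SC",
                            validity = "valid", cutoff = 5.0) {
  keep <- vapply(sites, function(st) {
    st$validity == validity &&
      any(st$residues$category == class & st$residues$on_surface)
  }, TRUE)
  sel <- sites[keep]
  if (!length(sel))
    stop("no sites for configuration (", class, ", ", validity, ")")
  bs_items <- lapply(sel, function(st) {
    r <- st$residues
    r$resname[r$category == class & r$on_surface]
  })
  struct_ids <- unique(vapply(sel, function(x) x$structure_id, ""))
  ps_items <- lapply(struct_ids, function(id) {
    surface_residues(surfaces[[id]], cutoff,
                     if (class == "SC") "sidechain" else "mainchain")$resname
  })
  bs <- accumulate_frequencies(bs_items, "binding_site", class, validity,
                               n_structures = length(struct_ids),
                               n_sites = length(sel))
  ps <- accumulate_frequencies(ps_items, "protein_surface", class, validity,
                               n_structures = length(struct_ids))
  compute_propensity(bs, ps)
}
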