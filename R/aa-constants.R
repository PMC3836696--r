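# Amino-acid bookkeeping shared across the package.

#' Standard amino acids
#'
#' Three-letter codes of the 20 standard amino acids, alphabetical by code.
#' This ordering is used for every count vector and frequency table in the
#' package.
#'
#' @format Character vector of length 20.
#' @export
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Heavy-atom counts of the standard amino acids
#'
#' Number of non-hydrogen atoms per residue (backbone N, CA, C, O plus side
#' chain), used to normalise contact counts to contacts per heavy atom.
#'
#' @format Named integer vector over [AA3].
#' @export
AA_HEAVY_ATOMS <- c(ALA = 5L, ARG = 11L, ASN = 8L, ASP = 8L, CYS = 6L,
                    GLN = 9L, GLU = 9L, GLY = 4L, HIS = 10L, ILE = 8L,
                    LEU = 8L, LYS = 9L, MET = 8L, PHE = 11L, PRO = 7L,
                    SER = 6L, THR = 7L, TRP = 14L, TYR = 12L, VAL = 7L)

# Backbone heavy-atom names. OXT (terminal carboxylate oxygen) is treated as
# backbone. Glycine's CA is special-cased to side chain in classify_atom_role.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Surface-like background residue frequencies
#'
#' Default per-residue background frequencies for the synthetic composition
#' generator: a charged/polar-heavy profile typical of solvent-exposed protein
#' surfaces (Lys/Glu/Asp/Arg frequent; Cys/Trp/Met rare). Values are a design
#' choice of the generator, normalised to sum to 1; they set the scale of
#' sampling noise per residue, so rare residues get the widest propensity
#' intervals, mirroring real surface statistics.
#'
#' @format Named numeric vector over [AA3], summing to 1.
#' @export
SURFACE_BACKGROUND <- c(ALA = 0.065, ARG = 0.060, ASN = 0.050, ASP = 0.075,
                        CYS = 0.010, GLN = 0.045, GLU = 0.090, GLY = 0.060,
                        HIS = 0.025, ILE = 0.045, LEU = 0.060, LYS = 0.095,
                        MET = 0.015, PHE = 0.030, PRO = 0.050, SER = 0.065,
                        THR = 0.060, TRP = 0.015, TYR = 0.035, VAL = 0.050)

# Zero-filled named count vector over the 20 standard residues.
empty_aa_counts <- function() {
  stats::setNames(numeric(length(AA3)), AA3)
}

# Turn a character vector of residue names into a named count vector over AA3.
# Non-standard names are dropped.
count_aa <- function(resnames) {
  counts <- empty_aa_counts()
  tab <- table(factor(resnames, levels = AA3))
  counts[names(tab)] <- as.numeric(tab)
  counts
}
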