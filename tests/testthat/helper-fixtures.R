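# In-code fixtures shared across the suite.

# A tiny hand-written PDB: three polymer residues (ALA, GLY, SER), one
# glycerol HET group, two waters. Coordinates are arbitrary but far enough
# apart to keep residues distinct.
tiny_pdb <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       3.200   1.600   0.000  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1       2.000  -1.200   0.900  1.00  0.00           C",
  "ATOM      6  N   GLY A   2       8.000   0.000   0.000  1.00  0.00           N",
  "ATOM      7  CA  GLY A   2       9.458   0.000   0.000  1.00  0.00           C",
  "ATOM      8  C   GLY A   2      10.000   1.400   0.000  1.00  0.00           C",
  "ATOM      9  O   GLY A   2      11.200   1.600   0.000  1.00  0.00           O",
  "ATOM     10  N   SER B   1      16.000   0.000   0.000  1.00  0.00           N",
  "ATOM     11  CA  SER B   1      17.458   0.000   0.000  1.00  0.00           C",
  "ATOM     12  C   SER B   1      18.000   1.400   0.000  1.00  0.00           C",
  "ATOM     13  O   SER B   1      19.200   1.600   0.000  1.00  0.00           O",
  "ATOM     14  CB  SER B   1      18.000  -1.200   0.900  1.00  0.00           C",
  "ATOM     15  OG  SER B   1      17.600  -2.500   0.500  1.00  0.00           O",
  "HETATM   16  C1  GOL A 101       4.000  -2.000   2.000  1.00  0.00           C",
  "HETATM   17  O1  GOL A 101       4.800  -2.900   2.400  1.00  0.00           O",
  "HETATM   18  C2  GOL A 101       4.500  -0.700   2.600  1.00  0.00           C",
  "HETATM   19  O   HOH A 201      25.000   0.000   0.000  1.00  0.00           O",
  "HETATM   20  O   HOH A 202      27.000   0.000   0.000  1.00  0.00           O",
  "END")

# Minimal protein+ligand structure from explicit atom rows; ligand atoms get
# record HETATM, everything else ATOM. Runs through the real parser so the
# object is exactly what the pipeline sees.
make_structure <- function(atoms, id = "test", annotations = NULL) {
  at <- atoms
  at$serial <- seq_len(nrow(at))
  at$icode <- ""
  lines <- bindprop:::write_pdb_lines(at)
  normalize_structure(parse_structure(lines, annotations = annotations,
                                      structure_id = id))
}

# One protein atom row.
prow <- function(name, el, resname, resno, x, y, z, chain = "A") {
  data.frame(name = name, element = el, resname = resname, chain = chain,
             resno = resno, x = x, y = y, z = z, record = "ATOM",
             stringsAsFactors = FALSE)
}

# One ligand atom row.
lrow <- function(name, el, het, resno, x, y, z, chain = "L") {
  data.frame(name = name, element = el, resname = het, chain = chain,
             resno = resno, x = x, y = y, z = z, record = "HETATM",
             stringsAsFactors = FALSE)
}

# A hand-made surface table (bp_surface) for threshold tests.
fake_surface <- function(df, id = "test") {
  df$icode <- ""
  df$abs_total <- df$abs_side + df$abs_main
  gly <- df$resname == "GLY"
  df$eff_side <- df$abs_side
  df$eff_main <- df$abs_main
  df$eff_side[gly] <- pmax(df$abs_side[gly], df$abs_main[gly])
  df$eff_main[gly] <- pmax(df$abs_side[gly], df$abs_main[gly])
  structure(list(structure_id = id, residues = df, atoms = NULL,
                 params = sasa_params()), class = "bp_surface")
}

# A hand-made binding site (bp_site) for dedup/summary/propensity tests.
fake_site <- function(resnames, categories = rep("SC", length(resnames)),
                      n_contacts = rep(2L, length(resnames)),
                      n_hbond = rep(0L, length(resnames)),
                      eff_area = rep(10, length(resnames)),
                      het = "LIG", validity = "valid", id = "s1",
                      chain = "A", cutoff = 5.0) {
  res <- data.frame(
    chain = chain, resno = seq_along(resnames), icode = "",
    resname = resnames, het_code = het, lig_chain = "L", lig_resno = 501L,
    lig_icode = "", category = categories, n_contacts = n_contacts,
    n_hbond = n_hbond, n_vdw = n_contacts - n_hbond,
    n_hb_bbN = 0L, n_hb_bbO = 0L, n_hb_sc = n_hbond,
    eff_side = eff_area, eff_main = eff_area, eff_area = eff_area,
    on_surface = eff_area >= cutoff, stringsAsFactors = FALSE)
  structure(list(structure_id = id, het_code = het, chain = "L",
                 resno = 501L, icode = "", validity = validity,
                 residues = res, counts = bindprop:::count_aa(resnames),
                 n_residues = nrow(res), site_sasa = sum(res$eff_area),
                 surface_cutoff = cutoff,
                 empty_surface = !any(res$on_surface)),
            class = "bp_site")
}

# Named enrichment vector helper.
enrich <- function(...) {
  k <- stats::setNames(rep(1, 20), AA3)
  ov <- c(...)
  k[names(ov)] <- ov
  k
}
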