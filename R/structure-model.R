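# Structure model: PDB biounit parsing, atom partitioning and atom roles.
#
# A parsed structure is a light S3 object ("bp_structure") holding one atom
# table plus a ligand-instance table. The biounit is kept as a single entity
# ("one entire protein"), however many chains it contains.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

TWO_LETTER_ELEMENTS <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA", "SE",
                         "CU", "NI", "CO", "CD", "HG", "IOD")

# Fallback element inference from the atom-name column, for files that omit
# the element field. Polymer atom names always start with the element letter
# once leading digits are stripped; ions commonly carry two-letter names.
infer_element <- function(name, is_polymer) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  out <- substr(nm, 1, 1)
  two <- !is_polymer & substr(nm, 1, 2) %in% TWO_LETTER_ELEMENTS
  out[two] <- substr(nm[two], 1, 2)
  out
}

#' Parse a PDB biounit into a typed structure model
#'
#' Reads ATOM/HETATM records and partitions every atom into one of three
#' groups: polymer (standard amino acids, plus configured modified residues
#' mapped to their parent), water, or ligand (any other HET group). Multimeric
#' assemblies are kept as one structure; each HET group that is not water
#' becomes one ligand instance, identified by (HET code, chain, residue
#' number, insertion code). Validity labels (biologically relevant "valid"
#' vs crystallographic additive "invalid") are taken from an annotation
#' table; unmatched instances are "unannotated".
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param annotations Optional ligand annotation table (see
#'   [read_ligand_annotations()]): columns `het_code`, `validity`, optionally
#'   `structure_id`, `chain`, `seqnum`, `icode`. Instance columns left `NA`
#'   match every instance of that HET code.
#' @param structure_id Identifier for the structure; defaults to the file
#'   base name or `"structure"`.
#' @param modres Named character vector mapping modified-residue codes to
#'   their parent amino acid (default `c(MSE = "MET")`). Non-water residues
#'   on ATOM records that are neither standard nor mapped are dropped with a
#'   warning.
#' @param model For multi-MODEL files, only the first model is read.
#' @return A `bp_structure`: list with `structure_id`, `atoms` (data frame
#'   with serial, name, altloc, resname, chain, resno, icode, x, y, z, occ,
#'   element, record, partition, role), `ligands` (instance table with
#'   validity), and `chain_count`.
#' @export
parse_structure <- function(pdb, annotations = NULL, structure_id = NULL,
                            modres = c(MSE = "MET"), model = 1L) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    lines <- readLines(path, warn = FALSE)
    if (is.null(structure_id))
      structure_id <- sub("\\.(pdb|ent)$", "", basename(path))
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path))
    if (is.null(structure_id)) structure_id <- "structure"
  }

  rec <- substr(lines, 1, 6)
  is_atom_line <- rec %in% c("ATOM  ", "HETATM")
  atom_lines <- lines[is_atom_line]
  lineno <- which(is_atom_line)
  if (length(atom_lines) == 0)
    stop("no ATOM/HETATM records found in '", structure_id, "'")
  bad <- nchar(atom_lines) < 54 |
    is.na(suppressWarnings(as.numeric(substr(atom_lines, 31, 38)))) |
    is.na(suppressWarnings(as.numeric(substr(atom_lines, 39, 46)))) |
    is.na(suppressWarnings(as.numeric(substr(atom_lines, 47, 54))))
  if (any(bad))
    stop("malformed ATOM/HETATM record at line ", lineno[which(bad)[1]],
         ": '", atom_lines[which(bad)[1]], "'")

  p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                        verbose = FALSE))
  a <- p$atom
  atoms <- data.frame(
    serial  = a$eleno,
    name    = toupper(trimws(a$elety)),
    altloc  = ifelse(is.na(a$alt), "", a$alt),
    resname = toupper(trimws(a$resid)),
    chain   = ifelse(is.na(a$chain), "", a$chain),
    resno   = a$resno,
    icode   = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ     = ifelse(is.na(a$o), 1, a$o),
    element = toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy))),
    record  = a$type,
    stringsAsFactors = FALSE
  )

  if (anyDuplicated(atoms$serial))
    warning("duplicate atom serial number(s) in '", structure_id,
            "'; keeping all records")

  # Partition.
  drop <- atoms$record == "ATOM" & !(atoms$resname %in% AA3) &
    !(atoms$resname %in% names(modres)) &
    !(atoms$resname %in% WATER_RESNAMES)
  if (any(drop)) {
    warning("dropping ", sum(drop), " ATOM record(s) with unmapped ",
            "non-standard residue name(s): ",
            paste(unique(atoms$resname[drop]), collapse = ", "))
    atoms <- atoms[!drop, , drop = FALSE]
  }
  std <- atoms$resname %in% AA3
  mapped <- atoms$resname %in% names(modres)
  water <- atoms$resname %in% WATER_RESNAMES
  partition <- rep("ligand", nrow(atoms))
  partition[std | mapped] <- "polymer"
  partition[water] <- "water"
  atoms$partition <- partition
  if (any(mapped))
    atoms$resname[mapped] <- unname(modres[atoms$resname[mapped]])

  blank <- atoms$element == ""
  if (any(blank))
    atoms$element[blank] <- infer_element(atoms$name[blank],
                                          atoms$partition[blank] == "polymer")

  atoms$role <- NA_character_
  pol <- atoms$partition == "polymer"
  atoms$role[pol] <- classify_atom_role(atoms$name[pol], atoms$resname[pol])

  lig <- atoms[atoms$partition == "ligand", , drop = FALSE]
  if (nrow(lig)) {
    key <- paste(lig$resname, lig$chain, lig$resno, lig$icode, sep = "\r")
    first <- !duplicated(key)
    ligands <- data.frame(het_code = lig$resname[first],
                          chain = lig$chain[first], resno = lig$resno[first],
                          icode = lig$icode[first],
                          validity = "unannotated",
                          stringsAsFactors = FALSE)
  } else {
    ligands <- data.frame(het_code = character(), chain = character(),
                          resno = integer(), icode = character(),
                          validity = character(), stringsAsFactors = FALSE)
  }

  s <- structure(list(structure_id = structure_id, atoms = atoms,
                      ligands = ligands,
                      chain_count = length(unique(atoms$chain[pol])),
                      normalized = FALSE),
                 class = "bp_structure")
  if (!is.null(annotations)) s <- annotate_ligands(s, annotations)
  s
}

#' Read a ligand annotation table
#'
#' TSV with columns `structure_id`, `het_code`, `chain`, `seqnum`, `icode`,
#' `validity` (`valid`/`invalid`). Instance columns may be `NA` to annotate
#' every instance of a HET code.
#'
#' @param path Path to the TSV file.
#' @return Data frame of annotations.
#' @export
read_ligand_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  stopifnot(all(c("het_code", "validity") %in% names(ann)))
  if (!all(ann$validity %in% c("valid", "invalid")))
    stop("validity must be 'valid' or 'invalid'")
  ann
}

# Apply validity annotations to the ligand-instance table.
annotate_ligands <- function(s, ann) {
  if (!nrow(s$ligands)) return(s)
  for (i in seq_len(nrow(ann))) {
    r <- ann[i, ]
    if (!is.null(r$structure_id) && !is.na(r$structure_id) &&
        r$structure_id != s$structure_id) next
    hit <- s$ligands$het_code == r$het_code
    if (!is.null(r$chain) && !is.na(r$chain))
      hit <- hit & s$ligands$chain == r$chain
    if (!is.null(r$seqnum) && !is.na(r$seqnum))
      hit <- hit & s$ligands$resno == r$seqnum
    if (!is.null(r$icode) && !is.na(r$icode))
      hit <- hit & s$ligands$icode == r$icode
    s$ligands$validity[hit] <- r$validity
  }
  s
}

#' Normalize a structure for geometric analysis
#'
#' Removes hydrogens (and deuteriums) everywhere and resolves alternate
#' locations by keeping, per atom site, the conformer with the highest
#' occupancy (ties broken by file order). Waters stay in their partition but
#' are excluded from all downstream geometry. Idempotent.
#'
#' @param s A `bp_structure`.
#' @param altloc_policy `"occupancy"` (default) or `"first"` (first conformer
#'   in file order regardless of occupancy).
#' @return The normalized `bp_structure`.
#' @export
normalize_structure <- function(s, altloc_policy = c("occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  a <- s$atoms
  a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  key <- paste(a$partition, a$chain, a$resno, a$icode, a$resname, a$name,
               sep = "\r")
  if (anyDuplicated(key)) {
    ord <- if (altloc_policy == "occupancy") {
      order(key, -a$occ, seq_len(nrow(a)))
    } else {
      order(key, seq_len(nrow(a)))
    }
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$partition, a$chain, a$resno, a$icode,
                             a$resname, a$name, sep = "\r")), , drop = FALSE]
    a <- a[order(match(a$serial, s$atoms$serial)), , drop = FALSE]
  }
  rownames(a) <- NULL
  s$atoms <- a
  # Drop ligand instances that lost all heavy atoms (e.g. hydrogen-only).
  if (nrow(s$ligands)) {
    la <- a[a$partition == "ligand", , drop = FALSE]
    keep <- paste(s$ligands$het_code, s$ligands$chain, s$ligands$resno,
                  s$ligands$icode) %in%
      paste(la$resname, la$chain, la$resno, la$icode)
    s$ligands <- s$ligands[keep, , drop = FALSE]
  }
  s$normalized <- TRUE
  s
}

#' Classify a polymer heavy atom as backbone or side chain
#'
#' Backbone atoms are N, CA, C, O and the terminal OXT; every other heavy
#' atom is side chain. Glycine is the special case: its CA is always
#' classified as side chain, so glycine can participate in side-chain
#' interactions despite having no side chain proper.
#'
#' @param name Atom name(s), e.g. `"CA"`, `"OD1"`.
#' @param resname Residue name(s), recycled against `name`.
#' @return Character vector, `"backbone"` or `"sidechain"`.
#' @export
classify_atom_role <- function(name, resname) {
  n <- max(length(name), length(resname))
  name <- rep_len(toupper(trimws(name)), n)
  resname <- rep_len(toupper(trimws(resname)), n)
  if (any(!resname %in% AA3))
    warning("non-standard residue name(s) ",
            paste(unique(resname[!resname %in% AA3]), collapse = ", "),
            "; classifying by atom-name convention")
  role <- ifelse(name %in% BACKBONE_ATOMS, "backbone", "sidechain")
  role[resname == "GLY" & name == "CA"] <- "sidechain"
  role
}

#' @export
print.bp_structure <- function(x, ...) {
  cat("<bp_structure>", x$structure_id, "\n")
  cat("  atoms:", nrow(x$atoms),
      sprintf("(polymer %d, ligand %d, water %d)",
              sum(x$atoms$partition == "polymer"),
              sum(x$atoms$partition == "ligand"),
              sum(x$atoms$partition == "water")), "\n")
  cat("  chains:", x$chain_count, " ligand instances:", nrow(x$ligands), "\n")
  invisible(x)
}

# Internal: polymer residue table (one row per residue).
polymer_residues <- function(s) {
  a <- s$atoms[s$atoms$partition == "polymer", , drop = FALSE]
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], resname = a$resname[first],
             stringsAsFactors = FALSE)
}

# Internal: atom table for one ligand instance (row of s$ligands).
ligand_atoms <- function(s, lig) {
  a <- s$atoms
  a[a$partition == "ligand" & a$resname == lig$het_code &
      a$chain == lig$chain & a$resno == lig$resno & a$icode == lig$icode, ,
    drop = FALSE]
}
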