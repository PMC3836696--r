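Package: bindprop
Title: Residue Composition and Propensity Analysis of Protein-Ligand Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the amino-acid composition of protein-ligand
    binding sites in biological assemblies. Detects ligand-protein heavy-atom
    contacts with geometric hydrogen-bond and van der Waals typing, computes
    per-residue solvent-accessible surface areas (Shrake-Rupley) split into
    side-chain and backbone components, assembles and deduplicates binding
    sites, pools residue frequencies across structures to compute binding-site
    propensities relative to the protein surface, and quantifies their
    significance with leave-10%-out resampling, validity-label permutation
    nulls, set-size convergence scans and subgroup-versus-random comparisons.
    Includes a synthetic-data generator producing both abstract composition
    datasets with known ground truth and toy protein-ligand complexes in PDB
    format for end-to-end geometric validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
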