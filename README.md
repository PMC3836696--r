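# bindprop

Residue composition and propensity analysis of protein–ligand binding
sites.

## What this is for

Binding sites are patches of a protein's surface, so the interesting
question is not "which residues appear in binding sites" but "which
residues appear there *more than the surface as a whole would predict*".
`bindprop` implements the full analysis chain for that question over
corpora of protein–ligand complexes in biological-assembly (biounit) PDB
form, for structural bioinformaticians studying molecular recognition or
building binding-site prediction scores:

* **Geometry** — binding sites as all residues with a heavy atom within
  4.0 Å of a ligand heavy atom; contacts typed as hydrogen bond (≤3.5 Å,
  both atoms non-carbon) or van der Waals; residue interactions
  categorized side-chain (SC) vs backbone-only (BB-only), with glycine's
  CA always counting as side chain.
* **Surface** — an in-package Shrake–Rupley SASA engine (water-sized
  probe, deterministic golden-spiral quadrature) producing per-residue
  side-chain (`abs_side`) and backbone (`abs_main`) absolute areas;
  surface residues defined by an inclusive cutoff (5.0 or 0.5 Å²), with
  the glycine max rule.
* **Sites** — per-biounit deduplication of symmetry-equivalent sites
  (identical ligand + identical residue-type counts), surface filtering,
  site SASA.
* **Statistics** — pooled frequencies and the propensity
  `P_i = F_i^BS / F_i^PS` (counts summed across sites/proteins *before*
  division), separately for valid (biologically relevant) vs invalid
  (crystallization additive) ligands, plus the valid/invalid ratio.
* **Significance** — leave-10%-out percentile bounds, a validity-label
  permutation null for the ratio, set-size convergence scans, and
  subgroup-vs-random comparison with disjoint-interval flagging.
* **Synthetic data** — generators for abstract composition datasets with
  known ground truth and for toy PDB complexes with enumerable contacts
  and burial states, so every stage is testable against brute force.

The package is organised as an analysis workflow: the numbered scripts in
`analysis/` drive the study end to end and write tables under `results/`,
while all computation lives in the package functions.

## Worked example

Generate a synthetic corpus of 500 proteins whose valid binding sites are
enriched 2× in Trp and depleted to 0.6× in Glu, then recover those factors
and test their significance:

```r
library(bindprop)

k <- setNames(rep(1, 20), AA3); k[["TRP"]] <- 2.0; k[["GLU"]] <- 0.6
ds <- generate_composition_dataset(
  composition_spec(n_proteins = 500, enrichment_valid = k, seed = 7))
ds
#> <bp_composition> 500 proteins, 1893 sites ( 1143 valid / 750 invalid )

p <- composition_propensity(ds, "valid")
subset(p, resname %in% c("TRP", "GLU", "LYS"))
#>  resname freq_bs freq_ps propensity
#>      GLU   0.053   0.091      0.585
#>      LYS   0.096   0.095      1.012
#>      TRP   0.029   0.015      1.979
```

The pooled propensities (0.585, 1.012, 1.979) recover the generator's
ground truth (0.613, 1.021, 2.043) to within sampling error. Leave-10%-out
resampling quantifies that error:

```r
leave_k_out(ds, resample_config(n_reps = 1000, seed = 8))$summary
#>  resname median lower upper    sd
#>      GLU  0.585 0.570 0.599 0.007
#>      LYS  1.012 0.993 1.030 0.010
#>      TRP  1.980 1.909 2.044 0.035
```

and the label-shuffle null decides which valid/invalid differences are
significant — here both injected effects escape the null envelope while
the null means stay at 1:

```r
shuffle_validity_null(ds, n_shuffles = 1000, seed = 9)$summary
#>  resname observed_ratio null_mean null_min null_max significant_envelope
#>      GLU          0.538     1.007    0.820    1.205                 TRUE
#>      TRP          1.585     1.006    0.725    1.317                 TRUE
```

For real structures, `run_full_analysis(run_config(...))` executes the
geometric pipeline (parse → normalize → SASA → contacts → sites → dedup →
propensities) over a directory of biounit PDB files plus a ligand
annotation TSV, writing per-site tables, contact summaries, propensity
tables and a manifest. The `analysis/` scripts show the intended sequence
on generated data:

```sh
Rscript analysis/01_simulate_composition.R   # study-scale dataset + truth
Rscript analysis/02_toy_geometry.R           # geometry pipeline vs truth
Rscript analysis/03_propensities.R           # propensities + ligand bias
Rscript analysis/04_significance.R           # resampling significance
```

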