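---
title: "Residue composition of protein-ligand binding sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue composition of protein-ligand binding sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindprop)
```

## The question

A ligand binding site is a patch of a protein's surface, so asking "which
amino acids are over-represented in binding sites?" only makes sense relative
to the composition of the surface as a whole. Arginine is abundant in binding
sites, but it is abundant everywhere on protein surfaces; tryptophan is rare
in binding sites in absolute terms but far more common there than its scarce
surface presence would predict. `bindprop` implements the full chain of
computation needed to make that comparison rigorously: geometric definition
of binding sites in biological assemblies, a solvent-accessibility filter,
pooled frequency and propensity statistics, and resampling machinery that
says which differences are real.

A second axis of the analysis is the distinction between *valid* ligands
(substrates, products, cofactors, drugs — biologically meaningful binding)
and *invalid* ones (sulfate, glycerol, and other crystallization additives
that stick to proteins opportunistically). Curated databases of complexes
annotate each bound HET group with such a label. Comparing valid against
invalid sites acts as an experimental control: a residue that merely makes
surfaces "sticky" for any small molecule shows up in both classes, while a
residue truly tied to functional recognition is biased toward valid sites.

## Site definition and contact typing

A binding site is the set of protein residues with at least one heavy (non
hydrogen) atom within **4.0 Å** (inclusive) of any heavy atom of a ligand
instance. Each residue-ligand interaction is categorized as:

* **SC** — at least one contacting protein atom is a side-chain atom
  (contacts through side chain only, or side chain plus backbone);
* **BB-only** — every contacting atom is backbone (N, CA, C, O, OXT).

Glycine is the deliberate exception: its CA is always treated as side chain,
so glycine contacts are SC. This keeps glycine — which dominates
backbone-mediated recognition — comparable with the other residues in the
SC statistics.

Atomic contacts are typed geometrically, with no angle criterion or
donor/acceptor typing (these are intractable and unnecessary at corpus
scale):

* distance ≤ 3.5 Å and both atoms non-carbon (N, O, S, P, ...) → hydrogen
  bond;
* everything else within 4.0 Å → van der Waals.

Both cutoffs are inclusive; the test suite pins the boundary behaviour with
binary-exact coordinates at exactly 3.5 and 4.0 Å. A residue within range
of two ligands is counted independently in each ligand's site. Waters,
hydrogens, and alternate conformations are removed beforehand (highest
occupancy wins, ties to file order); the biological assembly is treated as
one protein, so contacts across chain boundaries are ordinary contacts.

## Surface definition

Solvent-accessible surface area is computed with a Shrake–Rupley point
quadrature: each atom is expanded by the probe radius (1.4 Å, a water
molecule), covered with a deterministic golden-spiral point set (960 points
by default), and the exposed fraction of points scales the analytic sphere
area. The layout is seed-free, so SASA values are reproducible bit for bit.
Ligands and waters are removed before the calculation — the surface is that
of the unliganded protein. Radii default to a protein-atom set (C 1.87,
N 1.65, O 1.40, S 1.85 Å) and are fully configurable.

Per residue we report `abs_side` (sum of side-chain atom areas, glycine's CA
counting as side chain) and `abs_main` (backbone atom areas). A residue is a
*surface* residue when its class-appropriate area meets the cutoff
(inclusive): `abs_side` for SC analyses, `abs_main` for BB-only, and for
glycine the larger of the two in both cases. Two cutoffs matter in practice:
**5.0 Å²** (the standard definition) and **0.5 Å²** (a permissive variant).
The permissive cutoff admits many barely-exposed residues that contribute
negligible area, which distorts surface frequencies toward hydrophobic
residues; the package supports both so the comparison can be made, and uses
5.0 Å² by default. At 960 quadrature points the isolated-sphere area is
accurate to well under 2%, and adding a neighbour can only decrease an
atom's area (monotone burial) — both are enforced by tests.

Terminal OXT is classified as backbone; the alternative (side chain) would
only affect the C-terminal residue of each chain.

## Deduplication within biounits

Biological assemblies are often multimeric, with the same ligand bound in
several symmetry-equivalent pockets. Counting each copy would over-weight
multimeric proteins, so within one structure, sites of the same HET code
whose residue-type count vectors are identical collapse to a single
representative (first in instance order). Sites of the same ligand with
*different* count vectors are all retained: they represent genuine
variability of the binding. Identity is judged on residue-type counts only,
not chain or position — two symmetry mates with the same composition are the
same site. Deduplication never crosses structures; non-redundancy *across*
proteins is a property of the input set (e.g. one representative per 90%
sequence-identity family) and is out of scope here.

Sites whose contacting residues are all buried below the SASA cutoff
("empty-surface" sites, typically slivers that cannot fit a probe) are
excluded from frequency pools but retained in raw-contact summaries.

## The propensity statistic

For amino acid $i$, the propensity is the ratio of pooled frequencies

$$P_i = \frac{F_i^{BS}}{F_i^{PS}}, \qquad
F_i^{BS} = \frac{\sum_j n_{ij}}{\sum_j N_j}, \qquad
F_i^{PS} = \frac{\sum_p m_{ip}}{\sum_p M_p},$$

where $n_{ij}$ counts residue $i$ on the surface of binding site $j$ and
$m_{ip}$ counts it on the surface of protein $p$. Counts are summed across
sites and proteins **before** division. This pooling is essential: per-protein
propensities divide by tiny, often zero, surface counts for rare residues
(cysteine, tryptophan), producing undefined or wildly unstable values. When
a pooled surface frequency is still zero, the propensity is flagged
undefined rather than clamped or dropped. Only proteins that contain at
least one site of the configuration being analysed (SC/BB-only ×
valid/invalid) enter the surface denominator. $P_i = 1$ means no bias;
values are ratios of ratios, so they are naturally displayed on log axes.

The valid/invalid *ratio* $P_i^{valid}/P_i^{invalid}$ is the control
statistic: it cancels surface composition entirely and isolates the
difference between functional and opportunistic binding.

## Significance machinery

All stochastic operations take an explicit integer seed and are exactly
reproducible.

* **Leave-10%-out.** The pooled propensity is recomputed on random 90%
  subsets of the *proteins* (never of the sites), and the median with
  empirical 2.5/97.5 percentiles (linear interpolation) summarizes the
  replicate distribution. This measures the stability of the estimate under
  perturbation of the corpus.
* **Label-shuffle null.** Valid/invalid labels are permuted over sites —
  preserving class proportions, leaving protein membership untouched — and
  the ratio recomputed per shuffle. The per-residue mean over shuffles sits
  at 1 (the acceptance script verifies this to within 0.05), and the
  min/max envelope gives a dataset-specific significance band; observed
  ratios outside it are significant. The conventional fixed thresholds
  (>1.2 or <0.8) are reported alongside for comparison but are not the
  decision rule, because the width of the honest envelope depends on how
  rare the residue is.
* **Set-size convergence.** Propensities are recomputed on random subsets of
  increasing size (by default every 1% of the corpus, 100 subsets per size;
  a fixed-size table at {100, 500, 1000, 2000} structures with percentiles
  is also provided). Dispersion falls with size for every residue, and rare
  residues need far larger sets than frequent ones before their propensities
  stabilize — the practical message being that propensity studies on a few
  hundred structures are unreliable for rare residues.
* **Subgroup vs random.** To ask whether a subgroup (e.g. non-enzymes)
  differs from the corpus, its leave-10%-out interval is compared with the
  interval of propensities from random subsets of the same size; a residue
  is flagged only when the two 95% intervals are disjoint. This is the
  strictest variant of the criterion — any overlap withholds the flag.

## The synthetic-data generator

The generator produces the two kinds of input the analysis needs, each with
ground truth sufficient to recompute every expected value by brute force.

**Composition datasets** bypass geometry entirely: per protein a multinomial
draw of surface residues from a background profile, per site a multinomial
draw from background × enrichment. Defaults are fixed at the scale of a
curated biounit corpus: every protein has at least one valid site, ~2.34
valid and ~1.49 invalid sites per protein, and valid sites are about five
times larger than invalid ones (11.4 vs 3.6 residues on average; surface
~350 residues per protein). The background is a charged/polar-heavy,
surface-like profile (Lys 9.5%, Glu 9% ... Trp 1.5%, Cys 1%), chosen once so
that rare residues genuinely behave like rare residues (wide intervals, slow
convergence). One subtlety: if site probabilities are
$\propto b_i k_i$, the asymptotic propensity is $k_i / \sum_j b_j k_j$, not
$k_i$. The generator therefore normalizes the requested enrichment vector so
that $\sum_j b_j k_j = 1$ and stores the normalized vector as the ground
truth; "recovered propensity equals the enrichment" then holds exactly in
the large-sample limit, and relative enrichments are preserved.

**Toy complexes** exist solely to exercise the geometry end to end. Shell
residues are anchored at scripted distances straddling the 3.5/4.0 Å
boundaries, with anchor atoms chosen to hit every typing rule (backbone vs
side-chain anchors, carbon vs non-carbon elements, glycine CA); four
boundary residues sit at binary-exact 3.5/4.0 Å offsets from a dedicated
reference atom. Buried decoy residues are enclosed in a 180-atom carbon cage
(radius 4.2 Å) so their expected SASA is zero; the generator verifies
burial itself with a random-direction probe test and refuses to emit an
uncaged decoy. All coordinates are rounded to PDB precision *before* the
ground truth is computed, so truth and file agree exactly, and the truth
contact list comes from a deliberately naive all-pairs loop independent of
the package's contact code. The toys are not physically meaningful proteins
— no rotamers, no realistic bond geometry — and nothing downstream assumes
they are.

What passing tests on synthetic data do and do not show: they verify the
estimators, the resampling calibration and the geometric rules exactly as
specified, under multinomial sampling. Real corpora add phylogenetic
correlation between proteins, ligand-class structure, and annotation errors
that the generator does not emulate; conclusions about real data still
require the convergence and subgroup checks above on that data.

## Numerical and design choices

* Distance comparisons are inclusive at both cutoffs; equality is exercised
  with binary-exact coordinates.
* Altloc resolution keeps the highest-occupancy conformer, ties to file
  order; MSE maps to MET by default (configurable); unmapped non-standard
  polymer residues are dropped with a warning; every non-water HETATM group
  is a ligand candidate.
* Element symbols come from the PDB element column when present, otherwise
  from atom-name conventions.
* Site identity for deduplication uses total residue-type counts; a variant
  distinguishing SC from BB-only roles during deduplication would split some
  symmetry mates, and was not adopted.
* Percentiles are empirical with linear interpolation (R's default type 7).
* Undefined (zero-denominator) propensities stay `NA` with a flag — never
  infinity, never silently dropped.
* The glycine max rule is applied uniformly wherever surface membership is
  decided, including the protein-surface denominator.

## Problem sizes

The analysis scripts and the acceptance checks run at desk scale, chosen as
the sizes at which each property is statistically decidable: 2000–2500
synthetic proteins (~7,600 sites) for propensity recovery and convergence,
800 proteins (~3,000 sites, ≥1000 per class) for the shuffle null with 1000
shuffles, 1000 replicates per resampling operation, and toy complexes of
25–65 residues for exact geometric checks. Estimators are identical at any
scale; only interval widths change.

## Known limitations

* The SASA engine is quadrature-based; per-atom areas carry percent-level
  discretization error (the slice-based reference areas of classic
  implementations differ at the same level by radii choice). Cutoff
  semantics are unaffected.
* No mmCIF input; assemblies must be pre-expanded biounit PDB files.
* Hydrogen-bond typing is distance-only by design; it overcounts relative
  to angle-aware definitions.
* Sequence-level redundancy of the input corpus must be handled upstream.
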