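#!/usr/bin/env Rscript
# Stage 3: pooled frequencies, propensities and valid/invalid ratios.
#
# Computes the pooled propensity per residue for valid and invalid sites,
# compares the valid-class estimates against the generator's ground truth,
# and reports the valid/invalid ratio together with the effect of excluding
# the most frequent ligands.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))
dir.create("results", showWarnings = FALSE)

ds <- study_dataset()
pv <- composition_propensity(ds, "valid")
pi_ <- composition_propensity(ds, "invalid")
ratio <- propensity_ratio(pv, pi_)

truth <- unname(ds$truth$propensity_valid)
rel <- abs(pv$propensity / truth - 1)
message(sprintf(
  "valid-class propensity recovery: max rel. error %.3f (common residues), %.3f (rare)",
  max(rel[SURFACE_BACKGROUND >= 0.02]), max(rel[SURFACE_BACKGROUND < 0.02])))

out <- data.frame(resname = AA3,
                  freq_surface = pv$freq_ps,
                  freq_valid_sites = pv$freq_bs,
                  freq_invalid_sites = pi_$freq_bs,
                  propensity_valid = pv$propensity,
                  propensity_invalid = pi_$propensity,
                  true_propensity_valid = truth,
                  ratio_valid_invalid = ratio$ratio)
write.table(format(out, digits = 4), "results/propensities.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# Ligand-bias check: drop sites of the 3 most frequent HET codes per class.
kept <- exclude_top_ligands(ds$site_info, 3)
message(sprintf(
  "top-3 ligand exclusion: %d of %d sites remain (invalids shrink most: %d -> %d)",
  nrow(kept), nrow(ds$site_info),
  sum(ds$site_info$validity == "invalid"),
  sum(kept$validity == "invalid")))
keep_idx <- as.integer(rownames(kept))
ds2 <- ds
ds2$site_counts <- ds$site_counts[keep_idx, , drop = FALSE]
ds2$site_info <- ds$site_info[keep_idx, , drop = FALSE]
pv2 <- composition_propensity(ds2, "valid")
shift <- data.frame(resname = AA3,
                    propensity_all = pv$propensity,
                    propensity_excl_top3 = pv2$propensity,
                    shift = pv2$propensity - pv$propensity)
write.table(format(shift, digits = 4), "results/ligand_bias.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/propensities.tsv and results/ligand_bias.tsv")
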