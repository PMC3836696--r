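test_that("composition datasets are deterministic and conserve totals", {
  sp <- composition_spec(n_proteins = 50, seed = 31)
  d1 <- generate_composition_dataset(sp)
  d2 <- generate_composition_dataset(sp)
  expect_identical(d1, d2)
  expect_false(identical(
    d1$site_counts,
    generate_composition_dataset(composition_spec(n_proteins = 50,
                                                  seed = 32))$site_counts))
  # multinomial totals conserved
  expect_equal(unname(rowSums(d1$site_counts)),
               as.numeric(d1$site_info$size))
  expect_true(all(rowSums(d1$surface_counts) >= 20))
  # every protein has at least one valid site
  expect_setequal(unique(d1$site_info$protein[d1$site_info$validity ==
                                                "valid"]), 1:50)
})

test_that("a null generator recovers propensity 1 for every residue", {
  ds <- generate_composition_dataset(composition_spec(n_proteins = 500,
                                                      seed = 33))
  expect_equal(unname(ds$truth$propensity_valid), rep(1, 20))
  p <- composition_propensity(ds, "valid")
  expect_true(all(abs(p$propensity - 1) < 0.3))   # binomial-error bound
  common <- SURFACE_BACKGROUND >= 0.04
  expect_true(all(abs(p$propensity[common] - 1) < 0.1))
})

test_that("normalized enrichment equals the asymptotic propensity", {
  k <- enrich(TRP = 2.25, GLU = 0.5)
  sp <- composition_spec(n_proteins = 10, enrichment_valid = k, seed = 1)
  ds <- generate_composition_dataset(sp)
  kv <- ds$truth$propensity_valid
  bg <- ds$truth$background
  expect_equal(sum(bg * kv), 1)
  expect_equal(unname(ds$truth$site_freq_valid / bg), unname(kv))
  # relative ordering of the requested enrichment is preserved
  expect_equal(unname(kv["TRP"] / kv["GLU"]), 2.25 / 0.5)
})

test_that("toy complexes match an independent all-pairs distance scan", {
  tc <- generate_toy_complex(toy_complex_spec(n_shell_residues = 30,
                                              seed = 37))
  at <- tc$atoms
  pol <- at[at$record == "ATOM", ]
  lig <- at[at$record == "HETATM", ]
  # test-local vectorized oracle, independent of the generator's loop
  d <- sqrt(outer(pol$x, lig$x, "-")^2 + outer(pol$y, lig$y, "-")^2 +
              outer(pol$z, lig$z, "-")^2)
  hits <- which(d <= 4.0, arr.ind = TRUE)
  expect_equal(nrow(tc$truth$contacts), nrow(hits))
  ord_t <- order(tc$truth$contacts$resno, tc$truth$contacts$protein_atom,
                 tc$truth$contacts$ligand_atom)
  ord_h <- order(pol$resno[hits[, 1]], pol$name[hits[, 1]],
                 lig$name[hits[, 2]])
  expect_equal(tc$truth$contacts$distance[ord_t],
               d[hits][ord_h])
  hb <- d[hits][ord_h] <= 3.5 &
    pol$element[hits[, 1]][ord_h] != "C" &
    lig$element[hits[, 2]][ord_h] != "C"
  expect_equal(tc$truth$contacts$interaction[ord_t],
               ifelse(hb, "hbond", "vdw"))
})

test_that("boundary residues pin the inclusive cutoffs exactly", {
  tc <- generate_toy_complex(toy_complex_spec(n_shell_residues = 4,
                                              seed = 41))
  ctc <- tc$truth$contacts
  ctc <- ctc[ctc$ligand_atom == "O99", ]   # the clean-coordinate reference
  b401 <- ctc[ctc$resno == 401 & ctc$protein_atom == "OG", ]
  expect_equal(b401$distance, 3.5)
  expect_equal(b401$interaction, "hbond")      # non-carbon pair at 3.5
  b402 <- ctc[ctc$resno == 402 & ctc$protein_atom == "CB", ]
  expect_equal(b402$interaction, "vdw")        # carbon rule at 3.5
  b403 <- ctc[ctc$resno == 403 & ctc$protein_atom == "NZ", ]
  expect_equal(b403$distance, 4.0)             # in range exactly at 4.0
  expect_equal(b403$interaction, "vdw")
  expect_false(any(ctc$resno == 404))          # 4.5 A anchor out of range
})

test_that("generated PDB text round-trips through the parser", {
  tc <- generate_toy_complex(toy_complex_spec(n_shell_residues = 8,
                                              seed = 43))
  s <- normalize_structure(parse_structure(tc$pdb))
  expect_equal(nrow(s$atoms), nrow(tc$atoms))
  expect_equal(nrow(s$ligands), 1)
  expect_equal(s$ligands$het_code, "LIG")
  # elements survive the round trip
  m <- merge(s$atoms[, c("serial", "element")],
             tc$atoms[, c("serial", "element")], by = "serial")
  expect_equal(m$element.x, m$element.y)
})

test_that("enzyme splits label proteins and apply subgroup enrichment", {
  ds <- generate_composition_dataset(composition_spec(n_proteins = 80,
                                                      seed = 47))
  null_split <- generate_enzyme_split(ds, fraction_enzyme = 0.5, seed = 48)
  expect_equal(sum(null_split$enzyme), 40)
  expect_identical(null_split$site_counts, ds$site_counts)  # no redraw
  expect_equal(unname(null_split$truth$propensity_subgroup),
               unname(ds$truth$propensity_valid))
  enr <- generate_enzyme_split(ds, fraction_enzyme = 0.5,
                               subgroup_enrichment = enrich(LEU = 1.3),
                               seed = 48)
  expect_false(identical(enr$site_counts, ds$site_counts))
  expect_gt(enr$truth$propensity_subgroup[["LEU"]],
            ds$truth$propensity_valid[["LEU"]])
  full <- generate_enzyme_split(ds, fraction_enzyme = 1, seed = 49)
  expect_true(all(full$enzyme))
})
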