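test_that("contact detection is inclusive at 4.0 A", {
  # ligand O at origin-ish, protein N at scripted axial distances
  base <- lrow("O1", "O", "LIG", 501, 0, 0, 0)
  s1 <- make_structure(rbind(prow("N", "N", "THR", 1, 3.9, 0, 0),
                             prow("CA", "C", "THR", 1, 8, 0, 0), base))
  ct <- find_contacts(s1, 1)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$distance, 3.9)
  s2 <- make_structure(rbind(prow("N", "N", "THR", 1, 4.05, 0, 0),
                             prow("CA", "C", "THR", 1, 8, 0, 0), base))
  expect_equal(nrow(find_contacts(s2, 1)), 0)
  s3 <- make_structure(rbind(prow("N", "N", "THR", 1, 4.0, 0, 0),
                             prow("CA", "C", "THR", 1, 8, 0, 0), base))
  ct3 <- find_contacts(s3, 1)
  expect_equal(nrow(ct3), 1)          # boundary included
  expect_equal(ct3$interaction, "vdw") # beyond 3.5 -> vdw even for N...O
})

test_that("interaction typing follows the distance and carbon rules", {
  expect_equal(classify_contact_type("N", "O", 3.2), "hbond")
  expect_equal(classify_contact_type("C", "O", 3.2), "vdw")
  expect_equal(classify_contact_type("N", "C", 3.2), "vdw")
  expect_equal(classify_contact_type("N", "O", 3.8), "vdw")
  expect_equal(classify_contact_type("N", "O", 3.5), "hbond") # inclusive
  expect_equal(classify_contact_type("S", "P", 3.4), "hbond")
  # vectorized
  expect_equal(classify_contact_type(c("N", "C"), c("O", "O"), c(3.0, 3.0)),
               c("hbond", "vdw"))
})

test_that("a residue near two ligands joins both binding sites independently", {
  atoms <- rbind(prow("OG", "O", "SER", 1, 0, 0, 0),
                 prow("CB", "C", "SER", 1, 0, 0, 9),
                 lrow("O1", "O", "GOL", 501, 3.0, 0, 0),
                 lrow("O1", "O", "EDO", 502, -3.0, 0, 0))
  s <- make_structure(atoms)
  expect_equal(nrow(s$ligands), 2)
  c1 <- find_contacts(s, which(s$ligands$het_code == "GOL"))
  c2 <- find_contacts(s, which(s$ligands$het_code == "EDO"))
  expect_equal(c1$resno, 1)
  expect_equal(c2$resno, 1)
  expect_equal(c1$interaction, "hbond")
})

test_that("SC/BB-only classification is exclusive and follows the Gly rule", {
  mk <- function(atom, role, resname = "ALA") data.frame(
    chain = "A", resno = 1L, icode = "", resname = resname,
    protein_atom = atom, protein_role = role, protein_element = "C",
    het_code = "LIG", lig_chain = "L", lig_resno = 501L, lig_icode = "",
    ligand_atom = "O1", ligand_element = "O", distance = 3.8,
    interaction = "vdw", stringsAsFactors = FALSE)
  sc <- classify_residue_interaction(mk("CB", "sidechain"))
  expect_equal(sc$category, "SC")
  bb <- classify_residue_interaction(rbind(mk("N", "backbone"),
                                           mk("O", "backbone")))
  expect_equal(bb$category, "BB_only")
  expect_equal(bb$n_contacts, bb$n_hbond + bb$n_vdw)
  gly <- classify_residue_interaction(mk("CA", "sidechain", "GLY"))
  expect_equal(gly$category, "SC")
  mixed <- classify_residue_interaction(rbind(mk("N", "backbone"),
                                              mk("CB", "sidechain")))
  expect_equal(mixed$category, "SC")
  expect_error(classify_residue_interaction(mk("CB", "sidechain")[0, ]),
               "empty")
})

test_that("contact sets are nested in the cutoff and types are exhaustive", {
  tc <- generate_toy_complex(toy_complex_spec(n_shell_residues = 40,
                                              buried_decoy_count = 0,
                                              seed = 13))
  s <- normalize_structure(parse_structure(tc$pdb))
  c40 <- find_contacts(s, 1, cutoff = 4.0)
  c35 <- find_contacts(s, 1, cutoff = 3.5)
  key <- function(d) paste(d$resno, d$protein_atom, d$ligand_atom)
  expect_true(all(key(c35) %in% key(c40)))
  expect_equal(sum(c40$interaction == "hbond") +
                 sum(c40$interaction == "vdw"), nrow(c40))
  ri <- bindprop:::residue_interactions(c40)
  expect_true(all(ri$category %in% c("SC", "BB_only")))
  expect_equal(sum(ri$n_contacts), nrow(c40))
})

test_that("the per-residue summary equals a brute-force recount", {
  sites <- list(
    fake_site("ALA", n_contacts = 4L),
    fake_site(c("SER", "SER"), n_contacts = c(5L, 7L), n_hbond = c(1L, 2L)),
    fake_site(c("TRP", "GLY", "ALA"), n_contacts = c(9L, 3L, 2L),
              categories = c("SC", "SC", "SC"), validity = "invalid"))
  tab <- summarize_contacts(sites)
  v <- tab[tab$validity == "valid", ]
  expect_equal(v$contacts_per_res[v$resname == "ALA"], 4.0)
  expect_equal(v$contacts_per_ha[v$resname == "ALA"], 4 / 5)
  expect_equal(v$contacts_per_res[v$resname == "SER"], 6.0)
  expect_equal(v$pct_site[v$resname == "SER"], 100 * 2 / 3)
  iv <- tab[tab$validity == "invalid", ]
  expect_equal(iv$contacts_per_res[iv$resname == "TRP"], 9)
  expect_equal(iv$contacts_per_ha[iv$resname == "TRP"], 9 / 14)

  # scripted 10-site fixture vs an independent naive tally
  set.seed(17)
  sites10 <- lapply(1:10, function(i) {
    nres <- sample(2:6, 1)
    fake_site(sample(AA3, nres, replace = TRUE),
              n_contacts = sample(1:10, nres, replace = TRUE))
  })
  tab10 <- summarize_contacts(sites10)
  # naive loops
  tot <- list()
  for (st in sites10) for (i in seq_len(nrow(st$residues))) {
    aa <- st$residues$resname[i]
    tot[[aa]] <- c(tot[[aa]], st$residues$n_contacts[i])
  }
  for (aa in names(tot)) {
    row <- tab10[tab10$resname == aa, ]
    expect_equal(row$n_residues, length(tot[[aa]]))
    expect_equal(row$contacts_per_res, mean(tot[[aa]]))
  }
  # surface filter drops sub-cutoff residues
  mixed <- list(fake_site(c("ALA", "VAL"), eff_area = c(10, 1)))
  tabf <- summarize_contacts(mixed, surface_cutoff = 5)
  expect_equal(tabf$n_residues[tabf$resname == "VAL"], 0)
  expect_equal(tabf$n_residues[tabf$resname == "ALA"], 1)
})
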