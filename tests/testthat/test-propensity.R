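test_that("frequencies pool counts before division", {
  ft <- accumulate_frequencies(list(c("ALA"), c("ARG")), "binding_site")
  expect_equal(unname(ft$frequencies[c("ALA", "ARG")]), c(0.5, 0.5))
  ft2 <- accumulate_frequencies(list(c("TRP", "TRP", "ALA", "ALA")),
                                "binding_site")
  expect_equal(unname(ft2$frequencies["TRP"]), 0.5)
  expect_equal(sum(ft2$frequencies), 1)
  # matrix input pools identically
  m <- rbind(bindprop:::count_aa(c("ALA", "GLY")),
             bindprop:::count_aa(c("GLY", "GLY")))
  ft3 <- accumulate_frequencies(m, "protein_surface")
  expect_equal(unname(ft3$counts[c("ALA", "GLY")]), c(1, 3))
  expect_error(accumulate_frequencies(list(character(0)), "binding_site"),
               "zero total")
})

test_that("propensities are frequency ratios with undefined flags", {
  bs <- accumulate_frequencies(list(rep("TRP", 4), rep("ALA", 96)),
                               "binding_site")
  ps <- accumulate_frequencies(list(rep("TRP", 2), rep("ALA", 98)),
                               "protein_surface")
  p <- compute_propensity(bs, ps)
  expect_equal(p$propensity[p$resname == "TRP"], 2.0)
  # identical distributions -> propensity exactly 1
  p1 <- compute_propensity(
    accumulate_frequencies(list(c("ALA", "GLY")), "binding_site"),
    accumulate_frequencies(list(c("ALA", "GLY", "ALA", "GLY")),
                           "protein_surface"))
  expect_equal(p1$propensity[p1$resname %in% c("ALA", "GLY")], c(1, 1))
  # zero surface frequency -> undefined, not infinite
  bs0 <- accumulate_frequencies(list(c("CYS", "ALA")), "binding_site")
  ps0 <- accumulate_frequencies(list(rep("ALA", 10)), "protein_surface")
  p0 <- compute_propensity(bs0, ps0)
  expect_true(p0$undefined[p0$resname == "CYS"])
  expect_true(is.na(p0$propensity[p0$resname == "CYS"]))
  # configuration mismatch
  bs_bb <- accumulate_frequencies(list("ALA"), "binding_site",
                                  class = "BB_only")
  expect_error(compute_propensity(bs_bb, ps), "mismatch")
})

test_that("valid/invalid ratios divide propensities and propagate NA", {
  bs <- accumulate_frequencies(list(rep("ALA", 6), rep("GLY", 4)),
                               "binding_site")
  ps <- accumulate_frequencies(list(rep("ALA", 5), rep("GLY", 5)),
                               "protein_surface")
  pv <- compute_propensity(bs, ps)
  r1 <- propensity_ratio(pv, pv)
  expect_equal(r1$ratio[r1$resname == "ALA"], 1)
  bs2 <- accumulate_frequencies(list(rep("ALA", 4), rep("GLY", 6)),
                                "binding_site")
  pi_ <- compute_propensity(bs2, ps)
  r2 <- propensity_ratio(pv, pi_)
  expect_equal(r2$ratio[r2$resname == "ALA"], 1.2 / 0.8)
  expect_true(is.na(r2$ratio[r2$resname == "TRP"]))
})

test_that("top-ligand exclusion ranks per validity class with lexical ties", {
  sites <- c(lapply(1:8, function(i) fake_site("ALA", het = "SO4",
                                               validity = "invalid")),
             lapply(1:2, function(i) fake_site("ALA", het = "GOL",
                                               validity = "invalid")),
             lapply(1:3, function(i) fake_site("ALA", het = "NAD")))
  expect_equal(length(exclude_top_ligands(sites, 0)), 13)
  out1 <- exclude_top_ligands(sites, 1)
  expect_false(any(vapply(out1, function(x) x$het_code, "") == "SO4"))
  expect_true(any(vapply(out1, function(x) x$het_code, "") == "GOL"))
  expect_false(any(vapply(out1, function(x) x$het_code, "") == "NAD"))
  expect_equal(length(exclude_top_ligands(sites, 5)), 0)
  # tie broken lexicographically
  tied <- list(fake_site("ALA", het = "BBB"), fake_site("ALA", het = "AAA"))
  outt <- exclude_top_ligands(tied, 1)
  expect_equal(vapply(outt, function(x) x$het_code, ""), "BBB")
  # data-frame interface behaves identically
  df <- data.frame(het_code = c("SO4", "SO4", "GOL"),
                   validity = "invalid", stringsAsFactors = FALSE)
  expect_equal(exclude_top_ligands(df, 1)$het_code, "GOL")
})

test_that("pooled propensity differs from the mean of per-site propensities", {
  ps <- accumulate_frequencies(list(rep(c("ALA", "GLY"), 50)),
                               "protein_surface")
  s1 <- c("ALA", "ALA", "ALA", "GLY")
  s2 <- c("GLY", "GLY")   # different site size, so pooling != averaging
  pooled <- compute_propensity(
    accumulate_frequencies(list(s1, s2), "binding_site"), ps)
  per_site <- vapply(list(s1, s2), function(s)
    compute_propensity(accumulate_frequencies(list(s), "binding_site"),
                       ps)$propensity[1], 1)
  expect_false(isTRUE(all.equal(pooled$propensity[1], mean(per_site))))
  # equality when all sites are identical
  pooled2 <- compute_propensity(
    accumulate_frequencies(list(s1, s1), "binding_site"), ps)
  single <- compute_propensity(
    accumulate_frequencies(list(s1), "binding_site"), ps)
  expect_equal(pooled2$propensity, single$propensity)
})

test_that("duplicating every protein leaves propensities unchanged", {
  ds <- generate_composition_dataset(composition_spec(
    n_proteins = 60, seed = 3,
    enrichment_valid = enrich(TRP = 1.8, GLU = 0.6)))
  p1 <- composition_propensity(ds, "valid")
  dup <- ds
  dup$surface_counts <- rbind(ds$surface_counts, ds$surface_counts)
  dup$site_counts <- rbind(ds$site_counts, ds$site_counts)
  info2 <- ds$site_info
  info2$protein <- info2$protein + nrow(ds$surface_counts)
  dup$site_info <- rbind(ds$site_info, info2)
  p2 <- composition_propensity(dup, "valid")
  expect_equal(p1$propensity, p2$propensity)
  expect_equal(p1$freq_bs, p2$freq_bs)
})

test_that("100 generated sites tally identically to naive loops", {
  ds <- generate_composition_dataset(composition_spec(n_proteins = 80,
                                                      seed = 19))
  sel <- which(ds$site_info$validity == "valid")[1:100]
  expect_false(anyNA(sel))
  ft <- accumulate_frequencies(ds$site_counts[sel, ], "binding_site")
  naive <- stats::setNames(numeric(20), AA3)
  for (j in sel) for (aa in AA3)
    naive[aa] <- naive[aa] + ds$site_counts[j, aa]
  expect_equal(unname(ft$counts), unname(naive))
  expect_equal(sum(ft$frequencies), 1)
})
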