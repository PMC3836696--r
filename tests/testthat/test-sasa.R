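test_that("an isolated atom reproduces the analytic sphere area", {
  # vdW radius 1.64 + probe 1.4 -> expanded radius 3.04
  p <- sasa_params(radii = c(X = 1.64))
  a <- sasa_atom_areas(matrix(0, 1, 3), "X", p)
  expect_equal(a, 4 * pi * 3.04^2, tolerance = 0.02)
  # quadrature converges: error shrinks as the point count grows
  two <- sasa_atom_areas(rbind(c(0, 0, 0), c(2.5, 0, 0)), c("X", "X"),
                         sasa_params(radii = c(X = 1.64),
                                     n_sphere_points = 240))
  ref <- sasa_atom_areas(rbind(c(0, 0, 0), c(2.5, 0, 0)), c("X", "X"),
                         sasa_params(radii = c(X = 1.64),
                                     n_sphere_points = 7680))
  mid <- sasa_atom_areas(rbind(c(0, 0, 0), c(2.5, 0, 0)), c("X", "X"),
                         sasa_params(radii = c(X = 1.64),
                                     n_sphere_points = 960))
  expect_lt(abs(mid[1] - ref[1]), abs(two[1] - ref[1]) + 1e-9)
})

test_that("symmetric atom pairs expose equal areas and burial is monotone", {
  p <- sasa_params()
  # along z the spiral point set is mirror-symmetric, so equality is exact
  a <- sasa_atom_areas(rbind(c(0, 0, 0), c(0, 0, 3)), c("C", "C"), p)
  expect_equal(a[1], a[2])
  ax <- sasa_atom_areas(rbind(c(0, 0, 0), c(3, 0, 0)), c("C", "C"), p)
  expect_equal(ax[1], ax[2], tolerance = 0.01)  # quadrature-level agreement
  iso <- sasa_atom_areas(matrix(0, 1, 3), "C", p)
  set.seed(7)
  for (i in 1:50) {
    d <- runif(1, 0.5, 8)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    a2 <- sasa_atom_areas(rbind(c(0, 0, 0), d * u), c("C", "O"), p)
    expect_lte(a2[1], iso + 1e-9)
  }
})

test_that("a fully caged atom has zero accessible area", {
  cage <- bindprop:::golden_spiral_points(180) * 4.2
  coords <- rbind(c(0, 0, 0), cage)
  els <- c("C", rep("C", nrow(cage)))
  a <- sasa_atom_areas(coords, els, sasa_params())
  expect_equal(a[1], 0)
  # independent brute-force probe test: every probe position on the central
  # atom's expanded sphere must clash with a cage atom's expanded sphere
  set.seed(99)
  u <- matrix(rnorm(3 * 500), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * (1.87 + 1.4)
  covered <- vapply(seq_len(nrow(pts)), function(i) {
    any(rowSums(sweep(cage, 2, pts[i, ])^2) < (1.87 + 1.4)^2)
  }, TRUE)
  expect_true(all(covered))
})

test_that("residue areas sum their atoms and split side/main correctly", {
  tc <- generate_toy_complex(toy_complex_spec(n_shell_residues = 10,
                                              buried_decoy_count = 0,
                                              seed = 5))
  s <- normalize_structure(parse_structure(tc$pdb))
  surf <- compute_sasa(s)
  a <- surf$atoms
  key <- paste(a$chain, a$resno)
  for (k in unique(key)) {
    sub <- a[key == k, ]
    r <- surf$residues[paste(surf$residues$chain, surf$residues$resno) == k, ]
    expect_equal(r$abs_side + r$abs_main, sum(sub$area), tolerance = 1e-9)
    expect_equal(r$abs_side, sum(sub$area[sub$role == "sidechain"]),
                 tolerance = 1e-9)
  }
  expect_true(all(surf$residues$abs_side >= 0 & surf$residues$abs_main >= 0))
  # ligands are excluded from the SASA atom set
  expect_false(any(a$partition != "polymer"))
})

test_that("surface selection is inclusive at the cutoff with the Gly max rule", {
  surf <- fake_surface(data.frame(
    chain = "A", resno = 1:4, resname = c("SER", "ALA", "GLY", "LEU"),
    abs_side = c(5.0, 4.9, 2.0, 0.4), abs_main = c(1.0, 1.0, 6.0, 0.4),
    stringsAsFactors = FALSE))
  sel5 <- surface_residues(surf, 5.0, "sidechain")
  expect_setequal(sel5$resno, c(1, 3))   # 5.0 included; Gly via max rule
  sel05 <- surface_residues(surf, 0.5, "sidechain")
  expect_setequal(sel05$resno, c(1, 2, 3))
  selm <- surface_residues(surf, 5.0, "mainchain")
  expect_setequal(selm$resno, 3)
  expect_error(surface_residues(surf, -1), "non-negative")
})

test_that("the engine agrees with an independent SASA implementation", {
  # biotite's Shrake-Rupley with an identical radii set is the oracle
  tc <- generate_toy_complex(toy_complex_spec(n_shell_residues = 12,
                                              buried_decoy_count = 0,
                                              seed = 9))
  pdb_path <- tempfile(fileext = ".pdb")
  writeLines(tc$pdb, pdb_path)
  s <- normalize_structure(parse_structure(pdb_path))
  radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)
  surf <- compute_sasa(s, sasa_params(radii = radii))
  out_csv <- tempfile(fileext = ".csv")
  script <- c(
    "import sys, csv",
    "import biotite.structure as struc, biotite.structure.io.pdb as pdb",
    "f = pdb.PDBFile.read(sys.argv[1])",
    "arr = pdb.get_structure(f, model=1, extra_fields=['atom_id'])",
    "arr = arr[~arr.hetero]",
    "s = struc.sasa(arr, probe_radius=1.4, point_number=960,",
    "               vdw_radii='Single', ignore_ions=False)",
    "w = csv.writer(open(sys.argv[2], 'w'))",
    "w.writerow(['serial', 'area'])",
    "[w.writerow([int(i), float(a)]) for i, a in zip(arr.atom_id, s)]")
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  status <- system2("python", c(py, pdb_path, out_csv), stdout = FALSE,
                    stderr = FALSE)
  expect_equal(status, 0)
  ref <- utils::read.csv(out_csv)
  a <- surf$atoms
  m <- merge(data.frame(serial = a$serial, area = a$area), ref,
             by = "serial")
  expect_equal(nrow(m), nrow(a))
  big <- m$area.y > 1
  expect_true(all(abs(m$area.x[big] - m$area.y[big]) / m$area.y[big] < 0.05))
})
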