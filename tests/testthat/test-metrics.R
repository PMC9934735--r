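test_that("bond inference follows the reference-length envelopes", {
  bt <- bond_table()
  # O-H at 0.96 A -> single bond (reference 96 pm)
  oh <- molecule(rbind(c(0, 0, 0), c(0.96, 0, 0)), c("O", "H"))
  expect_equal(infer_bonds(oh, bt)[1, 2], 1L)
  # H-H at 0.74 A -> single bond (reference 74 pm)
  hh <- molecule(rbind(c(0, 0, 0), c(0.74, 0, 0)), c("H", "H"))
  expect_equal(infer_bonds(hh, bt)[1, 2], 1L)
  # C-C at 3.0 A -> no bond
  cc <- molecule(rbind(c(0, 0, 0), c(3, 0, 0)), c("C", "C"))
  expect_equal(infer_bonds(cc, bt)[1, 2], 0L)
  # C-N at 1.16 A falls in the triple-bond envelope
  cn <- molecule(rbind(c(0, 0, 0), c(1.16, 0, 0)), c("C", "N"))
  expect_equal(infer_bonds(cn, bt)[1, 2], 3L)
  # symmetric, zero diagonal
  w <- water_molecule()
  b <- infer_bonds(w, bt)
  expect_equal(b, t(b))
  expect_true(all(diag(b) == 0L))
})

test_that("bond inference is invariant under rotation, translation, permutation", {
  bt <- bond_table()
  set.seed(6)
  m <- sample_dataset(n = 1L, jitter_sd = 0.1, seed = 6L)[[1]]
  b <- infer_bonds(m, bt)
  R <- random_rotation()
  m2 <- m; m2$coords <- m$coords %*% t(R) + 3
  expect_equal(infer_bonds(m2, bt), b)
  p <- sample(n_atoms(m))
  m3 <- molecule(m$coords[p, ], m$types[p], m$charges[p])
  expect_equal(infer_bonds(m3, bt), b[p, p])
})

test_that("stability metrics reproduce the hand-built examples", {
  bt <- bond_table()
  water <- water_molecule()
  expect_equal(atom_stability(water, bt), 1.0)
  expect_true(molecule_stability(water, bt))
  # lone carbon: valence 0 != 4
  lone_c <- molecule(matrix(0, 1, 3), "C")
  expect_equal(atom_stability(lone_c, bt), 0.0)
  expect_false(molecule_stability(lone_c, bt))
  # stretched water: one H pulled to 2.5 A breaks a bond
  stretched <- water
  stretched$coords[3, ] <- c(-2.5, 0, 0)
  expect_false(molecule_stability(stretched, bt))
  expect_lt(atom_stability(stretched, bt), 1.0)
  # charge-aware valency: hydroxide O(-1) with one bond is stable
  ohm <- molecule(rbind(c(0, 0, 0), c(0.96, 0, 0)), c("O", "H"),
                  charges = c(-1L, 0L))
  expect_equal(atom_stability(ohm, bt), 1.0)
  expect_equal(atom_stability(ohm, bond_table(charge_aware = FALSE)), 0.5)
})

test_that("adding a distant lone atom strictly lowers AS and breaks MS", {
  bt <- bond_table()
  base <- water_molecule()
  grown <- molecule(rbind(base$coords, c(50, 50, 50)),
                    c(base$types, "C"))
  expect_true(molecule_stability(base, bt))
  expect_false(molecule_stability(grown, bt))
  expect_lt(atom_stability(grown, bt), atom_stability(base, bt))
})

test_that("RDKit validity and canonical SMILES behave on the hand examples", {
  bt <- bond_table()
  water <- water_molecule()
  v <- validity(water, bt)
  expect_true(v$valid[1])
  expect_equal(v$smiles[1], "O")
  # pentavalent carbon construction is rejected by sanitization
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  penta <- molecule(rbind(c(0, 0, 0), 1.09 * dirs), rep(c("C", "H"), c(1, 5)))
  expect_false(validity(penta, bt)$valid[1])
})

test_that("uniqueness and novelty are the stated set ratios", {
  expect_equal(uniqueness(c("O", "O", "C")), 2 / 3)
  expect_equal(uniqueness(c("A", "B", "C")), 1.0)
  expect_equal(uniqueness(rep("X", 5)), 1 / 5)
  expect_error(uniqueness(character(0)), "empty")
  expect_equal(novelty(c("A", "B"), c("A", "B", "C")), 0.0)
  expect_equal(novelty(c("D", "E"), c("A", "B")), 1.0)
  expect_equal(novelty(c("A", "B", "D", "E"), c("A", "B")), 0.5)
})

test_that("batch reports aggregate correctly", {
  bt <- bond_table()
  water <- water_molecule()
  lone_c <- molecule(matrix(0, 1, 3), "C")
  rep1 <- batch_report(list(water), bt)
  expect_equal(rep1$atom_stable, 100)
  expect_equal(rep1$mol_stable, 100)
  expect_equal(rep1$valid, 100)
  # water + lone carbon: 3 of 4 atoms stable, 1 of 2 molecules stable
  rep2 <- batch_report(list(water, lone_c), bt, with_validity = FALSE)
  expect_equal(rep2$atom_stable, 75)
  expect_equal(rep2$mol_stable, 50)
  rep3 <- batch_report(list(water, water, lone_c), bt,
                       reference = c("O"))
  expect_lte(rep3$valid_unique, rep3$valid)
  expect_equal(rep3$novel, 50)  # {O, [C]} vs reference {O}
  expect_error(batch_report(list()), "empty")
})

test_that("the energy ratio of a near-equilibrium pose is sane and flagged at 7", {
  methane <- make_templates()[[1]]
  m <- molecule(methane$coords, methane$types)
  er <- energy_ratio(m, n_conformers = 10L, seed = 1L)
  expect_true(is.finite(er$ratio))
  expect_lt(er$ratio, 7)
  expect_false(er$flagged)
})
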