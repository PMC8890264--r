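two_atom_struct <- function(el1, el2, dist, ...) {
  sc <- lig_scheme()
  typed_struct(rbind(c(0, 0, 0), c(dist, 0, 0)),
               rbind(type_atom(el1, ..., scheme = sc),
                     type_atom(el2, ..., scheme = sc)), sc)
}

test_that("bonds are proposed from covalent radii and pruned to valence", {
  b <- connect_atoms(two_atom_struct("C", "C", 1.54))
  expect_equal(nrow(b), 1L)
  expect_equal(nrow(connect_atoms(two_atom_struct("C", "C", 4.0))), 0L)
  # clash floor: overlapping atoms are not bonded
  expect_equal(nrow(connect_atoms(two_atom_struct("C", "C", 0.3))), 0L)
  # central carbon with five equidistant neighbors keeps only four bonds
  sc <- lig_scheme()
  ang <- seq(0, 2 * pi, length.out = 6)[1:5]
  coords <- rbind(c(0, 0, 0), cbind(1.5 * cos(ang), 1.5 * sin(ang), 0))
  # perturb one neighbor slightly farther so the pruned bond is unambiguous
  coords[6, ] <- coords[6, ] * 1.05
  st <- typed_struct(coords, t(replicate(6, type_atom("C", scheme = sc))), sc)
  b5 <- connect_atoms(st)
  deg1 <- sum(b5$i == 1 | b5$j == 1)
  expect_equal(deg1, 4L)
  expect_false(any((b5$i == 1 & b5$j == 6) | (b5$i == 6 & b5$j == 1)))
})

test_that("aromatic rings kekulize and geometric cues set orders", {
  ring <- make_fixture_molecule(fixture_spec(motif = "ring6_aromatic"))
  b <- connect_atoms(ring)
  o <- assign_bond_orders(ring, b)
  expect_null(o$failure)
  expect_equal(sum(o$bonds$aromatic), 6L)
  expect_equal(sort(unique(o$bonds$order[o$bonds$aromatic])), c(1L, 2L))
  expect_equal(sum(o$bonds$order[o$bonds$aromatic] == 2L), 3L)

  dbl <- assign_bond_orders(two_atom_struct("C", "C", 1.33),
                            connect_atoms(two_atom_struct("C", "C", 1.33)))
  expect_equal(dbl$bonds$order, 2L)
  sgl <- assign_bond_orders(two_atom_struct("C", "C", 1.54),
                            connect_atoms(two_atom_struct("C", "C", 1.54)))
  expect_equal(sgl$bonds$order, 1L)
})

test_that("implicit hydrogens fill default valence with donor constraints", {
  sc <- lig_scheme()
  lone <- typed_struct(matrix(0, 1, 3), matrix(type_atom("C", scheme = sc), 1), sc)
  mol <- make_molecule(lone)
  expect_equal(mol$atoms$implicit_h, 4L)   # methane
  expect_true(mol$valid)

  # benzene ring carbon: two kekulized ring bonds leave one hydrogen
  ring <- make_fixture_molecule(fixture_spec(motif = "ring6_aromatic"))
  bz <- make_molecule(ring)
  expect_true(bz$valid)
  expect_true(all(bz$atoms$implicit_h == 1L))

  # ammonium-like N+ with four single bonds keeps zero hydrogens, valid
  coords <- rbind(c(0, 0, 0),
                  1.5 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                              c(-1, -1, 1)) / sqrt(3))
  types <- rbind(type_atom("N", charge = 1L, scheme = sc),
                 t(replicate(4, type_atom("C", scheme = sc))))
  st <- typed_struct(coords, types, sc)
  mol4 <- make_molecule(st)
  expect_true(mol4$valid)
  expect_equal(mol4$atoms$implicit_h[1], 0L)

  # order raising reserves one valence unit on donor-typed atoms: a short
  # C-O bond with a donor-typed O stays single so the hydrogen survives
  o2 <- typed_struct(rbind(c(0, 0, 0), c(1.25, 0, 0)),
                     rbind(type_atom("O", donor = TRUE, scheme = sc),
                           type_atom("C", scheme = sc)), sc)
  molo <- make_molecule(o2)
  expect_true(molo$valid)
  expect_equal(molo$bonds$order, 1L)
  expect_equal(molo$atoms$implicit_h[1], 1L)

  # an ether-like donor-typed O bridging two carbons has no room for H
  o3 <- typed_struct(rbind(c(0, 0, 0), c(1.43, 0, 0), c(-1.43, 0, 0)),
                     rbind(type_atom("O", donor = TRUE, scheme = sc),
                           type_atom("C", scheme = sc),
                           type_atom("C", scheme = sc)), sc)
  molo3 <- make_molecule(o3)
  expect_false(molo3$valid)
  expect_equal(molo3$failure_reason, "donor without H")
})

test_that("make_molecule enforces the validity predicate", {
  sc <- lig_scheme()
  empty <- typed_struct(matrix(numeric(0), ncol = 3),
                        matrix(numeric(0), ncol = 18), sc)
  m0 <- make_molecule(empty)
  expect_false(m0$valid)
  expect_equal(m0$failure_reason, "no atoms")

  # two fragments 10 A apart
  st <- typed_struct(rbind(c(0, 0, 0), c(10, 0, 0)),
                     t(replicate(2, type_atom("C", scheme = sc))), sc)
  m2 <- make_molecule(st)
  expect_false(m2$valid)
  expect_equal(m2$failure_reason, "multiple fragments")

  ring <- make_fixture_molecule(fixture_spec(motif = "ring6_aromatic"))
  expect_equal(mol_to_smiles(make_molecule(ring)), "c1ccccc1")
})

test_that("bond inference is deterministic", {
  st <- make_fixture_molecule(fixture_spec(n_atoms = 8L, rng_seed = 12L,
                                           min_separation = 1.8))
  m1 <- make_molecule(st)
  m2 <- make_molecule(st)
  expect_identical(m1$bonds, m2$bonds)
  expect_identical(m1$atoms, m2$atoms)
})

test_that("no inferred bond exceeds the radii sum plus tolerance", {
  rules <- bond_rules()
  for (seed in 1:5) {
    st <- make_fixture_molecule(fixture_spec(n_atoms = 10L, rng_seed = seed,
                                             min_separation = 1.5))
    mol <- make_molecule(st, rules)
    if (nrow(mol$bonds) == 0L) next
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      cut <- rules$covalent_radii[mol$atoms$element[i]] +
        rules$covalent_radii[mol$atoms$element[j]] + rules$bond_tolerance
      expect_lte(mol$bonds$length[k], cut)
    }
  }
})

test_that("typed structures round-trip to their canonical SMILES", {
  for (name in c("ethanol", "acetone", "pyridine", "acetic_acid", "pyrrole")) {
    m <- fixture_mol_by_name(name)
    got <- mol_to_smiles(make_molecule(type_molecule(m)))
    expect_equal(got, attr(m, "smiles"), label = name)
  }
})

test_that("fit-then-bond recovers an ethanol-like molecule end to end", {
  m <- fixture_mol_by_name("ethanol")
  st <- type_molecule(m)
  spec <- grid_spec(center = colMeans(st$coords))
  fr <- fit_atoms(molecule_to_grid(st, spec))
  got <- mol_to_smiles(make_molecule(fr$struct))
  expect_equal(got, "CCO")
})
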