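benzene_mol <- function() make_molecule(type_molecule(fixture_mol_by_name("benzene")))
ethanol_mol <- function() make_molecule(type_molecule(fixture_mol_by_name("ethanol")))

test_that("validity requires one fragment and a sanitizable structure", {
  expect_true(is_valid(benzene_mol()))

  sc <- lig_scheme()
  frag <- make_molecule(typed_struct(rbind(c(0, 0, 0), c(10, 0, 0)),
                                     t(replicate(2, type_atom("C", scheme = sc))),
                                     sc))
  expect_false(is_valid(frag))

  # pentavalent neutral carbon fails the valence check
  bad <- gridmol:::new_inferred_molecule(
    data.frame(element = c("C", rep("H", 0), rep("C", 5)),
               x = c(0, 1.5, -1.5, 0, 0, 0), y = c(0, 0, 0, 1.5, -1.5, 0),
               z = c(0, 0, 0, 0, 0, 1.5), charge = 0L, aromatic = FALSE,
               donor = FALSE, acceptor = FALSE, implicit_h = 0L),
    data.frame(i = 1L, j = 2:6, order = 1L, aromatic = FALSE))
  expect_false(is_valid(bad))
})

test_that("novelty and uniqueness operate on canonical SMILES", {
  bz <- benzene_mol()
  expect_false(is_novel(bz, c("c1ccccc1", "CCO")))
  expect_true(is_novel(bz, character(0)))
  expect_true(is_novel(bz, c("CCO")))

  u1 <- is_unique(bz, character(0))
  expect_true(u1$unique)
  u2 <- is_unique(bz, u1$set)
  expect_false(u2$unique)
  expect_equal(length(u2$set), 1L)
})

test_that("tanimoto similarity is a bit-set ratio with expected properties", {
  bz <- benzene_mol(); et <- ethanol_mol()
  expect_equal(tanimoto(bz, bz), 1.0)
  s <- tanimoto(bz, et)
  expect_gte(s, 0); expect_lt(s, 1)
  expect_equal(tanimoto(et, bz), s)   # symmetry
  # independent cross-check through the OpenBabel CLI's FP2 Tanimoto
  tol <- make_molecule(type_molecule(fixture_mol_by_name("toluene")))
  t1 <- tempfile(fileext = ".sdf"); t2 <- tempfile(fileext = ".sdf")
  write_sdf(inferred_to_mol3d(bz), t1)
  write_sdf(inferred_to_mol3d(tol), t2)
  out <- suppressWarnings(system2("obabel", c(t1, t2, "-ofpt"),
                                  stdout = TRUE, stderr = FALSE))
  ln <- grep("Tanimoto from", out, value = TRUE)
  expect_length(ln, 1)
  cli <- as.numeric(sub(".*=\\s*", "", ln[1]))
  expect_equal(tanimoto(bz, tol), cli, tolerance = 1e-6)
})

test_that("per-target diversity is the inverse mean pairwise similarity", {
  bz <- benzene_mol(); et <- ethanol_mol()
  expect_equal(per_target_diversity(list(bz, bz, bz)), 1.0)
  s <- tanimoto(bz, et)
  expect_equal(per_target_diversity(list(bz, et)), 1 / s, tolerance = 1e-12)
  tol <- make_molecule(type_molecule(fixture_mol_by_name("toluene")))
  sims <- c(tanimoto(bz, et), tanimoto(bz, tol), tanimoto(et, tol))
  expect_equal(per_target_diversity(list(bz, et, tol)), 1 / mean(sims),
               tolerance = 1e-12)
  # ordering invariance
  expect_equal(per_target_diversity(list(tol, bz, et)),
               per_target_diversity(list(bz, et, tol)), tolerance = 1e-12)
  expect_true(is.na(per_target_diversity(list(bz))))
})

test_that("molecular weight sums standard masses with implicit hydrogens", {
  sc <- lig_scheme()
  methane <- make_molecule(typed_struct(matrix(0, 1, 3),
                                        matrix(type_atom("C", scheme = sc), 1),
                                        sc))
  expect_equal(molecular_weight(methane), 16.04, tolerance = 0.01)
  expect_equal(molecular_weight(benzene_mol()), 78.11, tolerance = 0.01)
  empty <- gridmol:::new_inferred_molecule(
    data.frame(element = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), charge = integer(0), aromatic = logical(0),
               donor = logical(0), acceptor = logical(0),
               implicit_h = integer(0)),
    data.frame(i = integer(0), j = integer(0), order = integer(0),
               aromatic = logical(0)))
  expect_equal(molecular_weight(empty), 0)
})

test_that("heavy-atom RMSD is zero on identity and rigid-transform invariant", {
  set.seed(8)
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(gridmol:::coord_rmsd(a, a), 0)
  b <- a + matrix(rnorm(15, sd = 0.1), 5, 3)
  r0 <- gridmol:::coord_rmsd(a, b)
  tf <- random_transform(1)
  aT <- a %*% t(tf$rotation) + matrix(tf$translation, 5, 3, byrow = TRUE)
  bT <- b %*% t(tf$rotation) + matrix(tf$translation, 5, 3, byrow = TRUE)
  expect_equal(gridmol:::coord_rmsd(aT, bT), r0, tolerance = 1e-12)
})

test_that("UFF relaxation reports energy change and displacement", {
  et <- ethanol_mol()
  res <- relax_and_rmsd(et)
  if (!is.null(res$missing)) skip(paste("force field unavailable:", res$missing))
  expect_true(is.finite(res$rmsd))
  expect_lt(res$rmsd, 2)      # MMFF-optimized input is already near a minimum
  expect_lte(res$delta_e, 1)  # minimization should not raise the energy

  # stretched bond relaxes back: energy drops, structure moves
  m <- fixture_mol_by_name("ethanol")
  stretched <- m
  heavy <- which(stretched$atoms$element != "H")
  stretched$atoms$x[heavy[1]] <- stretched$atoms$x[heavy[1]] + 0.5
  sm <- make_molecule(type_molecule(stretched))
  res2 <- relax_and_rmsd(sm)
  expect_lt(res2$delta_e, 0)
  expect_gt(res2$rmsd, 0)
})

test_that("aggregate metric report matches hand-computed percentages", {
  bz <- benzene_mol(); et <- ethanol_mol()
  sc <- lig_scheme()
  frag <- make_molecule(typed_struct(rbind(c(0, 0, 0), c(10, 0, 0)),
                                     t(replicate(2, type_atom("C", scheme = sc))),
                                     sc))
  rep <- evaluate_molecules(list(bz, et, bz, frag),
                            reference_smiles_set = c("CCO"),
                            reference_mol = bz)
  expect_equal(rep$aggregate$percent_valid, 75)
  # valid: bz, et, bz; novel among valid: benzene twice (CCO in training set)
  expect_equal(rep$aggregate$percent_novel_valid, 100 * 2 / 3)
  expect_equal(rep$aggregate$percent_unique_valid, 100 * 2 / 3)
  expect_equal(rep$per_molecule$valid, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(rep$per_molecule$unique, c(TRUE, TRUE, FALSE, NA))
  expect_equal(rep$per_molecule$tanimoto_to_reference[1], 1)
})

test_that("geometry tabulation keys bonds, angles and torsions by type", {
  et <- ethanol_mol()
  tab <- tabulate_geometry(et)
  expect_equal(nrow(tab$bonds), 2L)
  expect_setequal(tab$bonds$key, c("C-C", "C-O"))
  expect_equal(nrow(tab$angles), 1L)  # C-C-O
  expect_equal(tab$angles$key, "C-C-O")
  expect_equal(nrow(tab$torsions), 0L)
  bz <- tabulate_geometry(benzene_mol())
  expect_equal(nrow(bz$bonds), 6L)
  expect_true(all(abs(bz$angles$angle - 120) < 1))
})
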