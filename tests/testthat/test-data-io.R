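test_that("SDF reading preserves record order, atoms, bonds and charges", {
  sdf <- system.file("extdata", "fixture_molecules.sdf", package = "gridmol")
  mols <- read_structures(sdf, "SDF")
  expect_equal(length(mols), 40L)
  expect_equal(mols[[1]]$name, "ethane")
  expect_equal(sum(mols[[1]]$atoms$element == "C"), 2L)
  # a record written with formal charges round-trips them
  sc <- lig_scheme()
  st <- typed_struct(rbind(c(0, 0, 0), c(1.3, 0, 0), c(2.2, 1, 0)),
                     rbind(type_atom("O", charge = -1L, scheme = sc),
                           type_atom("C", scheme = sc),
                           type_atom("O", scheme = sc)), sc)
  mol <- make_molecule(st)
  tmp <- tempfile(fileext = ".sdf")
  write_sdf(inferred_to_mol3d(mol), tmp)
  back <- read_structures(tmp)[[1]]
  expect_equal(back$atoms$charge, c(-1L, 0L, 0L))
  expect_equal(back$atoms$x, mol$atoms$x, tolerance = 1e-4)
  expect_equal(nrow(back$bonds), nrow(mol$bonds))
})

test_that("corrupt structure files raise structured parse errors", {
  bad <- tempfile(fileext = ".sdf")
  writeLines(c("junk", "not an sdf"), bad)
  expect_error(read_structures(bad), "parse")
  expect_error(read_structures(tempfile(fileext = ".sdf")), "not found")
})

test_that("SMILES inputs carry no coordinates and refuse gridding", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene"), smi)
  mols <- read_structures(smi)
  expect_length(mols, 2L)
  expect_true(all(is.na(mols[[1]]$atoms$x)))
  st <- type_molecule(mols[[1]])
  expect_error(molecule_to_grid(st, grid_spec()), "coordinates|finite")
})

test_that("pose filtering keeps the 2 A boundary and drops unsanitizable", {
  poses <- data.frame(ligand_id = c("a", "b", "c"),
                      rmsd_to_crystal = c(0.5, 2.0, 2.1))
  kept <- filter_poses(poses)
  expect_equal(kept$ligand_id, c("a", "b"))  # boundary inclusive
  expect_equal(nrow(filter_poses(poses[0, ])), 0L)
  poses$sanitizable <- c(FALSE, TRUE, TRUE)
  expect_equal(filter_poses(poses)$ligand_id, "b")
  # idempotent
  k1 <- filter_poses(poses)
  expect_equal(filter_poses(k1), k1)
  # smiles-based sanitization path
  p2 <- data.frame(rmsd_to_crystal = c(0.1, 0.1),
                   smiles = c("CCO", "C1CC"))   # unclosed ring fails
  expect_equal(nrow(filter_poses(p2)), 1L)
})

test_that("test-target selection respects cluster and ligand-count rules", {
  set.seed(1)
  poses <- do.call(rbind, lapply(1:12, function(cl) {
    do.call(rbind, lapply(1:6, function(l) {
      data.frame(target_id = paste0("t", cl), cluster_id = cl,
                 ligand_id = paste0("l", cl, "_", l), rank = 1:3,
                 rmsd_to_crystal = 0.5)
    }))
  }))
  sel <- select_test_targets(poses, min_ligands = 5, n_targets = 10)
  expect_equal(length(unique(sel$cluster_id)), 10L)
  expect_true(all(sel$rank == 1L))
  expect_equal(unname(table(sel$target_id)[1]), 6L)  # one rank-1 pose per ligand
  # determinism under a fixed seed
  set.seed(42); s1 <- select_test_targets(poses)
  set.seed(42); s2 <- select_test_targets(poses)
  expect_identical(s1, s2)
  # a target with too few ligands is ineligible
  small <- poses[poses$ligand_id %in% paste0("l1_", 1:4) | poses$cluster_id != 1, ]
  expect_error(select_test_targets(small, n_targets = 12), "eligible")
})

test_that("fixture molecules are deterministic and respect separation", {
  s1 <- make_fixture_molecule(fixture_spec(n_atoms = 5L, rng_seed = 3L))
  s2 <- make_fixture_molecule(fixture_spec(n_atoms = 5L, rng_seed = 3L))
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$types, s2$types)
  d <- as.matrix(dist(s1$coords))
  expect_gte(min(d[upper.tri(d)]), 2.0)

  ring <- make_fixture_molecule(fixture_spec(motif = "ring6_aromatic"))
  dr <- sort(unique(round(as.matrix(dist(ring$coords))[upper.tri(diag(6))], 4)))
  expect_equal(dr, round(c(1.39, 1.39 * sqrt(3), 2.78), 4), tolerance = 1e-6)
})

test_that("fixture complexes have zero steric overlap by construction", {
  cx <- make_fixture_complex(rng_seed = 7)
  spec_r <- grid_spec(n_channels = 18L)
  rec <- molecule_to_grid(cx$receptor, spec_r)
  lig <- molecule_to_grid(cx$ligand, spec_r)
  expect_equal(steric_overlap(rec, lig), 0)
  # shrinking the shell below twice the kernel support forces overlap
  cx2 <- make_fixture_complex(rng_seed = 7, shell_radius = 3.5,
                              n_receptor_atoms = 15L)
  rec2 <- molecule_to_grid(cx2$receptor, spec_r)
  expect_gt(steric_overlap(rec2, lig), 0)
  cx3 <- make_fixture_complex(rng_seed = 7)
  expect_identical(cx3$ligand$coords, cx$ligand$coords)
})

test_that("every ligand element appears across the default fixtures", {
  elems <- character(0)
  for (m in load_fixture_molecules()) {
    elems <- union(elems, unique(m$atoms$element))
  }
  for (seed in 1:10) {
    st <- make_fixture_molecule(fixture_spec(
      rng_seed = seed, elements = c("B", "F", "Br", "I", "Fe")))
    elems <- union(elems, gridmol:::struct_elements(st))
  }
  expect_true(all(scheme_elements(lig_scheme()) %in% elems))
})

test_that("PDB receptor reading yields element-typed heavy atoms", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.571   5.516  -4.212  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       9.580   4.914  -4.632  1.00  0.00           O",
    "END"), pdb)
  mols <- read_structures(pdb)
  expect_length(mols, 1L)
  expect_equal(mols[[1]]$atoms$element, c("N", "C", "C", "O"))
  st <- type_molecule(mols[[1]], default_scheme("receptor"))
  expect_equal(nrow(st$coords), 4L)
})
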