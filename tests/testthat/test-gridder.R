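test_that("default grid geometry yields 48 points per axis", {
  spec <- grid_spec()
  expect_equal(spec$points_per_axis, 48L)
  ax <- grid_coordinates(spec)
  expect_equal(ax$x[1], -11.75)
  expect_equal(ax$x[48], 11.75)
  spec2 <- grid_spec(center = c(1, 2, 3))
  ax2 <- grid_coordinates(spec2)
  expect_equal(range(ax2$z), c(3 - 11.75, 3 + 11.75))
})

test_that("kernel is a truncated Gaussian with unit peak", {
  expect_equal(kernel(0, 1), 1)
  expect_equal(kernel(2, 1), 0)          # beyond the 1.5 r cutoff
  expect_equal(kernel(0.5, 1), exp(-0.5))
  d <- seq(0, 1.5, by = 0.01)
  expect_true(all(diff(kernel(d, 1)) <= 0))
  expect_equal(kernel(1.5, 1), exp(-2 * 1.5^2))  # support boundary included
  expect_error(kernel(-1, 1), "nonnegative")
  expect_error(kernel(1, 0), "positive")
})

test_that("density grids sum per-atom kernels into the typed channels", {
  spec <- odd_spec()
  st <- single_atom_struct("C")
  g <- molecule_to_grid(st, spec)
  ctr <- (spec$points_per_axis + 1) / 2
  expect_equal(g$values[2, ctr, ctr, ctr], 1.0)   # carbon channel peak
  expect_equal(sum(g$values[c(1, 3:11), , , ]), 0) # other element channels empty

  empty <- typed_struct(matrix(numeric(0), ncol = 3),
                        matrix(numeric(0), ncol = 18), lig_scheme())
  expect_equal(sum(molecule_to_grid(empty, spec)$values), 0)

  # two carbons both 0.4 A from the center grid point
  sc <- lig_scheme()
  st2 <- typed_struct(rbind(c(0.4, 0, 0), c(-0.4, 0, 0)),
                      rbind(type_atom("C", scheme = sc),
                            type_atom("C", scheme = sc)), sc)
  g2 <- molecule_to_grid(st2, spec)
  expect_equal(g2$values[2, ctr, ctr, ctr], 2 * exp(-2 * 0.16), tolerance = 1e-12)
})

test_that("gridding matches the brute-force oracle and is additive", {
  spec <- odd_spec(side = 4)
  sc <- lig_scheme()
  set.seed(11)
  stA <- typed_struct(matrix(runif(6, -1.5, 1.5), 2, 3),
                      rbind(type_atom("N", acceptor = TRUE, scheme = sc),
                            type_atom("C", scheme = sc)), sc)
  stB <- typed_struct(matrix(runif(3, -1.5, 1.5), 1, 3),
                      matrix(type_atom("O", scheme = sc), 1), sc)
  gA <- molecule_to_grid(stA, spec)
  expect_equal(gA$values, brute_grid(stA, spec)$values, tolerance = 1e-12)
  stAB <- typed_struct(rbind(stA$coords, stB$coords),
                       rbind(stA$types, stB$types), sc)
  expect_equal(molecule_to_grid(stAB, spec)$values,
               gA$values + molecule_to_grid(stB, spec)$values,
               tolerance = 1e-12)
  # boundedness: each voxel at most the atom count
  expect_true(max(molecule_to_grid(stAB, spec)$values) <= 3)
})

test_that("density is equivariant under rotation about the grid center", {
  spec <- odd_spec()
  sc <- lig_scheme()
  set.seed(5)
  st <- typed_struct(matrix(runif(9, -2, 2), 3, 3),
                     rbind(type_atom("C", scheme = sc),
                           type_atom("O", scheme = sc),
                           type_atom("N", scheme = sc)), sc)
  tf <- random_transform(max_translation = 0)
  rotated <- typed_struct(st$coords %*% t(tf$rotation), st$types, sc)
  pts <- matrix(runif(15, -2, 2), 5, 3)
  # density of the rotated structure at p equals the original at R^-1 p
  d_rot <- density_at_points(rotated, pts, spec)
  d_orig <- density_at_points(st, pts %*% tf$rotation, spec)
  expect_equal(d_rot, d_orig, tolerance = 1e-12)
})

test_that("random transforms are deterministic per seed and uniform", {
  set.seed(42); t1 <- random_transform(2)
  set.seed(42); t2 <- random_transform(2)
  expect_equal(t1$rotation, t2$rotation)
  expect_equal(t1$translation, t2$translation)
  R <- t1$rotation
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  set.seed(1)
  t0 <- random_transform(0)
  expect_equal(t0$translation, c(0, 0, 0))
  # uniformity over SO(3): rotated fixed vector has near-zero mean resultant
  set.seed(7)
  v <- c(1, 0, 0)
  imgs <- t(vapply(seq_len(2000), function(i) {
    as.numeric(random_transform(0)$rotation %*% v)
  }, numeric(3)))
  expect_lt(sqrt(sum(colMeans(imgs)^2)), 4 / sqrt(2000))
})

test_that("steric overlap is the channel-summed density product", {
  cx <- make_fixture_complex(rng_seed = 3)
  center <- c(0, 0, 0)
  spec_l <- grid_spec(center, n_channels = 18L)
  rec <- molecule_to_grid(cx$receptor, spec_l)
  lig <- molecule_to_grid(cx$ligand, spec_l)
  expect_equal(steric_overlap(rec, lig), 0)
  expect_equal(steric_overlap(lig, rec), steric_overlap(rec, lig))
  # brute-force agreement on random grids
  set.seed(2)
  spec_s <- odd_spec(side = 2, n_channels = 3L)
  np <- spec_s$points_per_axis
  a <- density_grid(array(runif(3 * np^3), c(3, np, np, np)), spec_s)
  b <- density_grid(array(runif(3 * np^3), c(3, np, np, np)), spec_s)
  manual <- 0
  for (ix in 1:np) for (iy in 1:np) for (iz in 1:np) {
    manual <- manual + sum(a$values[, ix, iy, iz]) * sum(b$values[, ix, iy, iz])
  }
  expect_equal(steric_overlap(a, b), manual, tolerance = 1e-10)
  zero <- density_grid(array(0, c(3, np, np, np)), spec_s)
  expect_equal(steric_overlap(a, zero), 0)
  expect_error(steric_overlap(a, molecule_to_grid(cx$ligand, spec_l)),
               "geometries")
})

test_that("analytic coordinate gradients match central finite differences", {
  spec <- odd_spec()
  sc <- lig_scheme()
  set.seed(9)
  gen <- typed_struct(matrix(runif(6, -1, 1), 2, 3),
                      rbind(type_atom("C", scheme = sc),
                            type_atom("O", scheme = sc)), sc)
  ref <- molecule_to_grid(gen, spec)
  st <- typed_struct(gen$coords + matrix(runif(6, -0.2, 0.2), 2, 3),
                     gen$types, sc)
  gr <- grid_l2_gradient(st, ref)
  h <- 1e-5
  for (a in 1:2) for (d in 1:3) {
    stp <- st; stp$coords[a, d] <- stp$coords[a, d] + h
    stm <- st; stm$coords[a, d] <- stm$coords[a, d] - h
    num <- (grid_l2(stp, ref) - grid_l2(stm, ref)) / (2 * h)
    expect_equal(gr[a, d], num, tolerance = 1e-5)
  }
})

test_that("grids round-trip bit-exactly through NPY + JSON", {
  spec <- odd_spec(side = 3, n_channels = 4L)
  np <- spec$points_per_axis
  set.seed(3)
  g <- density_grid(array(runif(4 * np^3), c(4, np, np, np)), spec)
  stem <- tempfile()
  write_grid(g, stem, channel_labels = paste0("ch", 1:4))
  g2 <- read_grid(stem)
  expect_identical(g2$values, g$values)
  expect_equal(g2$spec$center, spec$center)
  expect_equal(g2$spec$resolution, spec$resolution)
})
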