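# Shared test fixtures, built in code.

# Grid with an odd number of points so the center is a lattice node.
odd_spec <- function(side = 8, n_channels = 18L) {
  grid_spec(center = c(0, 0, 0), side = side, resolution = 0.5,
            n_channels = n_channels)
}

lig_scheme <- function() default_scheme("ligand")

single_atom_struct <- function(element = "C", at = c(0, 0, 0), ...) {
  sc <- lig_scheme()
  typed_struct(matrix(at, 1, 3), matrix(type_atom(element, ..., scheme = sc), 1),
               sc)
}

# Minimal single-channel scheme for fitting-oracle toy grids.
toy_scheme <- function() {
  type_scheme("ligand", list(atom_property("element", "C")))
}

# Brute-force R gridder: direct triple loop over grid points (oracle).
brute_grid <- function(struct, spec) {
  ax <- grid_coordinates(spec)
  np <- spec$points_per_axis
  vals <- array(0, c(spec$n_channels, np, np, np))
  for (a in seq_len(nrow(struct$coords))) {
    for (iz in seq_len(np)) for (iy in seq_len(np)) for (ix in seq_len(np)) {
      d <- sqrt(sum((c(ax$x[ix], ax$y[iy], ax$z[iz]) - struct$coords[a, ])^2))
      k <- kernel(d, spec$atomic_radius, spec$cutoff_mult)
      if (k > 0) vals[, ix, iy, iz] <- vals[, ix, iy, iz] + struct$types[a, ] * k
    }
  }
  density_grid(vals, spec)
}

fixture_mol_by_name <- function(name) {
  mols <- load_fixture_molecules()
  nm <- vapply(mols, function(m) m$name, character(1))
  mols[[match(name, nm)]]
}
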