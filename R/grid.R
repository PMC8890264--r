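# Atomic density grids ------------------------------------------------------
#
# A typed structure is rendered onto a cubic multi-channel grid by summing,
# at every grid point, a truncated-Gaussian kernel of each atom weighted by
# the atom's type-vector entry for that channel:
#
#   f(d, r) = exp(-2 d^2 / r^2)  for d <= cutoff_mult * r,  0 beyond,
#
# so f(0) = 1 and the density has compact support. The atomic radius is
# fixed at r = 1 A for all atoms; the default cutoff multiplier is 1.5.

#' Grid geometry specification
#'
#' Cubic grid with lattice points on both boundary faces: `side/resolution`
#' intervals give `round(side/resolution) + 1` points per axis (the default
#' 23.5 A side at 0.5 A resolution gives 48).
#'
#' @param center Grid center (3-vector, angstroms).
#' @param side Cube side length in angstroms (default 23.5).
#' @param resolution Grid step in angstroms (default 0.5).
#' @param n_channels Number of density channels (default 18, the default
#'   typing scheme width).
#' @param atomic_radius Kernel radius r in angstroms (default 1.0).
#' @param cutoff_mult Kernel support radius as a multiple of `atomic_radius`
#'   (default 1.5).
#' @return A `grid_spec` object with `points_per_axis` computed.
#' @export
grid_spec <- function(center = c(0, 0, 0), side = 23.5, resolution = 0.5,
                      n_channels = 18L, atomic_radius = 1.0, cutoff_mult = 1.5) {
  stopifnot(resolution > 0, atomic_radius > 0, side > 0, n_channels >= 1)
  structure(list(center = as.numeric(center), side = side,
                 resolution = resolution,
                 points_per_axis = as.integer(round(side / resolution)) + 1L,
                 n_channels = as.integer(n_channels),
                 atomic_radius = atomic_radius, cutoff_mult = cutoff_mult),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d channels x %d^3 points, side %.2f A @ %.2f A, center (%.2f, %.2f, %.2f)\n",
              x$n_channels, x$points_per_axis, x$side, x$resolution,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

grid_origin <- function(spec) spec$center - spec$side / 2

#' Density kernel
#'
#' Truncated Gaussian `exp(-2 d^2 / r^2)` for `d <= cutoff_mult * r`, zero
#' beyond. Continuous in value at 0 distance (value 1), monotone
#' nonincreasing, compact support.
#'
#' @param d Distance(s) in angstroms, `>= 0`.
#' @param r Atomic radius in angstroms, `> 0`.
#' @param cutoff_mult Support radius multiplier (default 1.5).
#' @return Density value(s) in `[0, 1]`.
#' @export
kernel <- function(d, r = 1.0, cutoff_mult = 1.5) {
  if (any(d < 0)) stop("distance must be nonnegative")
  if (r <= 0) stop("atomic radius must be positive")
  ifelse(d <= cutoff_mult * r, exp(-2 * d^2 / r^2), 0)
}

#' Grid point coordinates
#'
#' Point (i, j, k) (1-based in R) maps to
#' `center - side/2 + (i-1, j-1, k-1) * resolution`; the axis extremes span
#' exactly `[center - side/2, center + side/2]`.
#'
#' @param spec A `grid_spec`.
#' @return List with per-axis coordinate vectors `x`, `y`, `z`.
#' @export
grid_coordinates <- function(spec) {
  o <- grid_origin(spec)
  ax <- function(k) o[k] + (seq_len(spec$points_per_axis) - 1) * spec$resolution
  list(x = ax(1), y = ax(2), z = ax(3))
}

#' Rigid transform
#'
#' @param rotation 3x3 rotation matrix (determinant +1).
#' @param translation 3-vector in angstroms.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (abs(det(rotation) - 1) > 1e-9) stop("rotation must have determinant 1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Random pose augmentation transform
#'
#' Rotation uniform over SO(3) (quaternion method) plus a translation drawn
#' uniformly from a cube of half-width `max_translation` per axis. Driven by
#' R's RNG: fix the seed for reproducibility.
#'
#' @param max_translation Per-axis translation bound in angstroms (default 2).
#' @return A `rigid_transform`.
#' @export
random_transform <- function(max_translation = 2.0) {
  stopifnot(max_translation >= 0)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  tr <- stats::runif(3, -max_translation, max_translation)
  rigid_transform(R, tr)
}

# Apply a rigid transform to coordinates, rotating about `about`.
apply_transform <- function(coords, transform, about = c(0, 0, 0)) {
  if (is.null(transform)) return(coords)
  ctr <- matrix(about, nrow(coords), 3, byrow = TRUE)
  (coords - ctr) %*% t(transform$rotation) + ctr +
    matrix(transform$translation, nrow(coords), 3, byrow = TRUE)
}

#' Render a typed structure as a density grid
#'
#' Every voxel value is the sum over atoms of the kernel evaluated at the
#' atom-to-voxel distance, multiplied by the atom's type-vector entry for
#' that channel. All atoms whose kernel support intersects the grid
#' contribute; there is no atom-count cap. An optional rigid transform is
#' applied to the atoms about the grid center before rendering (pose
#' augmentation).
#'
#' @param struct A [typed_struct()].
#' @param spec A [grid_spec()]; `n_channels` must equal the scheme width.
#' @param transform Optional [rigid_transform()].
#' @return A `density_grid`: list of `values` (array `nch x np x np x np`)
#'   and `spec`.
#' @export
molecule_to_grid <- function(struct, spec, transform = NULL) {
  if (struct$scheme$total_width != spec$n_channels) {
    stop("scheme width ", struct$scheme$total_width,
         " does not match grid channels ", spec$n_channels)
  }
  coords <- struct$coords
  if (nrow(coords) && any(!is.finite(coords))) {
    stop("structure has no finite 3D coordinates (SMILES input? embed a conformer first)")
  }
  if (!is.null(transform)) coords <- apply_transform(coords, transform, spec$center)
  np <- spec$points_per_axis
  if (nrow(coords) == 0L) {
    values <- array(0, dim = c(spec$n_channels, np, np, np))
  } else {
    values <- cpp_density(coords, struct$types, grid_origin(spec),
                          spec$resolution, np, spec$n_channels,
                          spec$atomic_radius, spec$cutoff_mult)
  }
  density_grid(values, spec)
}

#' @rdname molecule_to_grid
#' @param values Density array of dim `c(n_channels, np, np, np)`.
#' @export
density_grid <- function(values, spec) {
  stopifnot(all(dim(values) == c(spec$n_channels, rep(spec$points_per_axis, 3))))
  structure(list(values = values, spec = spec), class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d^3, total density %.3f\n",
              x$spec$n_channels, x$spec$points_per_axis, sum(x$values)))
  invisible(x)
}

# Analytic density of a typed struct at arbitrary off-lattice points
# (channels x npoints); used for rotational-equivariance checks.
density_at_points <- function(struct, points, spec) {
  points <- matrix(points, ncol = 3)
  out <- matrix(0, struct$scheme$total_width, nrow(points))
  for (a in seq_len(n_atoms(struct))) {
    d <- sqrt(colSums((t(points) - struct$coords[a, ])^2))
    k <- kernel(d, spec$atomic_radius, spec$cutoff_mult)
    out <- out + outer(struct$types[a, ], k)
  }
  out
}

#' Steric overlap between two grids
#'
#' Sums each grid across channels, multiplies the two channel-sums at every
#' grid point, and sums over points. Nonnegative, symmetric, and zero when
#' the supports are disjoint; used both as a training loss term and as an
#' empirical clash check on complexes.
#'
#' @param rec,lig Two `density_grid`s with identical geometry.
#' @return Scalar overlap.
#' @export
steric_overlap <- function(rec, lig) {
  sa <- rec$spec; sb <- lig$spec
  if (sa$points_per_axis != sb$points_per_axis ||
      any(abs(sa$center - sb$center) > 1e-9) ||
      abs(sa$resolution - sb$resolution) > 1e-12) {
    stop("grid geometries do not match")
  }
  rs <- colSums(matrix(rec$values, sa$n_channels))
  ls <- colSums(matrix(lig$values, sb$n_channels))
  sum(rs * ls)
}

#' Gradient of the grid L2 objective with respect to atom coordinates
#'
#' Analytic partial derivatives of `sum((grid(struct) - ref)^2)` w.r.t. each
#' atom coordinate (kernel chain rule), as used by the atom-fitting gradient
#' descent. Matches central finite differences to high accuracy.
#'
#' @param struct A `typed_struct`.
#' @param ref Reference `density_grid`.
#' @return N x 3 gradient matrix.
#' @export
grid_l2_gradient <- function(struct, ref) {
  spec <- ref$spec
  if (struct$scheme$total_width != spec$n_channels) stop("channel mismatch")
  if (n_atoms(struct) == 0L) return(matrix(numeric(0), ncol = 3))
  cpp_l2_gradient(struct$coords, struct$types, as.numeric(ref$values),
                  grid_origin(spec), spec$resolution, spec$points_per_axis,
                  spec$n_channels, spec$atomic_radius, spec$cutoff_mult)
}

# Grid serialization ---------------------------------------------------------
#
# Channels-first array in NPY format (v1.0, Fortran order, float64) plus a
# JSON sidecar holding the grid geometry and channel labels. Round-trips
# bit-exactly.

write_npy <- function(x, path) {
  dims <- dim(x)
  header <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': (%s), }",
                    paste0(paste(dims, collapse = ", "),
                           if (length(dims) == 1L) "," else ""))
  # pad so magic(6) + version(2) + hlen(2) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  invisible(path)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  stopifnot(identical(magic[1:6], as.raw(c(0x93, utf8ToInt("NUMPY")))))
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  if (!grepl("'<f8'", header) || !grepl("'fortran_order': True", header)) {
    stop("unsupported NPY header: ", header)
  }
  shape <- as.integer(strsplit(gsub(".*\\(([0-9, ]*)\\).*", "\\1", header),
                               ",\\s*")[[1]])
  x <- readBin(con, "numeric", prod(shape), size = 8, endian = "little")
  array(x, dim = shape)
}

#' Write a density grid to disk
#'
#' Writes `<path>.npy` (channels-first float64 array) and `<path>.json`
#' (grid geometry and channel labels).
#'
#' @param grid A `density_grid`.
#' @param path Output path stem (without extension).
#' @param channel_labels Optional character vector of channel names.
#' @export
write_grid <- function(grid, path, channel_labels = NULL) {
  write_npy(grid$values, paste0(path, ".npy"))
  side <- list(center = grid$spec$center, side = grid$spec$side,
               resolution = grid$spec$resolution,
               n_channels = grid$spec$n_channels,
               atomic_radius = grid$spec$atomic_radius,
               cutoff_mult = grid$spec$cutoff_mult,
               channel_labels = channel_labels)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a density grid written by [write_grid()]
#'
#' @param path Path stem used when writing.
#' @return A `density_grid`.
#' @export
read_grid <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- grid_spec(center = side$center, side = side$side,
                    resolution = side$resolution, n_channels = side$n_channels,
                    atomic_radius = side$atomic_radius,
                    cutoff_mult = side$cutoff_mult)
  density_grid(read_npy(paste0(path, ".npy")), spec)
}
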