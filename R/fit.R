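# Atom fitting --------------------------------------------------------------
#
# Inverse problem of gridding: recover a typed structure whose rendered
# density best matches a reference grid under an L2 objective. The solver
# alternates atom detection (local maxima of the residual density in the
# element channels) with joint gradient descent on all atom coordinates,
# accepting rounds while the L2 keeps improving.

#' Atom-fitting configuration
#'
#' @param peak_threshold Minimum residual voxel value to seed an atom
#'   (default 0.25).
#' @param max_atoms Cap on fitted atoms (default 80).
#' @param gd_steps Gradient-descent iterations per refinement (default 100).
#' @param gd_step_size Initial learning rate in angstrom scale (default 0.1).
#' @param beam_width Number of candidate structures kept per round
#'   (default 1 = greedy).
#' @param convergence_tol Relative L2 improvement floor for accepting a
#'   round (default 1e-4).
#' @param gd_tol Gradient infinity-norm below which refinement stops
#'   (default 1e-7).
#' @return A `fit_config`.
#' @export
fit_config <- function(peak_threshold = 0.25, max_atoms = 80L, gd_steps = 100L,
                       gd_step_size = 0.1, beam_width = 1L,
                       convergence_tol = 1e-4, gd_tol = 1e-7) {
  stopifnot(peak_threshold > 0, beam_width >= 1, max_atoms >= 0, gd_steps >= 0)
  structure(list(peak_threshold = peak_threshold, max_atoms = as.integer(max_atoms),
                 gd_steps = as.integer(gd_steps), gd_step_size = gd_step_size,
                 beam_width = as.integer(beam_width),
                 convergence_tol = convergence_tol, gd_tol = gd_tol),
            class = "fit_config")
}

#' Grid L2 objective
#'
#' `sum((grid(struct) - ref)^2)` over all channels and voxels.
#'
#' @param struct A `typed_struct` on the same scheme as `ref`.
#' @param ref Reference `density_grid`.
#' @return Scalar loss.
#' @export
grid_l2 <- function(struct, ref) {
  if (struct$scheme$total_width != ref$spec$n_channels) stop("channel mismatch")
  model <- molecule_to_grid(struct, ref$spec)
  sum((model$values - ref$values)^2)
}

# Residual grid (ref - rendered current struct).
fit_residual <- function(ref, current) {
  model <- molecule_to_grid(current, ref$spec)
  ref$values - model$values
}

empty_struct <- function(scheme) {
  typed_struct(matrix(numeric(0), ncol = 3),
               matrix(numeric(0), ncol = scheme$total_width), scheme)
}

#' Detect candidate atoms in the unexplained density
#'
#' Finds 26-neighbor local maxima of the residual (reference minus current
#' model) within the element channels, at or above the peak threshold,
#' sorted by residual value descending. Each candidate's non-element
#' properties are decorated from the residual's property channels at the
#' peak voxel (value >= 0.5 sets the property); property channels never
#' seed atoms on their own.
#'
#' @param ref Reference `density_grid`.
#' @param current `typed_struct` of atoms already placed (may be empty).
#' @param config A [fit_config()].
#' @return A `typed_struct` of candidates (possibly 0 atoms), ordered by
#'   peak value, with attribute `"peak_values"`.
#' @export
detect_next_atoms <- function(ref, current, config = fit_config()) {
  scheme <- current$scheme
  spec <- ref$spec
  resid <- fit_residual(ref, current)
  peaks <- cpp_detect_peaks(as.numeric(resid), spec$points_per_axis,
                            spec$n_channels, n_element_channels(scheme),
                            config$peak_threshold)
  if (nrow(peaks) == 0L) {
    out <- empty_struct(scheme)
    attr(out, "peak_values") <- numeric(0)
    return(out)
  }
  axes <- grid_coordinates(spec)
  elems <- scheme_elements(scheme)
  coords <- cbind(axes$x[peaks[, 1] + 1], axes$y[peaks[, 2] + 1],
                  axes$z[peaks[, 3] + 1])
  types <- matrix(0, nrow(peaks), scheme$total_width)
  has <- function(p) !is.null(scheme$properties[[p]])
  for (k in seq_len(nrow(peaks))) {
    vox <- resid[, peaks[k, 1] + 1, peaks[k, 2] + 1, peaks[k, 3] + 1]
    chg <- 0L
    if (has("charge")) {
      chg_block <- vox[scheme_slots(scheme, "charge")]
      if (max(chg_block) >= 0.5) {
        chg <- scheme$properties[["charge"]]$values[which.max(chg_block)]
      }
    }
    types[k, ] <- type_atom(
      elems[peaks[k, 4] + 1],
      aromatic = has("aromatic") && vox[scheme_slots(scheme, "aromatic")[2]] >= 0.5,
      acceptor = has("acceptor") && vox[scheme_slots(scheme, "acceptor")] >= 0.5,
      donor = has("donor") && vox[scheme_slots(scheme, "donor")] >= 0.5,
      charge = chg, scheme = scheme)
  }
  out <- typed_struct(coords, types, scheme)
  attr(out, "peak_values") <- peaks[, 5]
  out
}

#' Refine atom coordinates by gradient descent
#'
#' Joint gradient descent on all atom coordinates against the grid L2
#' objective, with backtracking step-size control; atom types are never
#' changed and the best iterate is kept, so the returned loss never exceeds
#' the input loss.
#'
#' @param struct A `typed_struct`.
#' @param ref Reference `density_grid`.
#' @param config A [fit_config()].
#' @return The refined `typed_struct`, with attribute `"loss"`.
#' @export
refine_coordinates <- function(struct, ref, config = fit_config()) {
  spec <- ref$spec
  if (struct$scheme$total_width != spec$n_channels) stop("channel mismatch")
  res <- cpp_refine(struct$coords, struct$types, as.numeric(ref$values),
                    grid_origin(spec), spec$resolution, spec$points_per_axis,
                    spec$n_channels, spec$atomic_radius, spec$cutoff_mult,
                    config$gd_steps, config$gd_step_size,
                    if (is.null(config$gd_tol)) 1e-7 else config$gd_tol)
  out <- typed_struct(res$coords, struct$types, struct$scheme)
  attr(out, "loss") <- res$loss
  attr(out, "steps") <- res$steps
  out
}

add_atom <- function(struct, coords, type) {
  typed_struct(rbind(struct$coords, coords), rbind(struct$types, type),
               struct$scheme)
}

#' Fit atoms to a reference density grid
#'
#' Iterates atom detection and gradient-descent refinement: each round seeds
#' new atom candidates from the residual density, refines all coordinates,
#' and accepts the round if the L2 improves by more than
#' `convergence_tol * previous_loss`. Stops when no candidates remain, the
#' improvement stalls, or `max_atoms` is reached. With `beam_width > 1`,
#' each round expands every kept structure with its top candidates and
#' retains the `beam_width` best structures by L2, returning the best.
#'
#' @param ref Reference `density_grid`.
#' @param scheme Typing scheme matching the grid channels.
#' @param config A [fit_config()].
#' @return A `fit_result`: `struct`, `final_loss`, `loss_trace` (accepted
#'   rounds, nonincreasing), `n_rounds`.
#' @export
fit_atoms <- function(ref, scheme = default_scheme("ligand"),
                      config = fit_config()) {
  if (scheme$total_width != ref$spec$n_channels) stop("channel mismatch")
  base <- empty_struct(scheme)
  base_loss <- sum(ref$values^2)
  beams <- list(list(struct = base, loss = base_loss))
  trace <- base_loss
  n_rounds <- 0L
  repeat {
    if (n_atoms(beams[[1]]$struct) >= config$max_atoms) break
    children <- list()
    for (b in beams) {
      cand <- detect_next_atoms(ref, b$struct, config)
      ncand <- min(n_atoms(cand), config$beam_width)
      if (ncand == 0L) next
      for (k in seq_len(ncand)) {
        child <- add_atom(b$struct, cand$coords[k, ], cand$types[k, ])
        child <- refine_coordinates(child, ref, config)
        children[[length(children) + 1L]] <-
          list(struct = child, loss = attr(child, "loss"))
      }
    }
    if (length(children) == 0L) break
    children <- children[order(vapply(children, `[[`, numeric(1), "loss"))]
    best <- children[[1]]
    prev <- beams[[1]]$loss
    if (best$loss > prev - config$convergence_tol * prev) break
    beams <- children[seq_len(min(length(children), config$beam_width))]
    n_rounds <- n_rounds + 1L
    trace <- c(trace, best$loss)
  }
  best <- beams[[1]]
  polished <- snap_polish(best$struct, ref, best$loss)
  if (polished$loss < best$loss) {
    best <- polished
    trace <- c(trace, polished$loss)
  }
  structure(list(struct = best$struct, final_loss = best$loss,
                 loss_trace = trace, n_rounds = n_rounds),
            class = "fit_result")
}

# The truncated kernel is discontinuous at its support boundary, so the L2
# surface has small jumps where a voxel crosses the cutoff sphere; gradient
# descent can stall a hair away from an exactly-on-lattice optimum. Try
# snapping each atom to the grid nodes at its cell corners and keep strict
# improvements (inert for off-lattice optima).
snap_polish <- function(struct, ref, loss) {
  if (n_atoms(struct) == 0L) return(list(struct = struct, loss = loss))
  spec <- ref$spec
  res <- cpp_snap_polish(struct$coords, struct$types, as.numeric(ref$values),
                         grid_origin(spec), spec$resolution,
                         spec$points_per_axis, spec$n_channels,
                         spec$atomic_radius, spec$cutoff_mult)
  if (res$loss < loss) {
    list(struct = typed_struct(res$coords, struct$types, struct$scheme),
         loss = res$loss)
  } else {
    list(struct = struct, loss = loss)
  }
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d atoms in %d rounds, final L2 %.4g\n",
              n_atoms(x$struct), x$n_rounds, x$final_loss))
  invisible(x)
}
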