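# Latent-space sampling controls ---------------------------------------------
#
# Posterior sampling encodes a real complex into the latent distribution
# before drawing; prior sampling draws from the standard normal. Two
# controls modulate generation: the variability factor scales the latent
# standard deviation (z' = mu + lambda_var * sigma * eps), and the bias
# factor linearly interpolates the sampled distribution's parameters
# between the prior (0) and the posterior (1).

#' Sampling specification
#'
#' @param mode `"posterior"` or `"prior"`.
#' @param lambda_var Variability factor, `>= 0` (default 1.0).
#' @param lambda_bias Bias factor in `[0, 1]`; defaults to the mode-implied
#'   value (1 for posterior, 0 for prior).
#' @param n_samples Number of samples (default 100).
#' @param rng_seed Master seed; each sample index derives its own stream,
#'   so results are reproducible and order-independent.
#' @return A `sample_spec`.
#' @export
sample_spec <- function(mode = c("posterior", "prior"), lambda_var = 1.0,
                        lambda_bias = NULL, n_samples = 100L, rng_seed = 1L) {
  mode <- match.arg(mode)
  if (lambda_var < 0) stop("variability factor must be nonnegative")
  if (is.null(lambda_bias)) lambda_bias <- if (mode == "posterior") 1.0 else 0.0
  if (lambda_bias < 0 || lambda_bias > 1) stop("bias factor must lie in [0, 1]")
  stopifnot(n_samples >= 1)
  structure(list(mode = mode, lambda_var = lambda_var,
                 lambda_bias = lambda_bias, n_samples = as.integer(n_samples),
                 rng_seed = as.integer(rng_seed)),
            class = "sample_spec")
}

standard_prior <- function(dim) latent_distribution(numeric(dim), rep(1, dim))

#' Draw latent vectors with the variability factor
#'
#' `z' = mu + lambda_var * sigma * eps` with `eps ~ N(0, 1)` i.i.d.;
#' `lambda_var = 0` returns the mean exactly. In prior mode the
#' distribution is the standard normal.
#'
#' @param latent A [latent_distribution()], or `NULL` with `dim` given for
#'   the prior.
#' @param spec A [sample_spec()].
#' @param n Number of vectors (default `spec$n_samples`).
#' @param dim Latent dimension when `latent` is `NULL`.
#' @return `n x dim` matrix of latent vectors.
#' @export
sample_latent <- function(latent, spec = sample_spec(), n = spec$n_samples,
                          dim = NULL) {
  if (is.null(latent)) {
    if (is.null(dim)) stop("dim required for prior sampling")
    latent <- standard_prior(dim)
  }
  d <- length(latent$mean)
  out <- matrix(0, n, d)
  for (k in seq_len(n)) {
    eps <- with_seed(spec$rng_seed + k, stats::rnorm(d))
    out[k, ] <- latent$mean + spec$lambda_var * latent$std * eps
  }
  out
}

#' Interpolate between prior and posterior latent parameters
#'
#' `mu' = lambda_bias * mu_post`, `sigma' = lambda_bias * sigma_post +
#' (1 - lambda_bias)`; the endpoints reproduce the prior (0) and the
#' posterior (1) exactly.
#'
#' @param posterior A [latent_distribution()].
#' @param lambda_bias Bias factor in `[0, 1]`.
#' @return The interpolated `latent_distribution`.
#' @export
interpolate_distribution <- function(posterior, lambda_bias) {
  if (lambda_bias < 0 || lambda_bias > 1) stop("bias factor must lie in [0, 1]")
  latent_distribution(lambda_bias * posterior$mean,
                      lambda_bias * posterior$std + (1 - lambda_bias))
}

slerp_pair <- function(a, b, t) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  ua <- a / na; ub <- b / nb
  cosw <- max(-1, min(1, sum(ua * ub)))
  omega <- acos(cosw)
  dir <- if (omega < 1e-8) {
    (1 - t) * ua + t * ub
  } else if (abs(omega - pi) < 1e-6) {
    # antiparallel: plane of rotation undefined, fall back to linear
    warning("antiparallel latent endpoints; falling back to linear interpolation")
    v <- (1 - t) * a + t * b
    return(v)
  } else {
    (sin((1 - t) * omega) * ua + sin(t * omega) * ub) / sin(omega)
  }
  ((1 - t) * na + t * nb) * dir
}

#' Spherical interpolation trajectory through latent vectors
#'
#' Per segment, the direction rotates at constant angular speed in the
#' plane of the two endpoints while the vector norm interpolates linearly;
#' the trajectory passes exactly through every endpoint. Antiparallel
#' endpoints fall back to linear interpolation with a warning.
#'
#' @param endpoints List (or matrix rows) of latent vectors, at least two.
#' @param steps_per_segment Steps from one endpoint to the next; endpoints
#'   land at indices `1, steps+1, 2*steps+1, ...`.
#' @return Matrix of latent vectors along the trajectory, with attribute
#'   `"weights"` giving each row's interpolation weight pair.
#' @export
slerp_trajectory <- function(endpoints, steps_per_segment = 5L) {
  if (is.matrix(endpoints)) endpoints <- asplit(endpoints, 1)
  ne <- length(endpoints)
  if (ne < 2L) stop("need at least two endpoints")
  if (any(vapply(endpoints, function(e) sqrt(sum(e^2)), numeric(1)) == 0)) {
    stop("endpoints must be nonzero vectors")
  }
  out <- list()
  wts <- list()
  for (s in seq_len(ne - 1L)) {
    a <- as.numeric(endpoints[[s]]); b <- as.numeric(endpoints[[s + 1L]])
    last <- s == ne - 1L
    ts <- seq(0, 1, length.out = steps_per_segment + 1L)
    if (!last) ts <- ts[-length(ts)]
    for (t in ts) {
      out[[length(out) + 1L]] <- slerp_pair(a, b, t)
      wts[[length(wts) + 1L]] <- c(1 - t, t)
    }
  }
  traj <- do.call(rbind, out)
  attr(traj, "weights") <- do.call(rbind, wts)
  traj
}

#' Interpolate between encoded ligands in latent space
#'
#' Encodes each reference ligand (with the shared receptor) to its
#' posterior mean, builds a spherical interpolation trajectory through the
#' latent vectors, and decodes every step conditioned on the receptor. The
#' conditional grid center moves smoothly along the trajectory: at step t
#' of a segment it is the linear interpolation of the segment's ligand
#' heavy-atom centroids.
#'
#' @param receptor Receptor `typed_struct`.
#' @param ligands List of at least two ligand `typed_struct`s bound to the
#'   receptor.
#' @param model A `cvae_model`.
#' @param steps_per_segment Interpolation steps between consecutive
#'   ligands (default 5).
#' @param fit_cfg [fit_config()] for density inversion.
#' @param rules [bond_rules()] for bond inference.
#' @param resolution Grid resolution (default 0.5 A).
#' @return List of per-step results: `grid`, `molecule`, `z`, `center`,
#'   `weights` (endpoint interpolation weights).
#' @export
latent_interpolation <- function(receptor, ligands, model,
                                 steps_per_segment = 5L,
                                 fit_cfg = fit_config(), rules = bond_rules(),
                                 resolution = 0.5) {
  stopifnot(length(ligands) >= 2)
  cfg <- model$config
  centers <- lapply(ligands, function(l) colMeans(l$coords))
  zs <- lapply(seq_along(ligands), function(k) {
    ctr <- centers[[k]]
    rec_grid <- molecule_to_grid(receptor,
                                 model_grid_spec(cfg, ctr, resolution, "receptor"))
    lig_grid <- molecule_to_grid(ligands[[k]],
                                 model_grid_spec(cfg, ctr, resolution, "ligand"))
    encode_input(rec_grid, lig_grid, model)$mean
  })
  traj <- slerp_trajectory(zs, steps_per_segment)
  wts <- attr(traj, "weights")
  lig_scheme <- default_scheme("ligand")
  out <- vector("list", nrow(traj))
  for (i in seq_len(nrow(traj))) {
    seg <- min((i - 1L) %/% steps_per_segment + 1L, length(ligands) - 1L)
    t <- wts[i, 2]
    center <- (1 - t) * centers[[seg]] + t * centers[[seg + 1L]]
    rec_grid <- molecule_to_grid(receptor,
                                 model_grid_spec(cfg, center, resolution, "receptor"))
    cond <- encode_condition(rec_grid, model)
    g <- decode(traj[i, ], cond, model)
    fit <- fit_atoms(g, lig_scheme, fit_cfg)
    out[[i]] <- list(grid = g, molecule = make_molecule(fit$struct, rules),
                     z = traj[i, ], center = center, weights = wts[i, ])
  }
  out
}

#' Generate molecules conditioned on a receptor
#'
#' Full generation pipeline: grid the receptor (and, for posterior mode,
#' the ligand), encode, interpolate the latent parameters by the bias
#' factor, draw latent vectors with the variability factor, decode with
#' the conditional code, then invert each generated density by atom
#' fitting and bond inference.
#'
#' @param receptor Receptor `typed_struct` (receptor scheme).
#' @param ligand Ligand `typed_struct`; required for posterior mode (also
#'   sets the grid center; in prior mode the center defaults to the
#'   receptor centroid).
#' @param model A `cvae_model`.
#' @param spec A [sample_spec()].
#' @param fit_cfg A [fit_config()] for density inversion.
#' @param rules [bond_rules()] for bond inference.
#' @param resolution Grid resolution (default 0.5 A).
#' @return List of per-sample results: `grid`, `molecule`, `z`, `fit_loss`,
#'   `valid`.
#' @export
generate <- function(receptor, ligand = NULL, model, spec = sample_spec(),
                     fit_cfg = fit_config(), rules = bond_rules(),
                     resolution = 0.5) {
  cfg <- model$config
  if (spec$mode == "posterior" && is.null(ligand)) {
    stop("posterior sampling requires the reference ligand")
  }
  center <- if (!is.null(ligand)) colMeans(ligand$coords)
            else colMeans(receptor$coords)
  spec_r <- model_grid_spec(cfg, center, resolution, "receptor")
  rec_grid <- molecule_to_grid(receptor, spec_r)
  cond <- encode_condition(rec_grid, model)
  latent <- if (spec$mode == "posterior") {
    spec_l <- model_grid_spec(cfg, center, resolution, "ligand")
    lig_grid <- molecule_to_grid(ligand, spec_l)
    encode_input(rec_grid, lig_grid, model)
  } else {
    standard_prior(cfg$latent_dim)
  }
  latent <- interpolate_distribution(latent, spec$lambda_bias)
  zs <- sample_latent(latent, spec)
  lig_scheme <- default_scheme("ligand")
  lapply(seq_len(spec$n_samples), function(k) {
    g <- decode(zs[k, ], cond, model)
    fit <- fit_atoms(g, lig_scheme, fit_cfg)
    mol <- make_molecule(fit$struct, rules)
    list(grid = g, molecule = mol, z = zs[k, ], fit_loss = fit$final_loss,
         valid = isTRUE(mol$valid))
  })
}
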