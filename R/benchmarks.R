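# Validation studies ---------------------------------------------------------
#
# Reproducible study runners used by the test suite and the acceptance
# script: structure-recovery round trips through the grid representation,
# the exhaustive fitting oracle on toy grids, the SMILES round trip over
# the curated molecule list, and the desk-scale CVAE overfit run.

#' Structure-recovery round trip study
#'
#' Generates seeded fixture molecules (5-20 atoms, pairwise separation at
#' least 2 A), grids each on the default geometry, and fits atoms back
#' from the grid. A fixture counts as recovered when the fitted structure
#' reproduces the exact atom count and type vectors.
#'
#' @param n_fixtures Number of fixtures (default 200).
#' @param rng_seed Base seed; fixture k uses `rng_seed + k`.
#' @param fit_cfg Fitting configuration.
#' @return List: `recovery_rate` (fraction), `mean_coord_error` (A, over
#'   recovered fixtures), `max_final_loss`, `mean_final_loss`, and the
#'   per-fixture data.frame `details`.
#' @export
fit_roundtrip_study <- function(n_fixtures = 200L, rng_seed = 1L,
                                fit_cfg = fit_config()) {
  scheme <- default_scheme("ligand")
  res <- data.frame(recovered = logical(n_fixtures),
                    coord_error = NA_real_, final_loss = NA_real_,
                    n_atoms = NA_integer_)
  for (k in seq_len(n_fixtures)) {
    st <- make_fixture_molecule(fixture_spec(rng_seed = rng_seed + k))
    spec <- grid_spec(center = colMeans(st$coords))
    ref <- molecule_to_grid(st, spec)
    fr <- fit_atoms(ref, scheme, fit_cfg)
    res$n_atoms[k] <- nrow(st$coords)
    res$final_loss[k] <- fr$final_loss
    if (nrow(fr$struct$coords) == nrow(st$coords)) {
      map <- apply(fr$struct$coords, 1, function(r) {
        which.min(colSums((t(st$coords) - r)^2))
      })
      if (length(unique(map)) == nrow(st$coords) &&
          isTRUE(all.equal(fr$struct$types[order(map), ], st$types))) {
        res$recovered[k] <- TRUE
        res$coord_error[k] <- mean(sqrt(rowSums(
          (fr$struct$coords[order(map), ] - st$coords)^2)))
      }
    }
  }
  list(recovery_rate = mean(res$recovered),
       mean_coord_error = mean(res$coord_error[res$recovered]),
       max_final_loss = max(res$final_loss),
       mean_final_loss = mean(res$final_loss),
       details = res)
}

#' Exhaustive fitting oracle study on toy grids
#'
#' On single-channel 8^3 grids holding one or two lattice-placed atoms,
#' compares the greedy fit's final L2 against exhaustive enumeration of
#' all 1- and 2-atom lattice placements.
#'
#' @param n_grids Number of toy grids (default 50).
#' @param rng_seed Base seed.
#' @param fit_cfg Fitting configuration; the default deepens the
#'   gradient-descent budget so the optimality comparison measures the
#'   solver's limit, not its iteration cap.
#' @return List: `max_gap` (largest `fit - oracle` L2 difference),
#'   `n_grids`, and per-grid `details`.
#' @export
fit_oracle_study <- function(n_grids = 50L, rng_seed = 1L,
                             fit_cfg = fit_config(gd_steps = 2000L,
                                                  gd_tol = 1e-9)) {
  sc <- type_scheme("ligand", list(atom_property("element", "C")))
  spec <- grid_spec(center = c(0, 0, 0), side = 3.5, resolution = 0.5,
                    n_channels = 1L)
  ax <- grid_coordinates(spec)
  lattice <- as.matrix(expand.grid(ax$x, ax$y, ax$z))
  D <- apply(lattice, 1, function(p) {
    kernel(sqrt(colSums((t(lattice) - p)^2)), spec$atomic_radius,
           spec$cutoff_mult)
  })
  G <- crossprod(D)
  nrm <- colSums(D^2)
  details <- data.frame(fit = numeric(n_grids), oracle = numeric(n_grids))
  for (k in seq_len(n_grids)) {
    st <- with_seed(rng_seed + k, {
      n <- sample(1:2, 1)
      pos <- lattice[sample(nrow(lattice), 6), , drop = FALSE]
      keep <- pos[1, , drop = FALSE]
      for (j in 2:nrow(pos)) {
        if (nrow(keep) < n &&
            min(sqrt(rowSums((keep - matrix(pos[j, ], nrow(keep), 3,
                                            byrow = TRUE))^2))) >= 2) {
          keep <- rbind(keep, pos[j, ])
        }
      }
      typed_struct(keep, matrix(1, nrow(keep), 1), sc)
    })
    ref <- molecule_to_grid(st, spec)
    rv <- as.numeric(ref$values)
    dref <- drop(crossprod(D, rv))
    ssr <- sum(rv^2)
    best <- min(nrm - 2 * dref + ssr)
    loss2 <- outer(nrm, nrm, "+") + 2 * G - 2 * outer(dref, dref, "+") + ssr
    best <- min(best, min(loss2))
    fr <- fit_atoms(ref, sc, fit_cfg)
    details$fit[k] <- fr$final_loss
    details$oracle[k] <- best
  }
  list(max_gap = max(details$fit - details$oracle), n_grids = n_grids,
       details = details)
}

#' SMILES round-trip study over the curated molecule list
#'
#' For every molecule of the shipped fixture list: type the heavy atoms,
#' grid, fit atoms back, infer bonds and hydrogens, and compare the
#' resulting canonical SMILES with the input's.
#'
#' @param fit_cfg Fitting configuration.
#' @return List: `success_rate`, `n`, and per-molecule `details` with
#'   failure reasons.
#' @export
smiles_roundtrip_study <- function(fit_cfg = fit_config()) {
  mols <- load_fixture_molecules()
  details <- data.frame(name = vapply(mols, function(m) m$name, character(1)),
                        reference = vapply(mols, function(m) attr(m, "smiles"),
                                           character(1)),
                        recovered = NA_character_, ok = FALSE,
                        reason = NA_character_)
  for (k in seq_along(mols)) {
    st <- type_molecule(mols[[k]])
    spec <- grid_spec(center = colMeans(st$coords))
    fr <- fit_atoms(molecule_to_grid(st, spec), st$scheme, fit_cfg)
    im <- make_molecule(fr$struct)
    if (!isTRUE(im$valid)) {
      details$reason[k] <- im$failure_reason
      next
    }
    smi <- mol_to_smiles(im)
    details$recovered[k] <- smi
    details$ok[k] <- identical(smi, details$reference[k])
    if (!details$ok[k]) details$reason[k] <- "SMILES mismatch"
  }
  list(success_rate = mean(details$ok), n = nrow(details), details = details)
}

#' Desk-scale CVAE overfit study
#'
#' Trains a reduced model (12^3 grids, two levels) on five fixture
#' complexes and reports the reconstruction-loss reduction, a desk-scale
#' trainability proxy (full-scale training is out of reach on one CPU).
#'
#' @param n_iterations Training iterations (default 2000).
#' @param rng_seed Seed for fixtures, initialization and training.
#' @param batch_size Complexes per iteration (default 2).
#' @param learning_rate RMSprop step (default 1e-4; the reduced model
#'   tolerates a larger step than the full-scale default).
#' @return List: `initial_recon` (mean of first 10 iterations),
#'   `final_recon` (mean of last 50), `reduction` (1 - final/initial), and
#'   the training `history`.
#' @export
cvae_overfit_study <- function(n_iterations = 2000L, rng_seed = 1L,
                               batch_size = 2L, learning_rate = 1e-4) {
  cxs <- lapply(seq_len(5), function(s) {
    make_fixture_complex(rng_seed = rng_seed + s, n_ligand_atoms = 3L,
                         shell_radius = 4.5, cavity_radius = 1.2,
                         min_separation = 1.2, n_receptor_atoms = 20L)
  })
  cfg <- model_config(grid_points = 12L, latent_dim = 16L, n_levels = 2L,
                      block_widths = c(8L, 16L))
  model <- cvae_model(cfg, rng_seed = rng_seed)
  tc <- train_config(learning_rate = learning_rate, batch_size = batch_size,
                     rng_seed = rng_seed)
  model <- train_cvae(cxs, model, tc, n_iterations = n_iterations)
  h <- attr(model, "history")
  initial <- mean(h$recon[seq_len(min(10, nrow(h)))])
  final <- mean(utils::tail(h$recon, 50))
  list(initial_recon = initial, final_recon = final,
       reduction = 1 - final / initial, history = h, model = model)
}
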