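# Molecule-level evaluation metrics ------------------------------------------
#
# Validity (single connected fragment + sanitizable), novelty and
# uniqueness over canonical SMILES, Tanimoto fingerprint similarity and
# per-target diversity, molecular weight, and UFF relaxation displacement.

ATOMIC_MASSES <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                   F = 18.998, P = 30.974, S = 32.06, Cl = 35.453,
                   Br = 79.904, I = 126.904, Fe = 55.845, Na = 22.990,
                   Mg = 24.305, K = 39.098, Ca = 40.078, Zn = 65.38)

#' Is a molecule valid?
#'
#' A molecule is valid iff it consists of a single connected fragment and
#' passes an independent sanitization: the valence of every atom within
#' its (charge-adjusted) maximum and a successful kekulized round trip
#' through the OpenBabel canonical SMILES writer.
#'
#' @param mol An `inferred_molecule`.
#' @param rules [bond_rules()] supplying the valence table.
#' @return Logical.
#' @export
is_valid <- function(mol, rules = bond_rules()) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(FALSE)
  if (!is.null(mol$failure_reason) &&
      mol$failure_reason %in% c("kekulization/aromaticity failure")) return(FALSE)
  g <- igraph::graph_from_edgelist(cbind(mol$bonds$i, mol$bonds$j),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (igraph::components(g)$no != 1L) return(FALSE)
  s <- numeric(n)
  for (k in seq_len(nrow(mol$bonds))) {
    s[mol$bonds$i[k]] <- s[mol$bonds$i[k]] + mol$bonds$order[k]
    s[mol$bonds$j[k]] <- s[mol$bonds$j[k]] + mol$bonds$order[k]
  }
  for (a in seq_len(n)) {
    cap <- tryCatch(adjusted_valence(rules$max_valence, mol$atoms$element[a],
                                     mol$atoms$charge[a]),
                    error = function(e) NA_real_)
    if (is.na(cap) || s[a] > cap) return(FALSE)
  }
  !is.na(mol_to_smiles(mol))
}

#' Is a molecule novel relative to a reference set?
#'
#' TRUE iff the canonical SMILES is absent from the reference (training)
#' set. Call on valid molecules; invalid molecules are excluded from
#' novelty denominators by the aggregate report.
#'
#' @param mol An `inferred_molecule`, `mol3d`, or SMILES string.
#' @param reference_smiles_set Character vector of canonical SMILES.
#' @return Logical.
#' @export
is_novel <- function(mol, reference_smiles_set) {
  smi <- if (is.character(mol)) mol else mol_to_smiles(mol)
  if (is.na(smi)) return(NA)
  !(smi %in% reference_smiles_set)
}

#' Is a molecule unique among those generated so far?
#'
#' @param mol As in [is_novel()].
#' @param already_generated_set Character vector of canonical SMILES seen
#'   so far.
#' @return List with `unique` (logical) and the updated `set`.
#' @export
is_unique <- function(mol, already_generated_set = character(0)) {
  smi <- if (is.character(mol)) mol else mol_to_smiles(mol)
  if (is.na(smi)) return(list(unique = NA, set = already_generated_set))
  list(unique = !(smi %in% already_generated_set),
       set = union(already_generated_set, smi))
}

# Fingerprint bit set (positions of set bits) via OpenBabel; FP2 is a
# 1024-bit path-based fingerprint.
fingerprint_bits <- function(mol, kind = "FP2") {
  if (inherits(mol, "inferred_molecule")) mol <- inferred_to_mol3d(mol)
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  write_sdf(mol, tmp)
  sdfset <- ChemmineR::read.SDFset(tmp)
  fp <- ChemmineR::fingerprintOB(sdfset, kind)
  which(as.numeric(ChemmineR::as.matrix(fp)[1, ]) != 0)
}

#' Tanimoto fingerprint similarity
#'
#' `|A intersect B| / |A union B|` over the set bits of the configured
#' fingerprint (default OpenBabel FP2, a 1024-bit path fingerprint). If
#' both fingerprints are empty the similarity is 1 for identical canonical
#' SMILES and 0 otherwise.
#'
#' @param mol_a,mol_b Molecules (`inferred_molecule` or `mol3d`).
#' @param kind Fingerprint name passed to OpenBabel (default `"FP2"`).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(mol_a, mol_b, kind = "FP2") {
  ba <- fingerprint_bits(mol_a, kind)
  bb <- fingerprint_bits(mol_b, kind)
  if (length(ba) == 0L && length(bb) == 0L) {
    return(as.numeric(identical(mol_to_smiles(mol_a), mol_to_smiles(mol_b))))
  }
  length(intersect(ba, bb)) / length(union(ba, bb))
}

#' Per-target diversity
#'
#' Inverse of the mean Tanimoto similarity over all unordered distinct
#' pairs of the given molecules (generated for one conditional receptor).
#'
#' @param mols List of at least two valid molecules.
#' @param kind Fingerprint name (default `"FP2"`).
#' @return Scalar diversity (`>= 1` when mean similarity `<= 1`), or `NA`
#'   with fewer than two molecules.
#' @export
per_target_diversity <- function(mols, kind = "FP2") {
  n <- length(mols)
  if (n < 2L) return(NA_real_)
  bits <- lapply(mols, fingerprint_bits, kind = kind)
  sims <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ba <- bits[[i]]; bb <- bits[[j]]
    sims <- c(sims, if (length(ba) == 0L && length(bb) == 0L) 1
              else length(intersect(ba, bb)) / length(union(ba, bb)))
  }
  1 / mean(sims)
}

#' Molecular weight
#'
#' Sum of standard atomic masses over all atoms including implicit
#' hydrogens, in daltons.
#'
#' @param mol An `inferred_molecule` (or `mol3d` with explicit hydrogens).
#' @return Weight in Da (0 for an empty molecule).
#' @export
molecular_weight <- function(mol) {
  if (inherits(mol, "mol3d")) {
    return(sum(ATOMIC_MASSES[mol$atoms$element]))
  }
  if (nrow(mol$atoms) == 0L) return(0)
  sum(ATOMIC_MASSES[mol$atoms$element]) +
    sum(mol$atoms$implicit_h) * ATOMIC_MASSES[["H"]]
}

# Heavy-atom RMSD under identity atom mapping.
coord_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

uff_energy <- function(sdf_path) {
  out <- suppressWarnings(system2("obenergy", c("-ff", "UFF", sdf_path),
                                  stdout = TRUE, stderr = TRUE))
  ln <- grep("TOTAL ENERGY", out, value = TRUE)
  if (!length(ln)) return(NA_real_)
  as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1", ln[length(ln)]))
}

#' Relax a molecule with UFF and measure the displacement
#'
#' Adds explicit hydrogens, minimizes the internal degrees of freedom with
#' the Universal Force Field (OpenBabel's obminimize), and returns the
#' energy change (kcal/mol) and the heavy-atom RMSD between the pre- and
#' post-minimization poses under identity atom mapping. The downstream
#' "< 2 A" displacement gate is a threshold on the returned RMSD. The
#' receptor context is not included in the minimization (internal strain
#' only); a supplied receptor is currently ignored.
#'
#' @param mol A valid `inferred_molecule`.
#' @param receptor Optional receptor structure (unused; see above).
#' @param steps Maximum minimization steps (default 500).
#' @return List with `delta_e` (kcal/mol), `rmsd` (angstroms), or reason
#'   under `missing` if force-field setup failed.
#' @export
relax_and_rmsd <- function(mol, receptor = NULL, steps = 500L) {
  if (inherits(mol, "inferred_molecule")) {
    if (!isTRUE(mol$valid)) {
      return(list(delta_e = NA_real_, rmsd = NA_real_,
                  missing = "invalid molecule"))
    }
    mol <- inferred_to_mol3d(mol)
  }
  pre <- tempfile(fileext = ".sdf"); post <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(pre, post)))
  write_sdf(mol, pre)
  # explicit hydrogens for the force field
  preh <- tempfile(fileext = ".sdf"); on.exit(unlink(preh), add = TRUE)
  system2("obabel", c(pre, "-osdf", "-h", "-O", preh), stdout = FALSE,
          stderr = FALSE)
  e0 <- uff_energy(preh)
  status <- suppressWarnings(system2("obminimize",
                                     c("-ff", "UFF", "-n", steps, "-osdf", preh),
                                     stdout = post, stderr = FALSE))
  minimized <- tryCatch(read_structures(post, "SDF")[[1]],
                        error = function(e) NULL)
  if (is.null(minimized) || is.na(e0)) {
    return(list(delta_e = NA_real_, rmsd = NA_real_,
                missing = "force-field setup failure"))
  }
  e1 <- uff_energy(post)
  nheavy <- nrow(mol$atoms)
  pre_xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  post_heavy <- minimized$atoms[minimized$atoms$element != "H", , drop = FALSE]
  if (nrow(post_heavy) != nheavy) {
    return(list(delta_e = NA_real_, rmsd = NA_real_,
                missing = "atom count changed during minimization"))
  }
  list(delta_e = e1 - e0,
       rmsd = coord_rmsd(pre_xyz, as.matrix(post_heavy[, c("x", "y", "z")])),
       missing = NULL)
}

#' Aggregate metric report over generated molecules
#'
#' Computes per-molecule validity, canonical SMILES, novelty, uniqueness,
#' molecular weight and (optionally) Tanimoto similarity to a reference
#' molecule, plus per-target aggregates. Novelty and uniqueness
#' percentages are reported both over valid molecules (default
#' denominator) and over all samples.
#'
#' @param mols List of `inferred_molecule`s generated for one target.
#' @param reference_smiles_set Canonical SMILES of the training set.
#' @param reference_mol Optional reference molecule for similarity.
#' @param kind Fingerprint name (default `"FP2"`).
#' @return A `metric_report`: `per_molecule` data.frame and `aggregate`
#'   list.
#' @export
evaluate_molecules <- function(mols, reference_smiles_set = character(0),
                               reference_mol = NULL, kind = "FP2") {
  n <- length(mols)
  valid <- vapply(mols, is_valid, logical(1))
  smiles <- rep(NA_character_, n)
  smiles[valid] <- vapply(mols[valid], mol_to_smiles, character(1))
  novel <- ifelse(valid, !(smiles %in% reference_smiles_set), NA)
  unique_flag <- rep(NA, n)
  seen <- character(0)
  for (k in which(valid)) {
    u <- is_unique(smiles[k], seen)
    unique_flag[k] <- u$unique
    seen <- u$set
  }
  mw <- vapply(seq_len(n), function(k) {
    if (valid[k]) molecular_weight(mols[[k]]) else NA_real_
  }, numeric(1))
  sim <- rep(NA_real_, n)
  if (!is.null(reference_mol)) {
    for (k in which(valid)) sim[k] <- tanimoto(mols[[k]], reference_mol, kind)
  }
  per <- data.frame(valid = valid, canonical_smiles = smiles, novel = novel,
                    unique = unique_flag, mol_weight = mw,
                    tanimoto_to_reference = sim)
  nv <- sum(valid)
  agg <- list(
    n = n, n_valid = nv,
    percent_valid = 100 * nv / n,
    percent_novel_valid = if (nv) 100 * sum(novel[valid]) / nv else NA_real_,
    percent_unique_valid = if (nv) 100 * sum(unique_flag[valid]) / nv else NA_real_,
    percent_novel_all = 100 * sum(novel[valid]) / n,
    percent_unique_all = 100 * sum(unique_flag[valid]) / n,
    diversity = if (nv >= 2) per_target_diversity(mols[valid], kind) else NA_real_,
    mean_mol_weight = if (nv) mean(mw[valid]) else NA_real_
  )
  structure(list(per_molecule = per, aggregate = agg), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<metric_report> n=%d valid=%.1f%% novel=%.1f%% unique=%.1f%% diversity=%.2f\n",
              a$n, a$percent_valid,
              ifelse(is.na(a$percent_novel_valid), NaN, a$percent_novel_valid),
              ifelse(is.na(a$percent_unique_valid), NaN, a$percent_unique_valid),
              ifelse(is.na(a$diversity), NaN, a$diversity)))
  invisible(x)
}

#' Tabulate bond, angle and torsion geometry
#'
#' Extraction utility for geometric distributions: bonds keyed by element
#' pair and order, angles by typed triples, torsions by typed quadruples.
#'
#' @param mol An `inferred_molecule`.
#' @return List of data.frames `bonds`, `angles`, `torsions`.
#' @export
tabulate_geometry <- function(mol) {
  at <- mol$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  bonds <- mol$bonds
  bl <- data.frame(key = character(0), order = integer(0), length = numeric(0))
  if (nrow(bonds)) {
    bl <- data.frame(
      key = vapply(seq_len(nrow(bonds)), function(k) {
        pair_key(at$element[bonds$i[k]], at$element[bonds$j[k]])
      }, character(1)),
      order = bonds$order,
      length = sqrt(rowSums((xyz[bonds$i, , drop = FALSE] -
                             xyz[bonds$j, , drop = FALSE])^2)))
  }
  nb <- vector("list", nrow(at))
  for (k in seq_len(nrow(bonds))) {
    nb[[bonds$i[k]]] <- c(nb[[bonds$i[k]]], bonds$j[k])
    nb[[bonds$j[k]]] <- c(nb[[bonds$j[k]]], bonds$i[k])
  }
  ang <- list(); tor <- list()
  for (b in seq_len(nrow(at))) {
    for (a in nb[[b]]) for (c in nb[[b]]) {
      if (a >= c) next
      v1 <- xyz[a, ] - xyz[b, ]; v2 <- xyz[c, ] - xyz[b, ]
      th <- acos(max(-1, min(1, sum(v1 * v2) /
                               (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))))
      ang[[length(ang) + 1L]] <- data.frame(
        key = paste(at$element[a], at$element[b], at$element[c], sep = "-"),
        angle = th * 180 / pi)
    }
  }
  for (k in seq_len(nrow(bonds))) {
    b <- bonds$i[k]; c <- bonds$j[k]
    for (a in setdiff(nb[[b]], c)) for (d in setdiff(nb[[c]], b)) {
      b1 <- xyz[b, ] - xyz[a, ]; b2 <- xyz[c, ] - xyz[b, ]; b3 <- xyz[d, ] - xyz[c, ]
      n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
      m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
      phi <- atan2(sum(m1 * n2), sum(n1 * n2))
      tor[[length(tor) + 1L]] <- data.frame(
        key = paste(at$element[a], at$element[b], at$element[c],
                    at$element[d], sep = "-"),
        torsion = phi * 180 / pi)
    }
  }
  list(bonds = bl,
       angles = if (length(ang)) do.call(rbind, ang) else
         data.frame(key = character(0), angle = numeric(0)),
       torsions = if (length(tor)) do.call(rbind, tor) else
         data.frame(key = character(0), torsion = numeric(0)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
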