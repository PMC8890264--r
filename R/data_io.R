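# Structure I/O, dataset filtering rules, fixture generation ----------------

#' Read molecular structures
#'
#' Thin wrappers over the field's parsers: SDF through ChemmineR, PDB and
#' MOL2 through bio3d, SMILES lists through OpenBabel. Every structure is
#' returned as a [mol3d()]; SMILES inputs carry no coordinates (typing works,
#' gridding errors until a conformer is supplied).
#'
#' @param path Input file.
#' @param format One of `"SDF"`, `"MOL2"`, `"PDB"`, `"SMILES"`; guessed from
#'   the file extension by default.
#' @return List of `mol3d` structures (PDB: a single-element list).
#' @export
read_structures <- function(path, format = c("auto", "SDF", "MOL2", "PDB", "SMILES")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "SDF", mol = "SDF", mol2 = "MOL2", pdb = "PDB",
                     smi = "SMILES", smiles = "SMILES",
                     stop("cannot guess format of ", path))
  }
  switch(format,
         SDF = read_sdf_file(path),
         MOL2 = read_mol2_file(path),
         PDB = list(read_pdb_file(path)),
         SMILES = read_smiles_file(path))
}

read_sdf_file <- function(path) {
  str <- tryCatch(ChemmineR::read.SDFstr(path),
                  error = function(e) stop("SDF parse failure in ", path, ": ",
                                           conditionMessage(e)))
  recs <- as(str, "list")
  lapply(seq_along(recs), function(ri) {
    lines <- recs[[ri]]
    sdf <- tryCatch(ChemmineR::read.SDFset(methods::as(lines, "SDFstr"))[[1]],
                    error = function(e) stop("SDF parse failure in ", path,
                                             " record ", ri, ": ",
                                             conditionMessage(e)))
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    atoms <- data.frame(
      element = sub("_.*$", "", rownames(ab)),
      x = ab[, 1], y = ab[, 2], z = ab[, 3], charge = 0L)
    rownames(atoms) <- NULL
    # formal charges live on M  CHG lines, which the parser does not expose
    for (ln in grep("^M  CHG", lines, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      nset <- f[1]
      for (k in seq_len(nset)) atoms$charge[f[2 * k]] <- f[2 * k + 1]
    }
    bonds <- if (nrow(bb)) {
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    } else NULL
    mol3d(atoms, bonds, name = lines[1])
  })
}

read_mol2_file <- function(path) {
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e) stop("MOL2 parse failure in ", path, ": ",
                                         conditionMessage(e)))
  if (!is.list(m) || !is.null(m$atom)) m <- list(m)
  lapply(m, function(rec) {
    atoms <- data.frame(
      element = sub("\\..*$", "", rec$atom$elena),
      x = rec$atom$x, y = rec$atom$y, z = rec$atom$z,
      charge = ifelse(is.null(rec$atom$charge), 0L,
                      as.integer(round(rec$atom$charge))))
    bonds <- NULL
    if (!is.null(rec$bond) && nrow(rec$bond)) {
      ord <- rec$bond$type
      ordn <- ifelse(ord %in% c("ar", "am"), 4L,
                     suppressWarnings(as.integer(ord)))
      ordn[is.na(ordn)] <- 1L
      bonds <- data.frame(i = as.integer(rec$bond$origin),
                          j = as.integer(rec$bond$target), order = ordn)
    }
    mol3d(atoms, bonds, name = basename(path))
  })
}

read_pdb_file <- function(path) {
  p <- tryCatch(bio3d::read.pdb(path),
                error = function(e) stop("PDB parse failure in ", path, ": ",
                                         conditionMessage(e)))
  at <- p$atom
  elem <- trimws(at$elesy)
  elem[elem == ""] <- substr(trimws(at$elety[elem == ""]), 1, 1)
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substring(elem, 2)))
  mol3d(data.frame(element = elem, x = at$x, y = at$y, z = at$z, charge = 0L),
        NULL, name = basename(path))
}

read_smiles_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "[\t ]+")[[1]]
    smi <- parts[1]
    sdf <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n")),
                    error = function(e) stop("SMILES parse failure: ", smi))
    tmp <- tempfile(fileext = ".sdf"); on.exit(unlink(tmp))
    writeLines(sdf, tmp)
    mol <- read_sdf_file(tmp)[[1]]
    mol$atoms$x <- NA_real_; mol$atoms$y <- NA_real_; mol$atoms$z <- NA_real_
    mol$name <- if (length(parts) > 1) parts[2] else smi
    attr(mol, "smiles") <- smi
    mol
  })
}

# Dataset filtering rules -----------------------------------------------------

#' Filter docked poses
#'
#' Keeps poses whose RMSD to the crystal pose is at or below the cutoff
#' (boundary inclusive: a pose at exactly the cutoff is retained) and drops
#' records that fail sanitization. Sanitization uses the `sanitizable`
#' column when present, otherwise a canonical-SMILES parse of the `smiles`
#' column; records with neither are assumed sanitizable.
#'
#' @param poses data.frame of pose records with column `rmsd_to_crystal`
#'   and optionally `sanitizable` / `smiles`.
#' @param rmsd_cutoff Cutoff in angstroms (default 2.0).
#' @return The kept subset, same columns.
#' @export
filter_poses <- function(poses, rmsd_cutoff = 2.0) {
  if (nrow(poses) == 0L) return(poses)
  keep <- poses$rmsd_to_crystal <= rmsd_cutoff
  if ("sanitizable" %in% names(poses)) {
    keep <- keep & poses$sanitizable
  } else if ("smiles" %in% names(poses)) {
    ok <- vapply(poses$smiles, function(s) {
      out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
                      error = function(e) "")
      nzchar(trimws(out))
    }, logical(1))
    keep <- keep & ok
  }
  out <- poses[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select evaluation targets
#'
#' Uniform random choice of `n_targets` pocket clusters among those holding
#' an eligible target (at least `min_ligands` unique ligands), one target
#' per cluster; for every ligand of a selected target, the rank-1 pose is
#' kept. Driven by R's RNG.
#'
#' @param poses data.frame with columns `target_id`, `cluster_id`,
#'   `ligand_id`, `rank`.
#' @param min_ligands Minimum unique ligands per eligible target (default 5).
#' @param n_targets Number of clusters/targets to select (default 10).
#' @return data.frame of selected rank-1 poses.
#' @export
select_test_targets <- function(poses, min_ligands = 5L, n_targets = 10L) {
  lig_counts <- stats::aggregate(ligand_id ~ target_id + cluster_id,
                                 data = poses,
                                 FUN = function(x) length(unique(x)))
  eligible <- lig_counts[lig_counts$ligand_id >= min_ligands, , drop = FALSE]
  clusters <- unique(eligible$cluster_id)
  if (length(clusters) < n_targets) {
    stop("only ", length(clusters), " eligible pocket clusters (need ",
         n_targets, ")")
  }
  chosen_clusters <- sample(clusters, n_targets)
  out <- do.call(rbind, lapply(chosen_clusters, function(cl) {
    cands <- eligible$target_id[eligible$cluster_id == cl]
    tg <- if (length(cands) == 1L) cands else sample(cands, 1L)
    sub <- poses[poses$target_id == tg, , drop = FALSE]
    sub <- sub[order(sub$ligand_id, sub$rank), , drop = FALSE]
    sub[!duplicated(sub$ligand_id) & sub$rank == ave(sub$rank, sub$ligand_id,
                                                     FUN = min), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

# Fixture generation ----------------------------------------------------------

#' Fixture specification
#'
#' @param n_atoms Atom count or range (default 5-20) for random fixtures.
#' @param elements Element palette (subset of the ligand element list).
#' @param min_separation Minimum pairwise atom distance in angstroms
#'   (default 2.0).
#' @param box Cubic box extent in angstroms, centered at the origin
#'   (default 12).
#' @param rng_seed Integer seed; fixtures are bit-identical per seed.
#' @param motif `NULL` (random placement) or one of `"ring6_aromatic"`,
#'   `"chain"`, `"from_smiles_list"`.
#' @param motif_index For `"from_smiles_list"`: index into the curated list.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_atoms = c(5L, 20L),
                         elements = c("C", "N", "O", "S", "Cl"),
                         min_separation = 2.0, box = 12, rng_seed = 1L,
                         motif = NULL, motif_index = 1L) {
  stopifnot(min_separation > 0, box > 0)
  structure(list(n_atoms = as.integer(n_atoms), elements = elements,
                 min_separation = min_separation, box = box,
                 rng_seed = as.integer(rng_seed), motif = motif,
                 motif_index = as.integer(motif_index)),
            class = "fixture_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a deterministic fixture molecule
#'
#' Random fixtures place typed atoms with pairwise separation at or above
#' `min_separation` inside the box, with H-bond roles and occasional formal
#' charges on N/O atoms. The `ring6_aromatic` motif emits a regular hexagon
#' of aromatic carbons with 1.39 A sides; `chain` a tetrahedral carbon
#' zigzag at 1.54 A; `from_smiles_list` a 3D conformer from the curated
#' small-molecule list shipped with the package (ground-truth SMILES in
#' attribute `"smiles"`).
#'
#' @param spec A [fixture_spec()].
#' @param scheme Typing scheme (default ligand).
#' @return A `typed_struct`.
#' @export
make_fixture_molecule <- function(spec = fixture_spec(),
                                  scheme = default_scheme("ligand")) {
  if (!is.null(spec$motif)) {
    return(switch(spec$motif,
                  ring6_aromatic = fixture_ring6(scheme),
                  chain = fixture_chain(spec, scheme),
                  from_smiles_list = fixture_from_list(spec, scheme),
                  stop("unknown motif: ", spec$motif)))
  }
  with_seed(spec$rng_seed, {
    n <- if (length(spec$n_atoms) > 1) sample(spec$n_atoms[1]:spec$n_atoms[2], 1)
         else spec$n_atoms
    half <- spec$box / 2
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(pts) < n) {
      p <- stats::runif(3, -half, half)
      if (nrow(pts) == 0L ||
          min(sqrt(colSums((t(pts) - p)^2))) >= spec$min_separation) {
        pts <- rbind(pts, p)
      }
      tries <- tries + 1L
      if (tries > 10000L) stop("cannot pack ", n, " atoms at separation ",
                               spec$min_separation, " in box ", spec$box)
    }
    elems <- sample(spec$elements, n, replace = TRUE)
    types <- t(vapply(seq_len(n), function(i) {
      no <- elems[i] %in% c("N", "O")
      chg <- if (no && stats::runif(1) < 0.1) sample(c(-1L, 1L), 1) else 0L
      type_atom(elems[i],
                aromatic = FALSE,
                acceptor = no && stats::runif(1) < 0.7,
                donor = no && stats::runif(1) < 0.4,
                charge = chg, scheme = scheme)
    }, numeric(scheme$total_width)))
    typed_struct(pts, types, scheme)
  })
}

.fixture_cache <- new.env(parent = emptyenv())

fixture_ring6 <- function(scheme) {
  ang <- (0:5) * pi / 3
  pts <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  types <- t(replicate(6, type_atom("C", aromatic = TRUE, scheme = scheme)))
  out <- typed_struct(pts, types, scheme)
  attr(out, "smiles") <- "c1ccccc1"
  out
}

fixture_chain <- function(spec, scheme) {
  n <- spec$n_atoms[1]
  # tetrahedral zigzag in the xz plane, 1.54 A bonds
  step <- 1.54
  theta <- (109.47 / 2) * pi / 180
  pts <- cbind((seq_len(n) - 1) * step * sin(theta),
               rep(0, n),
               step * cos(theta) * (seq_len(n) %% 2))
  types <- t(replicate(n, type_atom("C", scheme = scheme)))
  out <- typed_struct(pts, types, scheme)
  attr(out, "smiles") <- paste(rep("C", n), collapse = "")
  out
}

#' Curated fixture molecules
#'
#' Loads the small drug-like molecules shipped with the package
#' (`inst/extdata/fixture_molecules.sdf`, 3D conformers with explicit
#' hydrogens) together with their canonical SMILES.
#'
#' @return List of `mol3d` objects, each with attribute `"smiles"`.
#' @export
load_fixture_molecules <- function() {
  if (!is.null(.fixture_cache$mols)) return(.fixture_cache$mols)
  sdf <- system.file("extdata", "fixture_molecules.sdf", package = "gridmol")
  mols <- read_structures(sdf, "SDF")
  for (k in seq_along(mols)) {
    attr(mols[[k]], "smiles") <- mol_to_smiles(mols[[k]])
  }
  .fixture_cache$mols <- mols
  mols
}

fixture_from_list <- function(spec, scheme) {
  mols <- load_fixture_molecules()
  k <- spec$motif_index
  if (k < 1 || k > length(mols)) stop("motif_index out of range")
  out <- type_molecule(mols[[k]], scheme)
  attr(out, "smiles") <- attr(mols[[k]], "smiles")
  out
}

#' Generate a deterministic receptor-ligand fixture complex
#'
#' The receptor is a spherical shell of typed atoms around a central
#' cavity; the ligand is a random fixture molecule confined to the cavity.
#' With the default geometry the gap between ligand and receptor atoms
#' exceeds twice the kernel support radius, so the steric overlap of the
#' two grids is exactly zero; shrinking `shell_radius` below that limit
#' produces overlapping densities (negative control).
#'
#' @param rng_seed Integer seed.
#' @param n_ligand_atoms Ligand atom count (default 5).
#' @param n_receptor_atoms Shell atom count (default 40).
#' @param shell_radius Receptor shell radius in angstroms (default 8).
#' @param cavity_radius Ligand confinement radius (default 2.5).
#' @param min_separation Minimum intra-structure atom separation (default 2).
#' @return List with `receptor` and `ligand` `typed_struct`s.
#' @export
make_fixture_complex <- function(rng_seed = 1L, n_ligand_atoms = 5L,
                                 n_receptor_atoms = 40L, shell_radius = 8,
                                 cavity_radius = 2.5, min_separation = 2.0) {
  lig_scheme <- default_scheme("ligand")
  rec_scheme <- default_scheme("receptor")
  with_seed(rng_seed, {
    # ligand inside the cavity (bounded rejection sampling; restart the
    # packing when a draw sequence dead-ends)
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(pts) < n_ligand_atoms) {
      p <- stats::runif(3, -cavity_radius, cavity_radius)
      tries <- tries + 1L
      if (tries > 50000L) {
        stop("cannot pack ", n_ligand_atoms, " ligand atoms at separation ",
             min_separation, " in cavity radius ", cavity_radius)
      }
      if (tries %% 2000L == 0L) pts <- matrix(NA_real_, 0, 3)  # restart
      if (sqrt(sum(p^2)) > cavity_radius) next
      if (nrow(pts) == 0L ||
          min(sqrt(colSums((t(pts) - p)^2))) >= min_separation) pts <- rbind(pts, p)
    }
    elems <- sample(c("C", "N", "O"), n_ligand_atoms, replace = TRUE)
    lt <- t(vapply(elems, function(e) {
      type_atom(e, acceptor = e %in% c("N", "O"), scheme = lig_scheme)
    }, numeric(lig_scheme$total_width)))
    ligand <- typed_struct(pts, lt, lig_scheme)

    # receptor shell
    rp <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(rp) < n_receptor_atoms) {
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2)) * shell_radius
      tries <- tries + 1L
      if (tries > 50000L) {
        stop("cannot pack ", n_receptor_atoms, " receptor atoms at separation ",
             min_separation, " on shell radius ", shell_radius)
      }
      if (tries %% 2000L == 0L) rp <- matrix(NA_real_, 0, 3)
      if (nrow(rp) == 0L ||
          min(sqrt(colSums((t(rp) - v)^2))) >= min_separation) rp <- rbind(rp, v)
    }
    relems <- sample(c("C", "N", "O", "S"), n_receptor_atoms, replace = TRUE)
    rt <- t(vapply(relems, function(e) {
      type_atom(e, scheme = rec_scheme)
    }, numeric(rec_scheme$total_width)))
    receptor <- typed_struct(rp, rt, rec_scheme)
    list(receptor = receptor, ligand = ligand)
  })
}
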