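# Lightweight 3D molecule container ----------------------------------------
#
# `mol3d` holds what the typing and bond modules need from a chemical file:
# an atom table (element, x, y, z, formal charge) and a bond table
# (i, j, order) with order 1/2/3 or 4 for aromatic. Explicit hydrogens are
# kept here (H-bond donor perception uses them) and stripped at typing time.

#' Construct a 3D molecule
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (defaults to 0).
#' @param bonds data.frame with columns `i`, `j`, `order` (1, 2, 3, or 4 for
#'   aromatic); may be empty for bondless structures such as receptors read
#'   from PDB.
#' @param name Optional molecule title.
#' @return A `mol3d` object.
#' @export
mol3d <- function(atoms, bonds = NULL, name = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  atoms$charge <- as.integer(atoms$charge)
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    if (any(bonds$i == bonds$j)) stop("self-bond in bond table")
  }
  structure(list(atoms = atoms, bonds = bonds, name = name), class = "mol3d")
}

#' @export
print.mol3d <- function(x, ...) {
  nh <- sum(x$atoms$element == "H")
  cat("<mol3d>", x$name, ":", nrow(x$atoms), "atoms (", nh, "H ),",
      nrow(x$bonds), "bonds\n")
  invisible(x)
}

heavy_centroid <- function(mol) {
  heavy <- mol$atoms$element != "H"
  colMeans(as.matrix(mol$atoms[heavy, c("x", "y", "z")]))
}

# Neighbor list over the bond table (indices into the atom table).
bond_neighbors <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

# Rings of bounded size via igraph (minimum cycle basis would be overkill:
# we enumerate simple cycles of size <= max_size on the heavy-atom graph).
find_rings <- function(mol, max_size = 6L) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(list())
  g <- igraph::graph_from_edgelist(cbind(mol$bonds$i, mol$bonds$j), directed = FALSE)
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nb)) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = i, to = j)$vpath[[1]])
    if (length(sp) >= 3 && length(sp) <= max_size) {
      ring <- sort(as.integer(sp))
      key <- paste(ring, collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- as.integer(sp)  # in path order
      }
    }
  }
  rings
}

#' Perceive atomic properties from structure annotations
#'
#' Derives the per-atom flags consumed by [type_molecule()] from a molecule's
#' bonds. The rules are deliberately simple and documented here as the
#' package's normative perception pass:
#'
#' * aromatic: atom carries a bond of order 4, or sits in a 5- or 6-membered
#'   ring of C/N/O/S atoms whose internal double-bond pattern is consistent
#'   with an aromatic sextet (6-ring: three alternating double bonds; 5-ring:
#'   two double bonds plus one pi-donor heteroatom).
#' * H-bond donor: N or O bearing at least one (explicit) hydrogen.
#' * H-bond acceptor: O with charge <= 0, or N with charge <= 0 that is not
#'   a pyrrole-type aromatic N-H.
#'
#' @param mol A `mol3d`.
#' @return List of logical vectors `aromatic`, `acceptor`, `donor` and the
#'   integer vector `n_h` (explicit hydrogen counts), one entry per atom.
#' @export
perceive_properties <- function(mol) {
  n <- nrow(mol$atoms)
  elem <- mol$atoms$element
  nb <- bond_neighbors(mol)
  n_h <- vapply(seq_len(n), function(i) sum(elem[nb[[i]]] == "H"), integer(1))

  aromatic <- logical(n)
  if (nrow(mol$bonds)) {
    ar_bonds <- mol$bonds[mol$bonds$order == 4L, , drop = FALSE]
    aromatic[unique(c(ar_bonds$i, ar_bonds$j))] <- TRUE

    # Hueckel-style count: an atom with any double (or aromatic) bond
    # contributes one pi electron, a lone-pair heteroatom two; a 5- or
    # 6-ring of C/N/O/S atoms is aromatic when the count reaches six.
    # (Handles fused systems like naphthalene, where an atom's double bond
    # may lie in the neighboring ring.)
    has_dbl <- logical(n)
    db <- mol$bonds[mol$bonds$order %in% c(2L, 4L), , drop = FALSE]
    has_dbl[unique(c(db$i, db$j))] <- TRUE
    for (ring in find_rings(mol)) {
      sz <- length(ring)
      if (!sz %in% c(5L, 6L)) next
      if (!all(elem[ring] %in% c("C", "N", "O", "S"))) next
      pi_e <- vapply(ring, function(a) {
        if (has_dbl[a]) 1L
        else if (elem[a] %in% c("N", "O", "S")) 2L
        else NA_integer_
      }, integer(1))
      if (!anyNA(pi_e) && sum(pi_e) == 6L) aromatic[ring] <- TRUE
    }
  }

  donor <- elem %in% c("N", "O") & n_h >= 1L
  acceptor <- (elem == "O" & mol$atoms$charge <= 0L) |
    (elem == "N" & mol$atoms$charge <= 0L & !(aromatic & n_h >= 1L))
  list(aromatic = aromatic, acceptor = acceptor, donor = donor, n_h = n_h)
}

# V2000 SDF writing ---------------------------------------------------------

# Serialize an atom/bond table pair as a single V2000 SDF record. Aromatic
# bonds must already be kekulized (orders 1/2/3); charges go to M CHG.
sdf_record <- function(atoms, bonds, name = "gridmol") {
  na <- nrow(atoms); nb <- nrow(bonds)
  lines <- c(name, "  gridmol", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  for (i in seq_len(na)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i]))
  }
  for (k in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", bonds$i[k], bonds$j[k],
                              as.integer(bonds$order[k])))
  }
  chg <- which(atoms$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste(sprintf("%4d%4d", grp, atoms$charge[grp]),
                                     collapse = "")))
    }
  }
  c(lines, "M  END", "$$$$")
}

#' Write molecules to an SDF file
#'
#' @param mols A `mol3d` or list of them.
#' @param path Output path.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "mol3d")) mols <- list(mols)
  out <- unlist(lapply(mols, function(m) sdf_record(m$atoms, m$bonds, m$name)))
  writeLines(out, path)
  invisible(path)
}
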