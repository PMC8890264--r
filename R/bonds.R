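# Bond inference ------------------------------------------------------------
#
# Fitted atoms carry coordinates and type vectors but no bonds. This module
# turns them into molecules by a fixed, deterministic rule order:
# distance-based connection -> valence pruning -> aromatic ring perception
# and kekulization -> geometric bond-order raising -> formal charges from
# the type vectors -> implicit hydrogens -> sanity pass. Formal charges are
# read from the charge block of the type vector, never re-perceived.

# Cordero (2008) consensus covalent radii, in angstroms.
COVALENT_RADII <- c(B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                    P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
                    Fe = 1.32, Na = 1.66, Mg = 1.41, K = 2.03, Ca = 1.76,
                    Zn = 1.22, H = 0.31)

# Maximum total bond order per neutral element (pruning / validity cap).
MAX_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 5, S = 6,
                 Cl = 1, Br = 1, I = 1, Fe = 6)

# Default (lowest common) valence used to fill implicit hydrogens.
DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                     Cl = 1, Br = 1, I = 1, Fe = 0)

# Typical bond lengths (angstroms) by element pair: single, double, triple.
# Used as geometric cues when raising bond orders; a bond shorter than the
# midpoint between two typical lengths is assigned the higher order.
TYPICAL_LENGTHS <- list(
  "C-C" = c(1.54, 1.34, 1.20), "C-N" = c(1.47, 1.28, 1.16),
  "C-O" = c(1.43, 1.22, 1.13), "N-N" = c(1.45, 1.25, 1.10),
  "N-O" = c(1.40, 1.21, NA),   "C-S" = c(1.82, 1.60, NA),
  "O-S" = c(1.57, 1.44, NA),   "O-P" = c(1.63, 1.50, NA),
  "N-P" = c(1.77, 1.60, NA),   "C-P" = c(1.84, 1.65, NA),
  "S-S" = c(2.05, 1.88, NA),   "N-S" = c(1.68, 1.55, NA)
)

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "-")

#' Bond inference rules
#'
#' @param bond_tolerance Slack added to the covalent radii sum when
#'   proposing bonds (default 0.45 A).
#' @param clash_floor Minimum distance for a bond proposal (default 0.4 A).
#' @param aromatic_ring_sizes Ring sizes eligible for aromaticity
#'   (default 5 and 6).
#' @return A `bond_rules` object bundling the covalent-radius, valence and
#'   typical-length tables.
#' @export
bond_rules <- function(bond_tolerance = 0.45, clash_floor = 0.4,
                       aromatic_ring_sizes = c(5L, 6L)) {
  structure(list(covalent_radii = COVALENT_RADII,
                 bond_tolerance = bond_tolerance, clash_floor = clash_floor,
                 max_valence = MAX_VALENCE, default_valence = DEFAULT_VALENCE,
                 typical_lengths = TYPICAL_LENGTHS,
                 aromatic_ring_sizes = as.integer(aromatic_ring_sizes)),
            class = "bond_rules")
}

# Charge-adjusted valence: cations of N/O gain a bond, anions lose one;
# charged carbon loses one. Other elements keep the neutral value.
adjusted_valence <- function(table, element, charge) {
  v <- unname(table[element])
  if (is.na(v)) stop("no valence entry for element ", element)
  if (element %in% c("N", "O", "B")) v + charge
  else if (element == "C") v - abs(charge)
  else v
}

struct_elements <- function(struct) {
  vapply(seq_len(n_atoms(struct)), function(i) {
    untype(struct$types[i, ], struct$scheme)$element
  }, character(1))
}

struct_props <- function(struct) {
  n <- n_atoms(struct)
  out <- list(element = character(n), aromatic = logical(n),
              acceptor = logical(n), donor = logical(n), charge = integer(n))
  for (i in seq_len(n)) {
    u <- untype(struct$types[i, ], struct$scheme)
    out$element[i] <- u$element; out$aromatic[i] <- u$aromatic
    out$acceptor[i] <- u$acceptor; out$donor[i] <- u$donor
    out$charge[i] <- as.integer(u$charge)
  }
  out
}

#' Propose candidate bonds from interatomic distances
#'
#' A bond (i, j) is proposed iff the distance lies in
#' `(clash_floor, radii[i] + radii[j] + bond_tolerance]`. If an atom ends up
#' with more proposed bonds than its (charge-adjusted) maximum valence, its
#' longest bonds are pruned first.
#'
#' @param struct A `typed_struct` (from atom fitting or typing).
#' @param rules A [bond_rules()].
#' @return data.frame with columns `i`, `j`, `length`.
#' @export
connect_atoms <- function(struct, rules = bond_rules()) {
  n <- n_atoms(struct)
  if (n == 0L) stop("cannot connect an empty structure")
  p <- struct_props(struct)
  d <- as.matrix(stats::dist(struct$coords))
  bonds <- data.frame(i = integer(0), j = integer(0), length = numeric(0))
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (n < 2L) break
      cut <- rules$covalent_radii[p$element[i]] +
        rules$covalent_radii[p$element[j]] + rules$bond_tolerance
      if (d[i, j] > rules$clash_floor && d[i, j] <= cut) {
        bonds <- rbind(bonds, data.frame(i = i, j = j, length = d[i, j]))
      }
    }
  }
  # prune over-valent atoms, longest bonds first
  repeat {
    deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
    caps <- vapply(seq_len(n), function(a) {
      adjusted_valence(rules$max_valence, p$element[a], p$charge[a])
    }, numeric(1))
    over <- which(deg > caps)
    if (!length(over)) break
    a <- over[1]
    mine <- which(bonds$i == a | bonds$j == a)
    drop <- mine[which.max(bonds$length[mine])]
    bonds <- bonds[-drop, , drop = FALSE]
  }
  rownames(bonds) <- NULL
  bonds
}

# Rings of the given sizes in a bond graph, as ordered atom index vectors.
bond_rings <- function(n, bonds, sizes = c(5L, 6L)) {
  if (nrow(bonds) == 0L) return(list())
  mol <- mol3d(data.frame(element = rep("C", n), x = 0, y = 0, z = 0),
               data.frame(i = bonds$i, j = bonds$j, order = 1L))
  Filter(function(r) length(r) %in% sizes, find_rings(mol, max_size = max(sizes)))
}

# Kekulize the aromatic subsystem: find a matching within the aromatic bonds
# that covers every aromatic carbon; donor-typed heteroatoms (pyrrole-type)
# are excluded from matching, other aromatic N/O/S may optionally be
# matched. Returns the matched bond indices, or NULL if no cover exists.
kekulize_matching <- function(arom_bonds, must_match, excluded) {
  matched <- logical(max(c(arom_bonds$i, arom_bonds$j, 1L)))
  chosen <- integer(0)
  need <- sort(must_match)
  bt <- arom_bonds
  solve <- function(need, matched, chosen) {
    need <- need[!matched[need]]
    if (!length(need)) return(chosen)
    a <- need[1]
    cand <- which((bt$i == a | bt$j == a))
    for (k in cand) {
      b <- if (bt$i[k] == a) bt$j[k] else bt$i[k]
      if (matched[b] || b %in% excluded) next
      m2 <- matched; m2[c(a, b)] <- TRUE
      res <- solve(need[-1], m2, c(chosen, k))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  solve(need, matched, chosen)
}

#' Assign bond orders
#'
#' Rings of aromatic-typed atoms of allowed size are marked aromatic and
#' kekulized (alternating single/double via a matching that covers every
#' aromatic carbon). Remaining bonds are raised from single order greedily,
#' shortest first, where the bond length matches a typical double/triple
#' length for the element pair and both atoms have free valence (one unit
#' of valence is reserved on donor-typed atoms so they can keep a
#' hydrogen).
#'
#' @param struct The `typed_struct` the bonds belong to.
#' @param bonds Candidate bonds from [connect_atoms()].
#' @param rules A [bond_rules()].
#' @return List with the augmented `bonds` data.frame (columns `i`, `j`,
#'   `length`, `order`, `aromatic`), per-atom `order_sum`, and `failure`
#'   (NULL or a reason label).
#' @export
assign_bond_orders <- function(struct, bonds, rules = bond_rules()) {
  p <- struct_props(struct)
  n <- n_atoms(struct)
  bonds$order <- rep(1L, nrow(bonds))
  bonds$aromatic <- rep(FALSE, nrow(bonds))
  failure <- NULL

  # aromatic rings: every atom in the ring must be aromatic-typed
  rings <- bond_rings(n, bonds, rules$aromatic_ring_sizes)
  arom_atoms <- integer(0)
  for (ring in rings) {
    if (all(p$aromatic[ring])) {
      sz <- length(ring)
      for (t in seq_len(sz)) {
        a <- ring[t]; b <- ring[if (t == sz) 1L else t + 1L]
        k <- which((bonds$i == a & bonds$j == b) | (bonds$i == b & bonds$j == a))
        bonds$aromatic[k] <- TRUE
      }
      arom_atoms <- union(arom_atoms, ring)
    }
  }
  if (length(arom_atoms)) {
    ab_idx <- which(bonds$aromatic)
    ab <- bonds[ab_idx, , drop = FALSE]
    must <- arom_atoms[p$element[arom_atoms] == "C"]
    excl <- arom_atoms[p$element[arom_atoms] != "C" & p$donor[arom_atoms]]
    m <- kekulize_matching(ab, must, excl)
    if (is.null(m)) {
      failure <- "kekulization/aromaticity failure"
    } else {
      bonds$order[ab_idx[m]] <- 2L
    }
  }
  # atoms typed aromatic but in no aromatic ring contradict their typing
  if (is.null(failure) && any(p$aromatic & !(seq_len(n) %in% arom_atoms))) {
    failure <- "kekulization/aromaticity failure"
  }

  # geometric order raising outside the aromatic system, shortest bonds first
  order_sum <- function() {
    s <- numeric(n)
    for (k in seq_len(nrow(bonds))) {
      s[bonds$i[k]] <- s[bonds$i[k]] + bonds$order[k]
      s[bonds$j[k]] <- s[bonds$j[k]] + bonds$order[k]
    }
    s
  }
  caps <- vapply(seq_len(n), function(a) {
    adjusted_valence(rules$max_valence, p$element[a], p$charge[a])
  }, numeric(1))
  reserve <- ifelse(p$donor, 1, 0)
  for (k in order(bonds$length)) {
    if (bonds$aromatic[k]) next
    a <- bonds$i[k]; b <- bonds$j[k]
    key <- pair_key(p$element[a], p$element[b])
    typ <- rules$typical_lengths[[key]]
    if (is.null(typ)) next
    target <- 1L
    if (!is.na(typ[2]) && bonds$length[k] <= (typ[1] + typ[2]) / 2) target <- 2L
    if (!is.na(typ[3]) && bonds$length[k] <= (typ[2] + typ[3]) / 2) target <- 3L
    while (bonds$order[k] < target) {
      s <- order_sum()
      free_a <- caps[a] - s[a] - reserve[a]
      free_b <- caps[b] - s[b] - reserve[b]
      if (free_a >= 1 && free_b >= 1) bonds$order[k] <- bonds$order[k] + 1L
      else break
    }
  }
  list(bonds = bonds, order_sum = order_sum(), failure = failure)
}

#' Add implicit hydrogens
#'
#' Implicit hydrogen counts fill each atom's default (charge-adjusted)
#' valence: `max(0, default_valence - sum of bond orders)`. An atom whose
#' bond orders exceed its maximum valence marks the molecule invalid
#' (`"valence exceeded"`); a donor-typed atom that ends up with no hydrogen
#' marks it invalid (`"donor without H"`).
#'
#' @param mol An `inferred_molecule` with bond orders assigned.
#' @param rules A [bond_rules()].
#' @return The molecule with `implicit_h` filled and validity updated.
#' @export
add_hydrogens <- function(mol, rules = bond_rules()) {
  n <- nrow(mol$atoms)
  s <- numeric(n)
  for (k in seq_len(nrow(mol$bonds))) {
    s[mol$bonds$i[k]] <- s[mol$bonds$i[k]] + mol$bonds$order[k]
    s[mol$bonds$j[k]] <- s[mol$bonds$j[k]] + mol$bonds$order[k]
  }
  h <- integer(n)
  for (a in seq_len(n)) {
    el <- mol$atoms$element[a]; ch <- mol$atoms$charge[a]
    if (s[a] > adjusted_valence(rules$max_valence, el, ch)) {
      mol$valid <- FALSE
      mol$failure_reason <- "valence exceeded"
    }
    h[a] <- max(0L, as.integer(round(adjusted_valence(rules$default_valence, el, ch) - s[a])))
  }
  mol$atoms$implicit_h <- h
  if (isTRUE(mol$valid) && any(mol$atoms$donor & h == 0L)) {
    mol$valid <- FALSE
    mol$failure_reason <- "donor without H"
  }
  mol
}

new_inferred_molecule <- function(atoms, bonds, valid = TRUE,
                                  failure_reason = NULL) {
  structure(list(atoms = atoms, bonds = bonds, valid = valid,
                 failure_reason = failure_reason),
            class = "inferred_molecule")
}

#' @export
print.inferred_molecule <- function(x, ...) {
  cat("<inferred_molecule>", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds,",
      if (isTRUE(x$valid)) "valid" else paste0("invalid (", x$failure_reason, ")"),
      "\n")
  invisible(x)
}

#' Construct a molecule from a typed structure
#'
#' Full bond-inference pipeline: connect atoms by distance, prune to
#' valence, perceive and kekulize aromatic rings, raise bond orders on
#' geometric cues, take formal charges from the type vectors, fill implicit
#' hydrogens, and run the sanity pass (single connected fragment, valences
#' within bounds, kekulizable aromatic system).
#'
#' @param struct A `typed_struct` from atom fitting or [type_molecule()].
#' @param rules A [bond_rules()].
#' @return An `inferred_molecule` with `valid`/`failure_reason` set.
#' @export
make_molecule <- function(struct, rules = bond_rules()) {
  n <- n_atoms(struct)
  if (n == 0L) {
    return(new_inferred_molecule(
      data.frame(element = character(0), x = numeric(0), y = numeric(0),
                 z = numeric(0), charge = integer(0), aromatic = logical(0),
                 donor = logical(0), acceptor = logical(0),
                 implicit_h = integer(0)),
      data.frame(i = integer(0), j = integer(0), order = integer(0),
                 aromatic = logical(0)),
      valid = FALSE, failure_reason = "no atoms"))
  }
  p <- struct_props(struct)
  atoms <- data.frame(element = p$element, x = struct$coords[, 1],
                      y = struct$coords[, 2], z = struct$coords[, 3],
                      charge = p$charge, aromatic = p$aromatic,
                      donor = p$donor, acceptor = p$acceptor)
  cand <- connect_atoms(struct, rules)
  ord <- assign_bond_orders(struct, cand, rules)
  bonds <- ord$bonds[, c("i", "j", "order", "aromatic", "length")]
  rownames(bonds) <- NULL
  mol <- new_inferred_molecule(atoms, bonds)
  if (!is.null(ord$failure)) {
    mol$valid <- FALSE
    mol$failure_reason <- ord$failure
  }
  mol <- add_hydrogens(mol, rules)
  # connectivity: a valid molecule is a single connected fragment
  if (isTRUE(mol$valid)) {
    g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    if (igraph::components(g)$no != 1L) {
      mol$valid <- FALSE
      mol$failure_reason <- "multiple fragments"
    }
  }
  mol
}

# Conversions ----------------------------------------------------------------

#' Convert an inferred molecule to a `mol3d`
#'
#' Bond orders are kekulized (1/2/3); hydrogens stay implicit.
#' @param mol An `inferred_molecule`.
#' @return A `mol3d`.
#' @export
inferred_to_mol3d <- function(mol) {
  mol3d(mol$atoms[, c("element", "x", "y", "z", "charge")],
        mol$bonds[, c("i", "j", "order")], name = "inferred")
}

#' Canonical SMILES of a molecule
#'
#' Serializes to SDF and converts through OpenBabel's canonical SMILES
#' writer; implicit hydrogens follow standard valence filling.
#'
#' @param mol An `inferred_molecule` or `mol3d`.
#' @return Canonical SMILES string, or `NA` if conversion fails.
#' @export
mol_to_smiles <- function(mol) {
  if (inherits(mol, "inferred_molecule")) mol <- inferred_to_mol3d(mol)
  txt <- paste(sdf_record(mol$atoms, mol$bonds, "m"), collapse = "\n")
  out <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", paste0(txt, "\n")),
                  error = function(e) NA_character_)
  if (is.na(out) || !nzchar(out)) return(NA_character_)
  strsplit(trimws(out), "[\t ]")[[1]][1]
}
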