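#' @useDynLib gridmol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Property-based atom typing ------------------------------------------------
#
# Atoms are described by a fixed, ordered set of atomic properties (element,
# aromaticity, H-bond acceptor/donor role, formal charge). Each property
# contributes a block of channels to the atom type vector; one-hot properties
# (element, aromatic, charge) get one channel per admissible value, indicator
# properties (acceptor, donor) a single channel. The concatenation order is
# fixed: element, aromatic, acceptor, donor, charge.

LIGAND_ELEMENTS   <- c("B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "Fe")
RECEPTOR_ELEMENTS <- c("C", "N", "O", "Na", "Mg", "P", "S", "Cl", "K", "Ca", "Zn")

#' Construct an atomic property
#'
#' An atomic property is a named, ordered list of admissible values; its
#' width (number of channels it occupies in a type vector) equals the number
#' of values.
#'
#' @param name Property label.
#' @param values Ordered vector of admissible values (must be distinct).
#' @return An `atom_property` object.
#' @export
atom_property <- function(name, values) {
  if (length(values) < 1L) stop("property '", name, "' needs at least one value")
  if (anyDuplicated(values)) stop("property '", name, "' has duplicate values")
  structure(list(name = name, values = values, width = length(values)),
            class = "atom_property")
}

#' Default atom typing scheme
#'
#' Returns the default typing scheme for one structural role. Both roles use
#' an 11-value element block (ligand: B, C, N, O, F, P, S, Cl, Br, I, Fe;
#' receptor: C, N, O, Na, Mg, P, S, Cl, K, Ca, Zn), a 2-value aromaticity
#' block, single-channel H-bond acceptor and donor indicators, and a 3-value
#' formal charge block (-1, 0, +1), for 18 channels in total. Hydrogen is not
#' typed; it is recovered downstream by bond inference.
#'
#' @param role Either `"ligand"` or `"receptor"`.
#' @return A `type_scheme` object.
#' @examples
#' sc <- default_scheme("ligand")
#' sc$total_width  # 18
#' @export
default_scheme <- function(role = c("ligand", "receptor")) {
  if (length(role) != 1L || !role %in% c("ligand", "receptor")) {
    stop("unknown role: ", paste(role, collapse = ", "),
         " (must be 'ligand' or 'receptor')")
  }
  elements <- if (role == "ligand") LIGAND_ELEMENTS else RECEPTOR_ELEMENTS
  type_scheme(role, list(
    atom_property("element",  elements),
    atom_property("aromatic", c(FALSE, TRUE)),
    atom_property("acceptor", TRUE),
    atom_property("donor",    TRUE),
    atom_property("charge",   c(-1L, 0L, 1L))
  ))
}

#' Assemble a typing scheme from atomic properties
#'
#' @param role Structural role label (`"ligand"` or `"receptor"`).
#' @param properties Ordered list of [atom_property()] objects.
#' @return A `type_scheme` with per-property channel offsets precomputed.
#' @export
type_scheme <- function(role, properties) {
  widths <- vapply(properties, `[[`, integer(1), "width")
  names(properties) <- vapply(properties, `[[`, character(1), "name")
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  names(offsets) <- names(properties)
  structure(list(role = role, properties = properties,
                 total_width = sum(widths), offsets = offsets),
            class = "type_scheme")
}

#' @export
print.type_scheme <- function(x, ...) {
  cat("<type_scheme> role:", x$role, " channels:", x$total_width, "\n")
  for (p in x$properties) {
    cat(sprintf("  %-9s [%d] %s\n", p$name, p$width,
                paste(p$values, collapse = ", ")))
  }
  invisible(x)
}

# Channel indices (1-based) occupied by a property block.
scheme_slots <- function(scheme, property) {
  p <- scheme$properties[[property]]
  if (is.null(p)) stop("scheme has no property '", property, "'")
  scheme$offsets[[property]] + seq_len(p$width)
}

#' Element list of a typing scheme
#'
#' @param scheme A `type_scheme`.
#' @return Character vector of supported element symbols, in channel order.
#' @export
scheme_elements <- function(scheme) scheme$properties[["element"]]$values

# Number of leading element channels (atom fitting seeds atoms only there).
n_element_channels <- function(scheme) scheme$properties[["element"]]$width

#' Type a single atom
#'
#' Builds the atom type vector: the concatenation of a one-hot element block,
#' one-hot aromaticity block, acceptor and donor indicator channels, and a
#' one-hot formal charge block, in scheme order.
#'
#' @param element Element symbol (must be in the scheme's element list).
#' @param aromatic,acceptor,donor Logical property flags.
#' @param charge Formal charge, one of -1, 0, +1.
#' @param scheme A `type_scheme`.
#' @return Numeric vector of length `scheme$total_width`.
#' @export
type_atom <- function(element, aromatic = FALSE, acceptor = FALSE,
                      donor = FALSE, charge = 0L, scheme = default_scheme("ligand")) {
  elems <- scheme_elements(scheme)
  ei <- match(element, elems)
  if (is.na(ei)) stop("unsupported element '", element, "' for ", scheme$role,
                      " scheme (supported: ", paste(elems, collapse = ", "), ")")
  t <- numeric(scheme$total_width)
  t[scheme_slots(scheme, "element")[ei]] <- 1
  has <- function(p) !is.null(scheme$properties[[p]])
  if (has("charge")) {
    charges <- scheme$properties[["charge"]]$values
    ci <- match(charge, charges)
    if (is.na(ci)) stop("formal charge ", charge, " outside supported range {",
                        paste(charges, collapse = ", "), "}")
    t[scheme_slots(scheme, "charge")[ci]] <- 1
  } else if (charge != 0L) {
    stop("scheme has no charge property")
  }
  if (has("aromatic")) {
    t[scheme_slots(scheme, "aromatic")[if (isTRUE(aromatic)) 2L else 1L]] <- 1
  }
  if (has("acceptor") && isTRUE(acceptor)) t[scheme_slots(scheme, "acceptor")] <- 1
  if (has("donor") && isTRUE(donor))       t[scheme_slots(scheme, "donor")] <- 1
  t
}

#' Decode a type vector back to atomic properties
#'
#' Left inverse of [type_atom()] on valid vectors: one-hot blocks are decoded
#' by argmax, indicator channels thresholded at 0.5. An all-zero charge block
#' decodes to the neutral default. Works on the fractional vectors produced
#' by reading properties off a fitted density residual.
#'
#' @param type_vector Numeric vector of length `scheme$total_width`.
#' @param scheme A `type_scheme`.
#' @return List with `element`, `aromatic`, `acceptor`, `donor`, `charge`.
#' @export
untype <- function(type_vector, scheme = default_scheme("ligand")) {
  if (length(type_vector) != scheme$total_width) {
    stop("type vector length ", length(type_vector), " does not match scheme width ",
         scheme$total_width)
  }
  eblock <- type_vector[scheme_slots(scheme, "element")]
  if (max(eblock) <= 0) stop("untypable density: element block is all zero")
  has <- function(p) !is.null(scheme$properties[[p]])
  aromatic <- FALSE
  if (has("aromatic")) {
    aromatic <- which.max(type_vector[scheme_slots(scheme, "aromatic")]) == 2L
  }
  charge <- 0L
  if (has("charge")) {
    cblock <- type_vector[scheme_slots(scheme, "charge")]
    charges <- scheme$properties[["charge"]]$values
    if (max(cblock) > 0) charge <- charges[which.max(cblock)]
  }
  list(
    element  = scheme_elements(scheme)[which.max(eblock)],
    aromatic = aromatic,
    acceptor = has("acceptor") && type_vector[scheme_slots(scheme, "acceptor")] >= 0.5,
    donor    = has("donor") && type_vector[scheme_slots(scheme, "donor")] >= 0.5,
    charge   = charge
  )
}

#' Typed structure: coordinates plus type vectors
#'
#' The atomistic twin of a density grid: an N x 3 coordinate matrix (in
#' angstroms) paired with an N x `total_width` matrix of atom type vectors.
#'
#' @param coords Numeric N x 3 matrix of heavy-atom coordinates.
#' @param types Numeric N x `scheme$total_width` matrix.
#' @param scheme The `type_scheme` the type vectors follow.
#' @return A `typed_struct` object.
#' @export
typed_struct <- function(coords, types, scheme) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  types <- matrix(as.numeric(types), ncol = scheme$total_width)
  if (nrow(coords) != nrow(types)) stop("coords and types disagree on atom count")
  structure(list(coords = coords, types = types, scheme = scheme),
            class = "typed_struct")
}

#' @export
print.typed_struct <- function(x, ...) {
  cat("<typed_struct>", nrow(x$coords), "atoms,", x$scheme$total_width,
      "channels (", x$scheme$role, ")\n")
  invisible(x)
}

n_atoms <- function(struct) nrow(struct$coords)

#' Type every heavy atom of a molecule
#'
#' Maps a 3D molecule to a [typed_struct()]: one typed atom per heavy atom,
#' hydrogens excluded (hydrogen is not part of either element list).
#' Aromaticity, H-bond roles and formal charges are perceived from the input
#' structure's bonds and annotations (see [perceive_properties()]).
#'
#' @param mol A `mol3d` structure (see [read_structures()]).
#' @param scheme Typing scheme; defaults to the ligand scheme.
#' @return A `typed_struct`.
#' @export
type_molecule <- function(mol, scheme = default_scheme("ligand")) {
  stopifnot(inherits(mol, "mol3d"))
  props <- perceive_properties(mol)
  heavy <- which(mol$atoms$element != "H")
  if (length(heavy) == 0L) {
    return(typed_struct(matrix(numeric(0), ncol = 3),
                        matrix(numeric(0), ncol = scheme$total_width), scheme))
  }
  elems <- mol$atoms$element[heavy]
  bad <- setdiff(unique(elems), scheme_elements(scheme))
  if (length(bad)) {
    idx <- heavy[elems %in% bad]
    stop("unsupported element(s) for ", scheme$role, " scheme: ",
         paste(sprintf("%s (atom %d)", mol$atoms$element[idx], idx), collapse = ", "))
  }
  types <- t(vapply(heavy, function(i) {
    type_atom(mol$atoms$element[i], props$aromatic[i], props$acceptor[i],
              props$donor[i], mol$atoms$charge[i], scheme)
  }, numeric(scheme$total_width)))
  coords <- as.matrix(mol$atoms[heavy, c("x", "y", "z")])
  dimnames(coords) <- NULL
  typed_struct(coords, types, scheme)
}

# Scheme serialization ------------------------------------------------------

#' Write a typing scheme to JSON
#'
#' Serializes property names and value lists so alternative channel layouts
#' are configurable outside the package defaults.
#'
#' @param scheme A `type_scheme`.
#' @param path Output file path.
#' @export
write_scheme <- function(scheme, path) {
  obj <- list(role = scheme$role,
              properties = lapply(scheme$properties, function(p) {
                list(name = p$name, values = p$values)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a typing scheme from JSON
#'
#' @param path Path written by [write_scheme()].
#' @return A `type_scheme`.
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  props <- lapply(obj$properties, function(p) {
    v <- p$values
    if (p$name %in% c("aromatic", "acceptor", "donor")) v <- as.logical(v)
    if (p$name == "charge") v <- as.integer(v)
    atom_property(p$name, v)
  })
  type_scheme(obj$role, props)
}
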