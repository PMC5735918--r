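#' Construct a molecule
#'
#' The basic container every other function consumes: an ordered vector of
#' element symbols plus Cartesian coordinates in Angstrom. Charge and spin
#' multiplicity are carried for electron bookkeeping; the default is a
#' neutral singlet, the only electronic state the sampling pipeline targets.
#'
#' @param species Character vector of element symbols, one per atom.
#' @param coordinates Numeric matrix, atoms x 3, Angstrom.
#' @param charge Integer total charge (default 0).
#' @param multiplicity Integer spin multiplicity (default 1).
#' @param id Optional molecule identifier (used for seeding and HDF5 group
#'   names); defaults to the chemical formula.
#' @param smiles Optional SMILES string, carried as opaque metadata only.
#' @param table Element table used to validate symbols.
#' @return An object of class `nms_molecule`.
#' @examples
#' water <- molecule(c("O", "H", "H"),
#'                   rbind(c(0, 0, 0.119), c(0, 0.763, -0.477), c(0, -0.763, -0.477)))
#' heavy_atom_count(water)
#' @export
molecule <- function(species, coordinates, charge = 0L, multiplicity = 1L,
                     id = NULL, smiles = "", table = element_table()) {
  species <- as.character(species)
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (length(species) < 1L)
    stop("a molecule needs at least one atom")
  if (nrow(coordinates) != length(species) || ncol(coordinates) != 3L)
    stop("coordinates must be a ", length(species), " x 3 matrix")
  if (any(!is.finite(coordinates)))
    stop("coordinates must be finite")
  element_masses(species, table)  # validates symbols
  if (is.null(id)) id <- chemical_formula(species)
  dimnames(coordinates) <- NULL
  structure(list(species = species, coordinates = coordinates,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 id = as.character(id), smiles = as.character(smiles)),
            class = "nms_molecule")
}

#' @export
print.nms_molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms (%d heavy), charge %d, multiplicity %d>\n",
              x$id, n_atoms(x), heavy_atom_count(x), x$charge, x$multiplicity))
  invisible(x)
}

# Hill-ish formula used for default ids
chemical_formula <- function(species) {
  cnt <- table(species)
  paste0(names(cnt), ifelse(cnt > 1L, cnt, ""), collapse = "")
}

#' Number of atoms in a molecule
#' @param molecule An `nms_molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(molecule) length(molecule$species)

#' Count non-hydrogen atoms
#'
#' The sampling schedule is keyed by this count (the "GDB subset" size).
#'
#' @param molecule An `nms_molecule`.
#' @return Integer count of heavy (non-H) atoms.
#' @export
heavy_atom_count <- function(molecule) sum(molecule$species != "H")

#' Count electrons
#'
#' Sum of atomic numbers minus the molecular charge; used to normalize total
#' energies in the per-electron energy distribution.
#'
#' @param molecule An `nms_molecule`.
#' @param table Element table providing atomic numbers.
#' @return Positive integer.
#' @export
electron_count <- function(molecule, table = element_table()) {
  n <- sum(element_numbers(molecule$species, table)) - molecule$charge
  if (n <= 0L) stop("non-positive electron count")
  as.integer(n)
}

#' Detect whether a molecule is linear
#'
#' A molecule is treated as linear when its smallest principal moment of
#' inertia is below `tolerance` times the largest. Diatomics are always
#' linear. Linearity decides whether 5 or 6 rigid-body degrees of freedom
#' are projected out of the Hessian.
#'
#' @param molecule An `nms_molecule` with at least 2 atoms.
#' @param tolerance Relative tolerance on the moment-of-inertia ratio.
#' @param table Element table providing masses.
#' @return Logical flag.
#' @export
detect_linearity <- function(molecule, tolerance = 1e-8,
                             table = element_table()) {
  na <- n_atoms(molecule)
  if (na < 2L) stop("linearity is undefined for a single atom")
  xyz <- molecule$coordinates
  d <- stats::dist(xyz)
  if (min(d) < 1e-10) stop("coincident atoms in molecule ", molecule$id)
  if (na == 2L) return(TRUE)
  m <- element_masses(molecule$species, table)
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2L, com)
  inertia <- matrix(0, 3L, 3L)
  for (i in seq_len(na)) {
    ri <- r[i, ]
    inertia <- inertia + m[i] * (sum(ri^2) * diag(3L) - tcrossprod(ri))
  }
  ev <- eigen(inertia, symmetric = TRUE, only.values = TRUE)$values
  min(ev) < tolerance * max(ev)
}

#' Vibrational degrees of freedom
#'
#' `3 * N_a - 5` for linear molecules, `3 * N_a - 6` otherwise. This is the
#' number of normal modes sampled and the `K` in the per-molecule conformer
#' count `N = S * K`.
#'
#' @param molecule An `nms_molecule` with at least 2 atoms.
#' @param linear Logical; defaults to geometric detection.
#' @return Non-negative integer.
#' @examples
#' h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' vibrational_dof(h2)  # 3*2 - 5 = 1
#' @export
vibrational_dof <- function(molecule, linear = detect_linearity(molecule)) {
  na <- n_atoms(molecule)
  if (na < 2L) stop("a single atom has no vibrational modes")
  as.integer(3L * na - if (isTRUE(linear)) 5L else 6L)
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: first line the atom count, second a free comment line,
#' then one `symbol x y z` row per atom. An `energy=<float>` token in the
#' comment line (Hartree) is parsed into the `energy` attribute.
#'
#' @param path Path to the XYZ file.
#' @param ... Passed on to [molecule()] (e.g. `id`, `charge`).
#' @return An `nms_molecule`; attribute `energy` holds the parsed energy or
#'   `NA` if the token is absent.
#' @export
read_xyz <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("not an XYZ file: ", path)
  na <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(na) || na < 1L) stop("bad atom count in XYZ header: ", path)
  if (length(lines) < 2L + na) stop("XYZ file truncated: ", path)
  comment <- lines[2L]
  rows <- strsplit(trimws(lines[3L:(2L + na)]), "\\s+")
  species <- vapply(rows, `[[`, "", 1L)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3L)))
  mol <- molecule(species, xyz, ...)
  energy <- NA_real_
  tok <- regmatches(comment, regexpr("energy=([-+0-9.eE]+)", comment))
  if (length(tok) == 1L)
    energy <- as.numeric(sub("energy=", "", tok))
  attr(mol, "energy") <- energy
  mol
}

#' Write a molecule to an XYZ file
#'
#' @param molecule An `nms_molecule`.
#' @param path Output path.
#' @param energy Optional energy (Hartree) recorded as `energy=<value>` in
#'   the comment line.
#' @param comment Extra comment text.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(molecule, path, energy = NULL, comment = "") {
  hdr <- comment
  if (!is.null(energy) && is.finite(energy))
    hdr <- trimws(paste(sprintf("energy=%.17g", energy), comment))
  body <- sprintf("%-2s %18.10f %18.10f %18.10f", molecule$species,
                  molecule$coordinates[, 1L], molecule$coordinates[, 2L],
                  molecule$coordinates[, 3L])
  writeLines(c(as.character(n_atoms(molecule)), hdr, body), path)
  invisible(path)
}
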