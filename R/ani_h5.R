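#' Construct an on-disk molecule record
#'
#' The per-molecule record of the dataset format: a block of low-energy
#' conformers (`coordinates`, `energies`), a possibly empty block of
#' high-energy conformers (`coordinatesHE`, `energiesHE`), the shared
#' `species` vector (one symbol per atom, ordered to match the atom
#' dimension of the coordinate arrays) and an opaque `smiles` string.
#'
#' @param species Character vector of element symbols.
#' @param coordinates Numeric array, conformers x atoms x 3 (Angstrom). A
#'   single atoms x 3 matrix is promoted to one conformer.
#' @param energies Numeric vector, one energy (Hartree) per conformer.
#' @param coordinatesHE,energiesHE High-energy block, same conventions;
#'   default empty.
#' @param smiles Opaque SMILES string metadata.
#' @param id Optional record identifier (defaults to the formula).
#' @return An object of class `ani_record`.
#' @export
ani_record <- function(species, coordinates, energies,
                       coordinatesHE = NULL, energiesHE = numeric(),
                       smiles = "", id = NULL) {
  species <- as.character(species)
  na <- length(species)
  coordinates <- promote_conf_array(coordinates, na, "coordinates")
  if (is.null(coordinatesHE))
    coordinatesHE <- array(numeric(0), dim = c(0L, na, 3L))
  coordinatesHE <- promote_conf_array(coordinatesHE, na, "coordinatesHE")
  energies <- as.numeric(energies)
  energiesHE <- as.numeric(energiesHE)
  if (dim(coordinates)[1L] != length(energies))
    stop("coordinates/energies conformer counts differ (",
         dim(coordinates)[1L], " vs ", length(energies), ")")
  if (dim(coordinatesHE)[1L] != length(energiesHE))
    stop("coordinatesHE/energiesHE conformer counts differ (",
         dim(coordinatesHE)[1L], " vs ", length(energiesHE), ")")
  if (is.null(id)) id <- chemical_formula(species)
  structure(list(species = species, coordinates = coordinates,
                 energies = energies, coordinatesHE = coordinatesHE,
                 energiesHE = energiesHE, smiles = as.character(smiles),
                 id = as.character(id)),
            class = "ani_record")
}

promote_conf_array <- function(x, na, what) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  x <- unname(x)
  if (length(dim(x)) != 3L || dim(x)[2L] != na || dim(x)[3L] != 3L)
    stop(what, " must be conformers x ", na, " x 3")
  storage.mode(x) <- "double"
  x
}

#' @export
print.ani_record <- function(x, ...) {
  cat(sprintf("<record %s: %d atoms, %d conformers + %d high-energy>\n",
              x$id, length(x$species), length(x$energies),
              length(x$energiesHE)))
  invisible(x)
}

#' Build a record from a curated conformer set
#'
#' @param split Result of [energy_window_split()] on a `conformer_set`
#'   (list with `low` and `high`).
#' @return An `ani_record` whose main arrays hold the low-energy conformers
#'   and whose HE arrays hold the high-energy ones.
#' @export
as_ani_record <- function(split) {
  low <- split$low
  ani_record(species = low$molecule$species,
             coordinates = low$coordinates, energies = low$energies,
             coordinatesHE = split$high$coordinates,
             energiesHE = split$high$energies,
             smiles = low$molecule$smiles, id = low$molecule$id)
}

#' Write records to an HDF5 dataset file
#'
#' One HDF5 group per molecule, nested as `gdb<NN>/mol<i>` where `NN` is
#' the zero-padded heavy-atom count and `i` a 0-based index in input order
#' within the size group. Each group holds datasets named exactly
#' `coordinates`, `energies`, `species`, `coordinatesHE`, `energiesHE` and
#' `smiles`. Coordinates are stored as 32-bit floats (the practical
#' precision of Cartesian geometries), energies as 64-bit floats (a
#' 275 kcal/mol window on total energies of hundreds of Hartree needs the
#' extra digits); both dtypes are overridable. From a C-order reader the
#' coordinate arrays appear as `(conformers, atoms, 3)`.
#'
#' @param path Output file path (overwritten).
#' @param records List of `ani_record`s.
#' @param coord_dtype HDF5 type for coordinates.
#' @param energy_dtype HDF5 type for energies.
#' @return `path`, invisibly.
#' @export
write_ani_h5 <- function(path, records, coord_dtype = "H5T_IEEE_F32LE",
                         energy_dtype = "H5T_IEEE_F64LE") {
  if (inherits(records, "ani_record")) records <- list(records)
  for (i in seq_along(records))
    if (!inherits(records[[i]], "ani_record"))
      stop("records[[", i, "]] is not an ani_record")
  unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  groups <- character(0)
  counter <- integer(0)
  for (rec in records) {
    nheavy <- sum(rec$species != "H")
    parent <- sprintf("gdb%02d", nheavy)
    if (!parent %in% groups) {
      rhdf5::h5createGroup(path, parent)
      groups <- c(groups, parent)
      counter[parent] <- 0L
    }
    grp <- sprintf("%s/mol%d", parent, counter[parent])
    counter[parent] <- counter[parent] + 1L
    rhdf5::h5createGroup(path, grp)
    write_conf_block(path, grp, "coordinates", "energies",
                     rec$coordinates, rec$energies, coord_dtype, energy_dtype)
    write_conf_block(path, grp, "coordinatesHE", "energiesHE",
                     rec$coordinatesHE, rec$energiesHE, coord_dtype,
                     energy_dtype)
    rhdf5::h5write(rec$species, path, paste0(grp, "/species"))
    rhdf5::h5write(rec$smiles, path, paste0(grp, "/smiles"))
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("nmsgen-1", fid, "schema_version")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

write_conf_block <- function(path, grp, cname, ename, coords, energies,
                             coord_dtype, energy_dtype) {
  n <- dim(coords)[1L]
  na <- dim(coords)[2L]
  # R arrays are column-major; storing (3, atoms, conformers) on the R side
  # yields (conformers, atoms, 3) in the file's C order
  rhdf5::h5createDataset(path, paste0(grp, "/", cname),
                         dims = c(3L, na, n), H5type = coord_dtype)
  if (n > 0L)
    rhdf5::h5write(aperm(coords, c(3L, 2L, 1L)), path,
                   paste0(grp, "/", cname))
  rhdf5::h5createDataset(path, paste0(grp, "/", ename), dims = n,
                         H5type = energy_dtype)
  if (n > 0L)
    rhdf5::h5write(energies, path, paste0(grp, "/", ename))
}

#' Read all records from an HDF5 dataset file
#'
#' Groups are visited in deterministic lexicographic order of their full
#' path. In strict mode (default) a group missing any mandatory dataset
#' raises an error naming the group; in lenient mode such groups are
#' skipped with a warning, and missing HE blocks or SMILES are tolerated
#' and defaulted, which admits foreign files that follow the same key
#' names but a different hierarchy.
#'
#' @param path Path to the HDF5 file.
#' @param strict Logical, see above.
#' @return Named list of `ani_record`s keyed by group path.
#' @export
read_ani_h5 <- function(path, strict = TRUE) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  if (nrow(ls) == 0L) return(structure(list(), names = character()))
  dsets <- ls[ls$otype == "H5I_DATASET", , drop = FALSE]
  full <- file.path(dsets$group, dsets$name)
  full <- sub("^//", "/", full)
  leaf_groups <- sort(unique(dsets$group[dsets$name == "coordinates"]))
  # also surface groups that look molecular but lack coordinates (strict)
  other_groups <- sort(unique(dsets$group[dsets$name %in%
                                            c("energies", "species")]))
  leaf_groups <- sort(unique(c(leaf_groups, other_groups)))
  records <- list()
  for (grp in leaf_groups) {
    have <- dsets$name[dsets$group == grp]
    mandatory <- c("coordinates", "energies", "species")
    miss <- setdiff(mandatory, have)
    if (length(miss) > 0L) {
      msg <- paste0("group ", grp, " is missing dataset(s): ",
                    paste(miss, collapse = ", "))
      if (strict) stop(msg)
      warning(msg, "; skipping")
      next
    }
    rd <- function(name) rhdf5::h5read(path, paste0(grp, "/", name))
    species <- as.character(rd("species"))
    na <- length(species)
    coords <- read_conf_array(rd("coordinates"), na)
    energies <- as.numeric(rd("energies"))
    coordsHE <- if ("coordinatesHE" %in% have)
      read_conf_array(rd("coordinatesHE"), na)
    else array(numeric(0), dim = c(0L, na, 3L))
    energiesHE <- if ("energiesHE" %in% have)
      as.numeric(rd("energiesHE")) else numeric()
    smiles <- if ("smiles" %in% have) as.character(rd("smiles")) else ""
    rec <- tryCatch(
      ani_record(species, coords, energies, coordsHE, energiesHE,
                 smiles = smiles,
                 id = sub("^/", "", grp)),
      error = function(e) {
        msg <- paste0("group ", grp, ": ", conditionMessage(e))
        if (strict) stop(msg) else warning(msg, "; skipping")
        NULL
      })
    if (!is.null(rec)) records[[sub("^/", "", grp)]] <- rec
  }
  records
}

read_conf_array <- function(x, na) {
  # file C-order (conformers, atoms, 3) arrives in R as (3, atoms, conformers)
  if (length(dim(x)) != 3L) stop("coordinates dataset is not 3-dimensional")
  aperm(x, c(3L, 2L, 1L))
}

#' Export one conformer of a record as an XYZ file
#'
#' @param record An `ani_record`.
#' @param conformer_index 1-based index into the main conformer block.
#' @param path Output path.
#' @param high_energy If `TRUE` index into the HE block instead.
#' @return `path`, invisibly.
#' @export
export_xyz <- function(record, conformer_index, path, high_energy = FALSE) {
  coords <- if (high_energy) record$coordinatesHE else record$coordinates
  energies <- if (high_energy) record$energiesHE else record$energies
  n <- dim(coords)[1L]
  if (conformer_index < 1L || conformer_index > n)
    stop("conformer_index ", conformer_index, " out of range 1..", n)
  mol <- molecule(record$species, coords[conformer_index, , ],
                  id = record$id, smiles = record$smiles)
  write_xyz(mol, path, energy = energies[conformer_index],
            comment = record$id)
}

#' @rdname energy_window_split
#' @details For an `ani_record` the main and HE blocks are concatenated and
#'   re-partitioned against the minimum energy of the concatenation, so a
#'   record curated under one window can be re-curated under another.
#' @export
energy_window_split.ani_record <- function(x, config = curation_config(),
                                           ...) {
  n_main <- length(x$energies)
  n_he <- length(x$energiesHE)
  if (n_main + n_he == 0L) stop("record ", x$id, " has no conformers")
  na <- length(x$species)
  all_coords <- array(NA_real_, dim = c(n_main + n_he, na, 3L))
  if (n_main > 0L) all_coords[seq_len(n_main), , ] <- x$coordinates
  if (n_he > 0L) all_coords[n_main + seq_len(n_he), , ] <- x$coordinatesHE
  all_e <- c(x$energies, x$energiesHE)
  rel <- all_e - min(all_e)
  low <- if (config$inclusive_boundary) rel <= config$threshold_ha
         else rel < config$threshold_ha
  ani_record(x$species,
             coordinates = all_coords[low, , , drop = FALSE],
             energies = all_e[low],
             coordinatesHE = all_coords[!low, , , drop = FALSE],
             energiesHE = all_e[!low],
             smiles = x$smiles, id = x$id)
}
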