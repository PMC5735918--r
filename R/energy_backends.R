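#' Single-point-energy calculator contract
#'
#' A calculator wraps a deterministic function from a geometry to a total
#' energy in Hartree. Evaluation failure (the analogue of an SCF that does
#' not converge) is a typed result, not an error: [evaluate_energy()] returns
#' `ok = FALSE` and the sampler records the conformer as `energy_failed` and
#' excludes it from exported arrays.
#'
#' @param name Short backend name.
#' @param fn Function `(species, coordinates)` returning a single finite
#'   energy (Hartree), or `NA`/non-finite to signal failure.
#' @param species Optional character vector of supported element symbols;
#'   `NULL` means all.
#' @return An object of class `nms_calculator`.
#' @seealso [harmonic_calculator()], [morse_calculator()],
#'   [command_calculator()]
#' @export
calculator <- function(name, fn, species = NULL) {
  stopifnot(is.character(name), is.function(fn))
  structure(list(name = name, fn = fn, species = species),
            class = "nms_calculator")
}

#' @export
print.nms_calculator <- function(x, ...) {
  cat(sprintf("<calculator %s%s>\n", x$name,
              if (is.null(x$species)) ""
              else paste0(" [", paste(x$species, collapse = ","), "]")))
  invisible(x)
}

#' Evaluate a calculator on one geometry
#'
#' @param calc An `nms_calculator`.
#' @param species Element symbols.
#' @param coordinates Atoms x 3 matrix, Angstrom.
#' @return List with `ok` (logical) and `energy` (Hartree, `NA` on failure).
#' @export
evaluate_energy <- function(calc, species, coordinates) {
  if (!is.null(calc$species) && !all(species %in% calc$species))
    stop("calculator '", calc$name, "' does not support species: ",
         paste(setdiff(species, calc$species), collapse = ", "))
  e <- tryCatch(calc$fn(species, coordinates), error = function(err) NA_real_)
  if (length(e) != 1L || !is.finite(e))
    list(ok = FALSE, energy = NA_real_)
  else
    list(ok = TRUE, energy = as.numeric(e))
}

#' Harmonic (quadratic) toy surface
#'
#' `E(x) = E_ref + 1/2 d' H d` with `d` the flattened Cartesian deviation
#' from the reference geometry. On this surface the thermal displacement
#' identity holds exactly, which makes it the reference backend for testing
#' the sampler. Never fails.
#'
#' @param reference Reference `nms_molecule` (the expansion point).
#' @param reference_energy Energy at the reference geometry, Hartree.
#' @param hessian `3N x 3N` Hessian, Hartree/Angstrom^2, atom-major order.
#' @return An `nms_calculator`.
#' @export
harmonic_calculator <- function(reference, reference_energy, hessian) {
  hessian <- as.matrix(hessian)
  n3 <- 3L * n_atoms(reference)
  stopifnot(all(dim(hessian) == n3))
  ref_flat <- as.vector(t(reference$coordinates))
  ref_species <- reference$species
  force(reference_energy)
  calculator("harmonic", function(species, coordinates) {
    if (!identical(species, ref_species))
      stop("geometry does not match the reference species")
    d <- as.vector(t(coordinates)) - ref_flat
    reference_energy + 0.5 * drop(crossprod(d, hessian %*% d))
  }, species = unique(ref_species))
}

#' Pairwise Morse toy surface
#'
#' Sum over all unordered atom pairs of a Morse well
#' `D (1 - exp(-a (r - r0)))^2 - D`, so each pair contributes `-D` at its
#' equilibrium distance and `0` at dissociation. Being anharmonic, it
#' produces the high-energy tail that energy-window curation is designed to
#' cut. Optionally signals failure (mimicking SCF non-convergence for
#' clashed geometries) when any pair distance drops below `r_fail`.
#'
#' @param de Well depth D, Hartree.
#' @param a Steepness, 1/Angstrom.
#' @param r0 Pair equilibrium distance, Angstrom. Either a single number or
#'   a named vector keyed by sorted element pairs like `"H-O"`.
#' @param r_fail Failure distance, Angstrom; `0` disables the failure mode.
#' @return An `nms_calculator`.
#' @export
morse_calculator <- function(de = 0.15, a = 1.8, r0 = 1.0, r_fail = 0.3) {
  calculator("morse", function(species, coordinates) {
    na <- length(species)
    if (na < 2L) return(0)
    e <- 0
    for (i in seq_len(na - 1L)) {
      for (j in (i + 1L):na) {
        r <- sqrt(sum((coordinates[i, ] - coordinates[j, ])^2))
        if (r_fail > 0 && r < r_fail) return(NA_real_)
        rij0 <- pair_r0(r0, species[i], species[j])
        e <- e + de * (1 - exp(-a * (r - rij0)))^2 - de
      }
    }
    e
  })
}

pair_r0 <- function(r0, s1, s2) {
  if (length(r0) == 1L && is.null(names(r0))) return(unname(r0))
  key <- paste(sort(c(s1, s2)), collapse = "-")
  if (!key %in% names(r0)) stop("no r0 entry for pair ", key)
  unname(r0[[key]])
}

#' External command calculator
#'
#' Wraps a child process implementing the single-point contract: the process
#' receives the geometry as XYZ on stdin and must print a single float
#' (Hartree) on stdout; a nonzero exit status signals an SCF-style failure.
#'
#' @param exe Path to the executable.
#' @param args Extra arguments.
#' @return An `nms_calculator`.
#' @export
command_calculator <- function(exe, args = character()) {
  calculator(paste0("command:", basename(exe)), function(species, coordinates) {
    xyz <- c(as.character(length(species)), "",
             sprintf("%-2s %18.10f %18.10f %18.10f", species,
                     coordinates[, 1L], coordinates[, 2L], coordinates[, 3L]))
    out <- suppressWarnings(
      system2(exe, args, stdout = TRUE, stderr = FALSE,
              input = paste(xyz, collapse = "\n")))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0L) return(NA_real_)
    as.numeric(out[[1L]])
  })
}

#' Atomization energy
#'
#' Total energy minus the sum of isolated-atom reference energies; negative
#' for bound molecules. This is the quantity whose distribution, after
#' energy-window curation, should never exceed 0 Hartree.
#'
#' @param total_energy Numeric vector of total energies, Hartree.
#' @param species Element symbols of the molecule.
#' @param table Named numeric vector, symbol -> single-atom energy (Hartree).
#' @return Numeric vector, same length as `total_energy`.
#' @examples
#' atomization_energy(-5, c("O", "H", "H"), c(H = -0.5, O = -75))
#' @export
atomization_energy <- function(total_energy, species, table) {
  miss <- setdiff(unique(species), names(table))
  if (length(miss) > 0L)
    stop("atomic energy table is missing: ", paste(miss, collapse = ", "))
  total_energy - sum(table[species])
}

#' Read an atomic-energy table file
#'
#' Two whitespace-delimited columns, `symbol energy_Ha`; `#` starts a
#' comment.
#'
#' @param path Path to the file.
#' @return Named numeric vector, symbol -> energy (Hartree).
#' @export
read_atomic_energy_table <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("symbol", "energy"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$energy), df$symbol)
}

#' Synthetic atomic-energy table for the toy backends
#'
#' Fixture values on the rough scale of isolated-atom total energies; they
#' are synthetic and only make the toy pipeline's atomization arithmetic
#' exercisable. Real reference values are loaded with
#' [read_atomic_energy_table()].
#'
#' @return Named numeric vector (Hartree).
#' @export
toy_atomic_energies <- function() {
  c(H = -0.5, C = -37.8, N = -54.5, O = -75.0, F = -99.7)
}
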