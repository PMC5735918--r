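#' Physical constants used throughout the package
#'
#' Internal unit conventions are fixed: coordinates in Angstrom, energies in
#' Hartree, temperatures in Kelvin. Conversions happen only at I/O and
#' reporting boundaries.
#'
#' @param k_b Boltzmann constant, Hartree per Kelvin.
#' @param hartree_to_kcalmol Conversion factor, kcal/mol per Hartree.
#' @return A list of class `nms_constants` with components `k_b` and
#'   `hartree_to_kcalmol`.
#' @examples
#' physical_constants()$k_b
#' @export
physical_constants <- function(k_b = 3.166811563e-6,
                               hartree_to_kcalmol = 627.5094741) {
  stopifnot(is.numeric(k_b), length(k_b) == 1L, k_b > 0,
            is.numeric(hartree_to_kcalmol), length(hartree_to_kcalmol) == 1L,
            hartree_to_kcalmol > 0)
  structure(list(k_b = k_b, hartree_to_kcalmol = hartree_to_kcalmol),
            class = "nms_constants")
}

#' Element lookup table
#'
#' Atomic numbers and standard atomic weights (CODATA/IUPAC abridged values)
#' for the elements the sampler handles by default. The table is versioned by
#' the package release; extend it by `rbind`-ing rows with the same columns.
#'
#' @param symbols Optional character vector restricting the returned rows.
#' @return A `data.frame` with columns `symbol`, `number` (atomic number) and
#'   `mass` (amu).
#' @examples
#' element_table(c("H", "O"))
#' @export
element_table <- function(symbols = NULL) {
  tab <- data.frame(
    symbol = c("H", "C", "N", "O", "F"),
    number = c(1L, 6L, 7L, 8L, 9L),
    mass   = c(1.008, 12.011, 14.007, 15.999, 18.998403163),
    stringsAsFactors = FALSE
  )
  if (!is.null(symbols)) {
    miss <- setdiff(symbols, tab$symbol)
    if (length(miss) > 0L)
      stop("unknown element symbol(s): ", paste(miss, collapse = ", "))
    tab <- tab[match(symbols, tab$symbol), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

# masses (amu) for a species vector, erroring on unknown symbols
element_masses <- function(species, table = element_table()) {
  idx <- match(species, table$symbol)
  if (anyNA(idx))
    stop("unknown element symbol(s): ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  table$mass[idx]
}

element_numbers <- function(species, table = element_table()) {
  idx <- match(species, table$symbol)
  if (anyNA(idx))
    stop("unknown element symbol(s): ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  table$number[idx]
}
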