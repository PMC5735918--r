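#' Sampling schedule
#'
#' Per-molecule-size sampling parameters: `S`, the number of conformers
#' generated per vibrational degree of freedom, and `t_max`, the temperature
#' (Kelvin) bounding the thermal energy of the random displacements. The
#' per-molecule conformer count is `N = S * N_f`.
#'
#' @param heavy_atoms Integer vector of heavy-atom counts (row keys).
#' @param S Positive integers, points per degree of freedom.
#' @param t_max Positive temperatures, Kelvin.
#' @param temperature_mode `"fixed_at_max"` draws every conformer at
#'   `t_max`; `"uniform_up_to_max"` draws a fresh `T ~ U(0, t_max]` per
#'   conformer.
#' @return A `data.frame` of class `nms_schedule`.
#' @seealso [default_schedule()] for the published 1-8 heavy-atom schedule.
#' @export
sampling_schedule <- function(heavy_atoms, S, t_max,
                              temperature_mode = c("fixed_at_max",
                                                   "uniform_up_to_max")) {
  temperature_mode <- match.arg(temperature_mode)
  stopifnot(length(heavy_atoms) == length(S), length(S) == length(t_max),
            all(S >= 1L), all(t_max > 0), !anyDuplicated(heavy_atoms))
  out <- data.frame(heavy_atoms = as.integer(heavy_atoms),
                    S = as.integer(S), t_max = as.numeric(t_max))
  attr(out, "temperature_mode") <- temperature_mode
  class(out) <- c("nms_schedule", "data.frame")
  out
}

#' The published 1-8 heavy-atom sampling schedule
#'
#' The schedule used to build the reference 57k-molecule dataset: small
#' molecules get many points per mode at high temperature (500 per mode at
#' 2000 K for one heavy atom), large ones few at moderate temperature (5 per
#' mode at 450 K for eight).
#'
#' @inheritParams sampling_schedule
#' @return An `nms_schedule` with rows for 1-8 heavy atoms.
#' @export
default_schedule <- function(temperature_mode = "fixed_at_max") {
  sampling_schedule(
    heavy_atoms = 1:8,
    S     = c(500L, 450L, 425L, 400L, 200L, 30L, 20L, 5L),
    t_max = c(2000, 1500, 1000, 600, 600, 600, 600, 450),
    temperature_mode = temperature_mode
  )
}

#' Look up the schedule row for a molecule size
#'
#' @param schedule An `nms_schedule`.
#' @param heavy_atoms Heavy-atom count to look up.
#' @return List with `S`, `t_max` and `temperature_mode`.
#' @examples
#' schedule_lookup(default_schedule(), 8)  # S = 5, t_max = 450
#' @export
schedule_lookup <- function(schedule, heavy_atoms) {
  i <- match(heavy_atoms, schedule$heavy_atoms)
  if (is.na(i))
    stop("no schedule row for ", heavy_atoms, " heavy atoms")
  list(S = schedule$S[i], t_max = schedule$t_max[i],
       temperature_mode = attr(schedule, "temperature_mode") %||% "fixed_at_max")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conformers per molecule
#'
#' `N = S * dof`, the number of sampled conformers for one molecule.
#'
#' @param S Points per degree of freedom.
#' @param dof Vibrational degrees of freedom (`N_f`).
#' @return Positive integer.
#' @export
conformer_count <- function(S, dof) {
  stopifnot(length(S) == 1L, length(dof) == 1L)
  if (dof < 1L) stop("dof must be positive")
  if (S < 1L) stop("S must be positive")
  as.integer(S) * as.integer(dof)
}

#' Draw normal-mode energy weights
#'
#' Produces `N_f` non-negative weights `c_i` whose sum lies in `[0, 1]`;
#' `c_i` is the fraction of the classical thermal energy `3/2 N_a k_b T`
#' assigned to mode `i`. Two schemes are provided, both satisfying the sum
#' constraint:
#' \describe{
#'   \item{`"simplex"` (default)}{normalize `N_f` i.i.d. uniforms to unit
#'     sum, then scale by one further independent uniform, so the total is
#'     itself `U[0, 1]` for any `N_f`.}
#'   \item{`"rejection"`}{redraw `N_f` i.i.d. uniforms until their sum is
#'     at most 1 (practical only for small `N_f`).}
#' }
#'
#' @param n_modes Number of modes, at least 1.
#' @param scheme Weight scheme, see above.
#' @return Numeric vector of length `n_modes`, `sum(c) <= 1`.
#' @export
draw_mode_weights <- function(n_modes, scheme = c("simplex", "rejection")) {
  scheme <- match.arg(scheme)
  if (n_modes < 1L) stop("n_modes must be at least 1")
  if (scheme == "simplex") {
    u <- stats::runif(n_modes)
    u / sum(u) * stats::runif(1L)
  } else {
    repeat {
      u <- stats::runif(n_modes)
      if (sum(u) <= 1) return(u)
    }
  }
}

#' Draw displacement signs
#'
#' Independent fair Bernoulli signs so both sides of each harmonic well are
#' sampled equally.
#'
#' @param n_modes Number of modes.
#' @return Vector of `+1`/`-1` values.
#' @export
draw_signs <- function(n_modes) {
  sample(c(-1, 1), n_modes, replace = TRUE)
}

#' Thermal displacement magnitude along one mode
#'
#' Solves `1/2 K_i R_i^2 = c_i * 3/2 N_a k_b T` for `R_i`:
#' `R_i = sqrt(3 c_i N_a k_b T / K_i)`. The harmonic energy stored in mode
#' `i` at displacement `R_i` is thus exactly the `c_i`-scaled average
#' classical energy of `N_a` particles at temperature `T`.
#'
#' @param c_i Weight in `[0, 1]`.
#' @param n_atoms Atom count `N_a`.
#' @param temperature Kelvin, positive.
#' @param force_constant `K_i`, Hartree/Angstrom^2, positive.
#' @param constants Physical constants, see [physical_constants()].
#' @return Displacement magnitude in Angstrom (vectorized over `c_i` and
#'   `force_constant`).
#' @export
displacement_magnitude <- function(c_i, n_atoms, temperature, force_constant,
                                   constants = physical_constants()) {
  if (any(force_constant <= 0))
    stop("imaginary mode: force constant must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  if (any(c_i < 0 | c_i > 1)) stop("weights must lie in [0, 1]")
  sqrt(3 * c_i * n_atoms * constants$k_b * temperature / force_constant)
}

#' Generate one displaced conformer
#'
#' One realization of the normal-mode displacement: draw weights and signs
#' (unless supplied), convert each weight to a displacement magnitude, and
#' superpose the signed mode displacements onto the reference geometry.
#'
#' @param modes An `nms_modes` object.
#' @param temperature Kelvin.
#' @param constants Physical constants.
#' @param weights,signs Optional fixed draws (for deterministic tests);
#'   defaults draw fresh ones from the current RNG stream.
#' @param weight_scheme Passed to [draw_mode_weights()].
#' @return A list of class `nms_draw`: `weights`, `signs`, `magnitudes`,
#'   `displacement` (atoms x 3), `geometry` (displaced `nms_molecule`),
#'   `temperature`.
#' @export
generate_conformer <- function(modes, temperature,
                               constants = physical_constants(),
                               weights = NULL, signs = NULL,
                               weight_scheme = "simplex") {
  nf <- length(modes$force_constants)
  na <- n_atoms(modes$reference)
  if (is.null(weights)) weights <- draw_mode_weights(nf, weight_scheme)
  if (is.null(signs)) signs <- draw_signs(nf)
  stopifnot(length(weights) == nf, length(signs) == nf,
            all(signs %in% c(-1, 1)))
  r <- displacement_magnitude(weights, na, temperature,
                              modes$force_constants, constants)
  disp <- matrix(0, na, 3L)
  for (i in seq_len(nf))
    disp <- disp + signs[i] * r[i] * modes$modes[i, , ]
  geom <- modes$reference
  geom$coordinates <- geom$coordinates + disp
  structure(list(weights = weights, signs = signs, magnitudes = r,
                 displacement = disp, geometry = geom,
                 temperature = temperature),
            class = "nms_draw")
}

#' Sample a window of the potential surface around one equilibrium geometry
#'
#' Draws `N = S * N_f` conformers by normal-mode displacement at the
#' scheduled temperature, evaluates each with the supplied calculator, and
#' collects the results. Conformers whose energy evaluation fails are kept
#' in the set with status `"energy_failed"` but carry `NA` energy and are
#' excluded from all exported arrays, mirroring how failed single-point
#' calculations are dropped from a production dataset.
#'
#' @param molecule Equilibrium `nms_molecule`.
#' @param modes `nms_modes` for that geometry.
#' @param schedule An `nms_schedule`; the row is selected by
#'   [heavy_atom_count()].
#' @param calc An `nms_calculator`.
#' @param seed Integer seed; the per-molecule stream is derived from
#'   `(seed, molecule$id)` so results are independent of processing order.
#' @param n Overrides the conformer count (default `S * N_f`).
#' @param constants Physical constants.
#' @param weight_scheme Passed to [draw_mode_weights()].
#' @return A `conformer_set`: list with `molecule`, `equilibrium_energy`,
#'   `coordinates` (N x atoms x 3), `energies` (length N, `NA` where
#'   failed), `status` (`"ok"`/`"energy_failed"`), `weight_sums`,
#'   `temperatures`, and `provenance`.
#' @export
sample_window <- function(molecule, modes, schedule, calc, seed = 1L,
                          n = NULL, constants = physical_constants(),
                          weight_scheme = "simplex") {
  if (!is.null(calc$species) && !all(molecule$species %in% calc$species))
    stop("calculator '", calc$name, "' does not support species: ",
         paste(setdiff(molecule$species, calc$species), collapse = ", "))
  row <- schedule_lookup(schedule, heavy_atom_count(molecule))
  nf <- length(modes$force_constants)
  na <- n_atoms(molecule)
  if (is.null(n)) n <- conformer_count(row$S, nf)

  eq <- evaluate_energy(calc, molecule$species, molecule$coordinates)
  if (!eq$ok)
    warning("calculator failed on the equilibrium geometry of ",
            molecule$id, "; equilibrium energy recorded as NA")

  coords <- array(NA_real_, dim = c(n, na, 3L))
  energies <- rep(NA_real_, n)
  status <- character(n)
  wsums <- numeric(n)
  temps <- numeric(n)

  with_seed(derive_seed(seed, molecule$id), {
    for (k in seq_len(n)) {
      temp <- if (identical(row$temperature_mode, "uniform_up_to_max"))
        stats::runif(1L, 0, row$t_max) else row$t_max
      draw <- generate_conformer(modes, temp, constants,
                                 weight_scheme = weight_scheme)
      res <- evaluate_energy(calc, molecule$species,
                             draw$geometry$coordinates)
      coords[k, , ] <- draw$geometry$coordinates
      energies[k] <- res$energy
      status[k] <- if (res$ok) "ok" else "energy_failed"
      wsums[k] <- sum(draw$weights)
      temps[k] <- temp
    }
  })

  structure(list(molecule = molecule, equilibrium_energy = eq$energy,
                 coordinates = coords, energies = energies, status = status,
                 weight_sums = wsums, temperatures = temps,
                 provenance = list(S = row$S, t_max = row$t_max,
                                   temperature_mode = row$temperature_mode,
                                   seed = seed, calculator = calc$name,
                                   weight_scheme = weight_scheme)),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  n_ok <- sum(x$status == "ok")
  cat(sprintf(
    "<conformer set %s: %d conformers (%d ok, %d failed), T_max %g K, S %d>\n",
    x$molecule$id, length(x$energies), n_ok, length(x$energies) - n_ok,
    x$provenance$t_max, x$provenance$S))
  invisible(x)
}

#' @export
summary.conformer_set <- function(object, constants = physical_constants(), ...) {
  ok <- object$status == "ok"
  rise <- (object$energies[ok] - object$equilibrium_energy) *
    constants$hartree_to_kcalmol
  out <- list(id = object$molecule$id, n = length(object$energies),
              n_ok = sum(ok),
              energy_rise_kcalmol = if (any(ok)) summary(rise) else NULL)
  class(out) <- "summary.conformer_set"
  out
}

#' @export
print.summary.conformer_set <- function(x, ...) {
  cat(sprintf("conformer set %s: %d drawn, %d ok\n", x$id, x$n, x$n_ok))
  if (!is.null(x$energy_rise_kcalmol)) {
    cat("energy above equilibrium (kcal/mol):\n")
    print(x$energy_rise_kcalmol)
  }
  invisible(x)
}

# run code with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# mix a global seed with a molecule id into a 31-bit stream seed
derive_seed <- function(seed, id) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(id)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}
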