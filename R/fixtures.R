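#' Analytic Hessian from internal-coordinate springs
#'
#' Builds `H = sum_t k_t g_t g_t'` where each `g_t` is the Cartesian
#' gradient of an internal coordinate (bond length, bond angle, or a linear
#' bend) at the given geometry. At a stationary point of a potential
#' `sum 1/2 k_t (q_t - q_t0)^2` this is the exact Hessian, and it is exactly
#' invariant under rigid translations (and rotations, for well-chosen
#' internals), which makes it the ideal desk-scale stand-in for an ab initio
#' Hessian.
#'
#' @param coords Atoms x 3 matrix, Angstrom.
#' @param bonds List of `list(i, j, k)` bond springs (`k` in
#'   Hartree/Angstrom^2).
#' @param angles List of `list(i, j, k, k_theta)` angle springs with `j`
#'   central (`k_theta` in Hartree/rad^2).
#' @param linear_bends List of `list(i, j, k, k_bend, axis)` degenerate
#'   bends for collinear `i-j-k` with `axis` a unit vector perpendicular to
#'   the molecular axis (`k_bend` in Hartree/Angstrom^2).
#' @return Symmetric `3N x 3N` matrix, Hartree/Angstrom^2.
#' @export
internal_coordinate_hessian <- function(coords, bonds = list(),
                                        angles = list(),
                                        linear_bends = list()) {
  na <- nrow(coords)
  h <- matrix(0, 3L * na, 3L * na)
  add <- function(k, g) h <<- h + k * tcrossprod(g)
  slot <- function(i) (3L * (i - 1L) + 1L):(3L * i)
  for (b in bonds) {
    g <- numeric(3L * na)
    u <- coords[b$i, ] - coords[b$j, ]
    u <- u / sqrt(sum(u^2))
    g[slot(b$i)] <- u
    g[slot(b$j)] <- -u
    add(b$k, g)
  }
  for (a in angles) {
    g <- numeric(3L * na)
    u <- coords[a$i, ] - coords[a$j, ]
    v <- coords[a$k, ] - coords[a$j, ]
    ru <- sqrt(sum(u^2)); rv <- sqrt(sum(v^2))
    uh <- u / ru; vh <- v / rv
    cth <- sum(uh * vh)
    sth <- sqrt(max(1 - cth^2, 1e-12))
    gi <- (cth * uh - vh) / (ru * sth)
    gk <- (cth * vh - uh) / (rv * sth)
    g[slot(a$i)] <- gi
    g[slot(a$k)] <- gk
    g[slot(a$j)] <- -(gi + gk)
    add(a$k_theta, g)
  }
  for (lb in linear_bends) {
    g <- numeric(3L * na)
    e <- lb$axis / sqrt(sum(lb$axis^2))
    g[slot(lb$i)] <- e
    g[slot(lb$j)] <- -2 * e
    g[slot(lb$k)] <- e
    add(lb$k_bend, g / sqrt(6))
  }
  (h + t(h)) / 2
}

toy_entry <- function(molecule, hessian, reference_energy,
                      closed_form_K = NULL) {
  list(molecule = molecule, hessian = hessian,
       reference_energy = reference_energy, closed_form_K = closed_form_K)
}

#' Toy molecule builders
#'
#' Parameterized builders for the four toy systems the package tests
#' against. Each returns the molecule, its analytic quadratic-surface
#' Hessian, a synthetic reference energy, and (where one exists) the
#' closed-form normal-mode force constant.
#'
#' `make_diatomic()` is the fully solvable case: an equal-mass diatomic
#' with bond spring `k` has a single stretch mode whose Cartesian-normalized
#' force constant is exactly `2 k` (the unit displacement along
#' `(u, -u)/sqrt(2)` stretches the bond by `sqrt(2)`, so the spring energy
#' is `1/2 k (sqrt(2) x)^2 = 1/2 (2k) x^2`).
#'
#' @param d,k Bond length (Angstrom) and spring constant (Ha/A^2).
#' @param species Element symbols.
#' @param e_ref Synthetic reference energy, Hartree.
#' @return A list with `molecule`, `hessian`, `reference_energy`,
#'   `closed_form_K`.
#' @name toy_builders
NULL

#' @rdname toy_builders
#' @export
make_diatomic <- function(d = 0.74, k = 0.35, species = c("H", "H"),
                          e_ref = -1.17, id = NULL) {
  mol <- molecule(species, rbind(c(0, 0, 0), c(0, 0, d)), id = id)
  h <- internal_coordinate_hessian(mol$coordinates,
                                   bonds = list(list(i = 1L, j = 2L, k = k)))
  kk <- if (species[1L] == species[2L]) 2 * k else NULL
  toy_entry(mol, h, e_ref, closed_form_K = kk)
}

#' @rdname toy_builders
#' @param r Bond length(s), Angstrom.
#' @param theta Bond angle, degrees.
#' @param k_theta,k_bend Angle/bend spring constants.
#' @param id Molecule id override.
#' @export
make_water_like <- function(r = 0.9584, theta = 104.45, k = 0.45,
                            k_theta = 0.12, e_ref = -76.4, id = NULL) {
  half <- theta / 2 * pi / 180
  coords <- rbind(c(0, 0, 0),
                  c(0, r * sin(half), r * cos(half)),
                  c(0, -r * sin(half), r * cos(half)))
  mol <- molecule(c("O", "H", "H"), coords, id = id)
  h <- internal_coordinate_hessian(
    coords,
    bonds = list(list(i = 2L, j = 1L, k = k), list(i = 3L, j = 1L, k = k)),
    angles = list(list(i = 2L, j = 1L, k = 3L, k_theta = k_theta)))
  toy_entry(mol, h, e_ref)
}

#' @rdname toy_builders
#' @export
make_linear_triatomic <- function(r = 1.16, k = 0.6, k_bend = 0.08,
                                  e_ref = -188.6, id = NULL) {
  coords <- rbind(c(0, 0, -r), c(0, 0, 0), c(0, 0, r))
  mol <- molecule(c("O", "C", "O"), coords, id = id)
  h <- internal_coordinate_hessian(
    coords,
    bonds = list(list(i = 1L, j = 2L, k = k), list(i = 3L, j = 2L, k = k)),
    linear_bends = list(
      list(i = 1L, j = 2L, k = 3L, k_bend = k_bend, axis = c(1, 0, 0)),
      list(i = 1L, j = 2L, k = 3L, k_bend = k_bend, axis = c(0, 1, 0))))
  toy_entry(mol, h, e_ref)
}

#' @rdname toy_builders
#' @export
make_methane_like <- function(r = 1.09, k = 0.4, k_theta = 0.08,
                              e_ref = -40.5, id = NULL) {
  a <- r / sqrt(3)
  coords <- rbind(c(0, 0, 0), c(a, a, a), c(a, -a, -a), c(-a, a, -a),
                  c(-a, -a, a))
  mol <- molecule(c("C", "H", "H", "H", "H"), coords, id = id)
  bonds <- lapply(2:5, function(i) list(i = i, j = 1L, k = k))
  pairs <- utils::combn(2:5, 2L)
  angles <- lapply(seq_len(ncol(pairs)), function(p)
    list(i = pairs[1L, p], j = 1L, k = pairs[2L, p], k_theta = k_theta))
  h <- internal_coordinate_hessian(coords, bonds = bonds, angles = angles)
  toy_entry(mol, h, e_ref)
}

#' Library of toy molecules with analytic Hessians
#'
#' Four desk-scale systems chosen to exercise every branch of the
#' vibrational analysis: an equal-mass diatomic (1 mode, closed-form force
#' constant), a bent water-like triatomic (3 modes), a linear symmetric
#' triatomic (4 modes, the `3N-5` branch), and a tetrahedral methane-like
#' 5-atom system (9 modes).
#'
#' @return Named list of toy entries (`molecule`, `hessian`,
#'   `reference_energy`, `closed_form_K`).
#' @export
toy_molecule_library <- function() {
  list(diatomic = make_diatomic(id = "diatomic"),
       water = make_water_like(id = "water"),
       linear_triatomic = make_linear_triatomic(id = "linear_triatomic"),
       methane = make_methane_like(id = "methane"))
}

# one randomized toy: template choice + jittered geometry/springs,
# drawn from the current RNG stream
random_toy_molecule <- function(index) {
  template <- sample(c("water", "co_diatomic", "linear_triatomic",
                       "methane"), 1L)
  jg <- stats::runif(1L, 0.97, 1.03)   # geometry jitter
  jk <- stats::runif(1L, 0.8, 1.2)     # spring jitter
  id <- sprintf("%s_%03d", template, index)
  switch(template,
    water = make_water_like(r = 0.9584 * jg, k = 0.45 * jk,
                            k_theta = 0.12 * jk, id = id),
    co_diatomic = make_diatomic(d = 1.128 * jg, k = 0.8 * jk,
                                species = c("C", "O"), e_ref = -113.3,
                                id = id),
    linear_triatomic = make_linear_triatomic(r = 1.16 * jg, k = 0.6 * jk,
                                             k_bend = 0.08 * jk, id = id),
    methane = make_methane_like(r = 1.09 * jg, k = 0.4 * jk,
                                k_theta = 0.08 * jk, id = id))
}

#' Build a complete synthetic dataset end to end
#'
#' Emulates the whole production pipeline at desk scale: draw randomized
#' toy molecules, run normal-mode analysis on their analytic Hessians,
#' sample a window of conformers per molecule under the schedule, evaluate
#' every conformer with the chosen backend, curate at the energy window,
#' and write the records to the HDF5 format. Deterministic under `seed`.
#'
#' @param n_molecules Number of randomized toy molecules.
#' @param schedule Sampling schedule (default: the published 1-8 heavy-atom
#'   schedule).
#' @param seed Integer seed.
#' @param path Output HDF5 path, or `NULL` to skip writing.
#' @param backend `"harmonic"` (exact quadratic surfaces, never fails) or
#'   `"morse"` (anharmonic, with clash-induced evaluation failures).
#' @param config Curation configuration.
#' @return List with `records` (list of `ani_record`), `splits` (window
#'   splits), `summary` (an `nms_summary`), `n_failed` (conformers whose
#'   energy evaluation failed), and `path`.
#' @export
build_synthetic_dataset <- function(n_molecules = 8L,
                                    schedule = default_schedule(),
                                    seed = 1L, path = NULL,
                                    backend = c("harmonic", "morse"),
                                    config = curation_config()) {
  backend <- match.arg(backend)
  toys <- with_seed(derive_seed(seed, "toy-draw"),
                    lapply(seq_len(n_molecules), random_toy_molecule))
  splits <- vector("list", n_molecules)
  n_failed <- 0L
  for (i in seq_len(n_molecules)) {
    toy <- toys[[i]]
    nm <- normal_mode_analysis(toy$molecule, toy$hessian)
    calc <- if (backend == "harmonic")
      harmonic_calculator(toy$molecule, toy$reference_energy, toy$hessian)
    else
      morse_calculator(r0 = 1.1, r_fail = 0.5)
    cs <- sample_window(toy$molecule, nm, schedule, calc, seed = seed)
    n_failed <- n_failed + sum(cs$status != "ok")
    splits[[i]] <- energy_window_split(cs, config)
  }
  records <- lapply(splits, as_ani_record)
  if (!is.null(path)) write_ani_h5(path, records)
  list(records = records, splits = splits,
       summary = summarize_dataset(splits, schedule),
       n_failed = n_failed, path = path)
}

#' Equilibrium-only baseline dataset
#'
#' One conformer per toy molecule, at its equilibrium geometry and
#' reference energy. This is the comparison set for coverage statistics:
#' its pair-distance and angle histograms occupy only the bins an
#' off-equilibrium sampler expands beyond.
#'
#' @param library Named list of toy entries (default
#'   [toy_molecule_library()]).
#' @param path Output HDF5 path, or `NULL` to skip writing.
#' @return List with `records` and `path`.
#' @export
make_equilibrium_only_dataset <- function(library = toy_molecule_library(),
                                          path = NULL) {
  records <- lapply(library, function(toy)
    ani_record(toy$molecule$species,
               coordinates = toy$molecule$coordinates,
               energies = toy$reference_energy,
               smiles = toy$molecule$smiles, id = toy$molecule$id))
  names(records) <- names(library)
  if (!is.null(path)) write_ani_h5(path, records)
  list(records = records, path = path)
}
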