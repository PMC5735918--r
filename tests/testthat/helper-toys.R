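# shared fixtures: toy library + precomputed normal modes
toys <- toy_molecule_library()
toy_modes <- lapply(toys, function(t)
  normal_mode_analysis(t$molecule, t$hessian))
kc <- physical_constants()

# a tiny schedule usable for any heavy-atom count that appears in the toys
desk_schedule <- function(S = 2L, t_max = 300)
  sampling_schedule(heavy_atoms = 0:8, S = rep(S, 9L),
                    t_max = rep(t_max, 9L))

# calculator that always reports an SCF-style failure
failing_calculator <- function()
  calculator("always-fails", function(species, coordinates) NA_real_)

# harmonic backend for a toy entry
toy_harmonic <- function(toy)
  harmonic_calculator(toy$molecule, toy$reference_energy, toy$hessian)

# a random valid record for roundtrip-style property tests
random_record <- function(n_atoms = 3L, n_low = 4L, n_high = 2L,
                          species = NULL) {
  if (is.null(species))
    species <- sample(c("H", "C", "N", "O"), n_atoms, replace = TRUE)
  ani_record(species,
             coordinates = array(stats::rnorm(n_low * n_atoms * 3L),
                                 dim = c(n_low, n_atoms, 3L)),
             energies = stats::rnorm(n_low, mean = -40),
             coordinatesHE = array(stats::rnorm(n_high * n_atoms * 3L),
                                   dim = c(n_high, n_atoms, 3L)),
             energiesHE = stats::rnorm(max(n_high, 0L), mean = -39),
             smiles = "C")
}
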