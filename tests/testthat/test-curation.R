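# build a conformer_set-shaped object with prescribed energies
fake_set <- function(energies, eq_energy = min(energies),
                     status = rep("ok", length(energies))) {
  n <- length(energies)
  structure(list(molecule = toys$water$molecule,
                 equilibrium_energy = eq_energy,
                 coordinates = array(0, dim = c(n, 3L, 3L)),
                 energies = energies, status = status,
                 weight_sums = rep(0.5, n), temperatures = rep(300, n),
                 provenance = list(S = 1L, t_max = 300,
                                   temperature_mode = "fixed_at_max",
                                   seed = 1L, calculator = "fake",
                                   weight_scheme = "simplex")),
            class = "conformer_set")
}

kcal <- function(x) x / physical_constants()$hartree_to_kcalmol

test_that("the energy window keeps the boundary and splits strictly above", {
  cfg <- curation_config(threshold_kcal = 275)
  # all energies equal: everything low
  sp <- energy_window_split(fake_set(rep(-10, 5L)), cfg)
  expect_length(sp$low$energies, 5L)
  expect_length(sp$high$energies, 0L)
  # one conformer 300 kcal/mol above the minimum goes high
  e <- c(-10, -10 + kcal(300))
  sp <- energy_window_split(fake_set(e), cfg)
  expect_equal(sp$high$energies, -10 + kcal(300))
  # exactly at the threshold stays low under the inclusive default
  # (minimum anchored at 0 so the relative energy is bit-exact)
  e <- c(0, kcal(275))
  sp <- energy_window_split(fake_set(e), cfg)
  expect_length(sp$low$energies, 2L)
  # and moves high when the boundary is exclusive
  cfg_ex <- curation_config(275, inclusive_boundary = FALSE)
  sp <- energy_window_split(fake_set(e), cfg_ex)
  expect_length(sp$high$energies, 1L)
})

test_that("window splitting conserves, shifts and orders correctly", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:60, 1L)
    e <- -40 + stats::rcauchy(n) * 0.1  # heavy tails cross the window
    cs <- fake_set(e)
    cfg <- curation_config(threshold_kcal = stats::runif(1L, 5, 400))
    sp <- energy_window_split(cs, cfg)
    # partition conservation
    expect_identical(length(sp$low$energies) + length(sp$high$energies), n)
    expect_setequal(c(sp$low$energies, sp$high$energies), e)
    # shift invariance of the relative window
    sp_shift <- energy_window_split(fake_set(e + 3.21), cfg)
    expect_equal(sort(sp_shift$low$energies) - 3.21,
                 sort(sp$low$energies), tolerance = 1e-12)
    # threshold monotonicity
    cfg_wide <- curation_config(cfg$threshold_kcal * 1.5)
    sp_wide <- energy_window_split(cs, cfg_wide)
    expect_gte(length(sp_wide$low$energies), length(sp$low$energies))
  }
})

test_that("failed conformers belong to neither partition", {
  e <- c(-10, -9.9, NA, -9.8)
  cs <- fake_set(e, eq_energy = -10,
                 status = c("ok", "ok", "energy_failed", "ok"))
  sp <- energy_window_split(cs, curation_config(1000))
  expect_identical(length(sp$low$energies) + length(sp$high$energies), 3L)
  expect_error(energy_window_split(
    fake_set(NA_real_, eq_energy = NA_real_, status = "energy_failed")),
    "no usable energies")
})

test_that("the equilibrium energy anchors the window reference by default", {
  # equilibrium below every sampled conformer: with it included, a
  # conformer 280 kcal/mol above equilibrium but 0 above the lowest sample
  # is still high
  e <- -10 + kcal(c(280, 280))
  cs <- fake_set(e, eq_energy = -10)
  sp <- energy_window_split(cs, curation_config(275))
  expect_length(sp$high$energies, 2L)
  cfg_no_eq <- curation_config(275, include_equilibrium = FALSE)
  sp2 <- energy_window_split(cs, cfg_no_eq)
  expect_length(sp2$high$energies, 0L)
})

test_that("summary rows add low plus high and the grand total sums columns", {
  counts <- data.frame(heavy_atoms = c(1L, 2L), molecules = c(1L, 2L),
                       t_max = c(300, 300), S = c(2L, 2L),
                       low = c(6L, 10L), high = c(0L, 3L))
  s <- dataset_summary(counts)
  expect_equal(s$total[1:2], c(6L, 13L))
  expect_equal(s["Total", "low"], 16L)
  expect_equal(s["Total", "high"], 3L)
  expect_equal(s["Total", "total"], 19L)
  expect_equal(s["Total", "molecules"], 3L)
})

test_that("summarize_dataset groups curated sets by heavy-atom count", {
  toy_sets <- list(
    energy_window_split(fake_set(rep(-10, 4L))),
    energy_window_split(fake_set(c(-10, -10 + kcal(300)))))
  s <- summarize_dataset(toy_sets, desk_schedule())
  row <- s[!is.na(s$heavy_atoms), ]
  expect_identical(nrow(row), 1L)  # both sets are 1-heavy-atom molecules
  expect_equal(row$molecules, 2L)
  expect_equal(row$low, 5L)
  expect_equal(row$high, 1L)
  expect_equal(s["Total", "total"], 6L)
})

test_that("exclusion accounting reproduces retained counts and rates", {
  rep1 <- exclusion_report(485L, 57947L)
  expect_identical(rep1$n_retained, 57462L)
  expect_identical(rep1$failure_rate_percent, 0.84)
  rep2 <- exclusion_report(integer(), 100L)
  expect_identical(rep2$n_retained, 100L)
  expect_identical(rep2$failure_rate_percent, 0)
  # a log vector counts by length
  rep3 <- exclusion_report(c("mol_a", "mol_b"), 10L)
  expect_identical(rep3$n_failed, 2L)
  expect_error(exclusion_report(11L, 10L), "more failures")
})
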