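test_that("mode weights are nonnegative with sum at most one", {
  set.seed(11)
  expect_error(draw_mode_weights(0L), "at least 1")
  for (scheme in c("simplex", "rejection")) {
    w1 <- draw_mode_weights(1L, scheme)
    expect_true(w1 >= 0 && w1 <= 1)
    for (nf in c(2L, 5L, 9L)) {
      w <- draw_mode_weights(nf, scheme)
      expect_length(w, nf)
      expect_true(all(w >= 0))
      expect_lte(sum(w), 1)
    }
  }
})

test_that("total assigned thermal fraction averages one half", {
  # under the simplex scheme sum(c) is itself U[0,1]; Monte-Carlo oracle:
  # mean 0.5, sd 1/sqrt(12), so a 3-standard-error band at n = 1e5 is
  # 0.5 +/- 3 * 0.28868 / sqrt(1e5)
  set.seed(42)
  n <- 1e5L
  sums <- replicate(n, sum(draw_mode_weights(3L)))
  expect_lt(abs(mean(sums) - 0.5), 3 * sqrt(1 / 12) / sqrt(n))
  expect_lte(max(sums), 1)
})

test_that("displacement magnitudes follow the thermal closed form", {
  expect_identical(displacement_magnitude(0, 3L, 300, 0.5), 0)
  # frozen high-precision evaluation of sqrt(3 * (1/3) * 3 * k_b * 300 / 0.5)
  expect_equal(displacement_magnitude(1 / 3, 3L, 300, 0.5),
               0.0755000716118866, tolerance = 1e-12)
  r <- displacement_magnitude(0.2, 4L, 350, 0.8)
  expect_equal(displacement_magnitude(0.2, 4L, 700, 0.8), sqrt(2) * r,
               tolerance = 1e-12)
  expect_equal(displacement_magnitude(0.2, 4L, 350, 3.2), r / 2,
               tolerance = 1e-12)
  expect_error(displacement_magnitude(0.2, 4L, 350, -1), "imaginary")
  expect_error(displacement_magnitude(0.2, 4L, 0, 1), "temperature")
  expect_error(displacement_magnitude(1.2, 4L, 350, 1), "\\[0, 1\\]")
})

test_that("signs are fair, two-valued and seed-reproducible", {
  set.seed(5)
  s <- draw_signs(1e5L)
  expect_true(all(s %in% c(-1, 1)))
  # binomial oracle: fraction of +1 within 3 sigma of 0.5
  expect_lt(abs(mean(s == 1) - 0.5), 3 * 0.5 / sqrt(1e5))
  set.seed(99)
  a <- draw_signs(20L)
  set.seed(99)
  expect_identical(draw_signs(20L), a)
})

test_that("conformer displacement is the signed superposition of modes", {
  nm <- toy_modes$water
  nf <- length(nm$force_constants)
  # all weights zero: geometry identical to equilibrium
  d0 <- generate_conformer(nm, 300, weights = rep(0, nf),
                           signs = rep(1, nf))
  expect_identical(d0$geometry$coordinates, nm$reference$coordinates)
  # single active mode: displacement is exactly sign * R * q_hat
  w <- c(0.4, 0, 0)
  d1 <- generate_conformer(nm, 300, weights = w, signs = c(-1, 1, 1))
  r1 <- displacement_magnitude(0.4, 3L, 300, nm$force_constants[1L])
  expect_equal(d1$displacement, -r1 * nm$modes[1L, , ], tolerance = 1e-12)
  # general draw: displacement equals the mode superposition
  set.seed(3)
  d <- generate_conformer(nm, 500)
  manual <- Reduce(`+`, lapply(seq_len(nf), function(i)
    d$signs[i] * d$magnitudes[i] * nm$modes[i, , ]))
  expect_equal(d$displacement, manual, tolerance = 1e-12)
})

test_that("on a quadratic surface the energy rise is the scaled thermal energy", {
  toy <- toys$methane
  nm <- toy_modes$methane
  calc <- toy_harmonic(toy)
  set.seed(8)
  for (rep in 1:25) {
    d <- generate_conformer(nm, 450)
    e <- evaluate_energy(calc, toy$molecule$species,
                         d$geometry$coordinates)$energy
    expect_equal(e - toy$reference_energy,
                 1.5 * 5 * kc$k_b * 450 * sum(d$weights),
                 tolerance = 1e-9)
  }
})

test_that("conformer counts multiply points per mode by mode count", {
  expect_identical(conformer_count(5L, 60L), 300L)
  expect_identical(conformer_count(425L, 3L), 1275L)
  expect_error(conformer_count(5L, 0L), "dof")
  expect_error(conformer_count(0L, 3L), "S must")
})

test_that("the shipped schedule matches the published sampling table", {
  sched <- default_schedule()
  row8 <- schedule_lookup(sched, 8L)
  expect_identical(row8$S, 5L)
  expect_identical(row8$t_max, 450)
  row1 <- schedule_lookup(sched, 1L)
  expect_identical(row1$S, 500L)
  expect_identical(row1$t_max, 2000)
  expect_error(schedule_lookup(sched, 9L), "no schedule row")
})

test_that("sample_window draws S x dof conformers and records failures", {
  toy <- toys$water
  nm <- toy_modes$water
  cs <- sample_window(toy$molecule, nm, desk_schedule(S = 2L),
                      toy_harmonic(toy), seed = 1L)
  expect_length(cs$energies, 6L)  # S=2 x 3 modes
  expect_true(all(cs$status == "ok"))
  expect_true(all(cs$energies >= cs$equilibrium_energy))
  # an always-failing backend yields zero usable conformers but keeps count
  expect_warning(
    cs_fail <- sample_window(toy$molecule, nm, desk_schedule(S = 2L),
                             failing_calculator(), seed = 1L, n = 4L),
    "equilibrium")
  expect_length(cs_fail$status, 4L)
  expect_true(all(cs_fail$status == "energy_failed"))
  expect_true(all(is.na(cs_fail$energies)))
  # unsupported species are rejected before any sampling happens
  narrow <- calculator("h-only", function(s, x) 0, species = "H")
  expect_error(sample_window(toy$molecule, nm, desk_schedule(), narrow),
               "does not support species")
})

test_that("sampling is deterministic under the seed and processing order", {
  toy <- toys$water
  nm <- toy_modes$water
  calc <- toy_harmonic(toy)
  a <- sample_window(toy$molecule, nm, desk_schedule(S = 3L), calc, seed = 7L)
  b <- sample_window(toy$molecule, nm, desk_schedule(S = 3L), calc, seed = 7L)
  expect_identical(a, b)
  # the per-molecule stream derives from (seed, id): interleaving another
  # molecule does not change this molecule's draw
  other <- toys$diatomic
  invisible(sample_window(other$molecule, toy_modes$diatomic,
                          desk_schedule(S = 3L), toy_harmonic(other),
                          seed = 7L))
  c <- sample_window(toy$molecule, nm, desk_schedule(S = 3L), calc, seed = 7L)
  expect_identical(a, c)
  # a different seed gives a different draw
  d <- sample_window(toy$molecule, nm, desk_schedule(S = 3L), calc, seed = 8L)
  expect_false(identical(a$energies, d$energies))
})

test_that("displacement magnitudes grow stochastically with temperature", {
  nm <- toy_modes$water
  set.seed(21)
  mags <- function(temp) replicate(400L, {
    d <- generate_conformer(nm, temp)
    sqrt(sum(d$displacement^2))
  })
  m300 <- mags(300)
  m1200 <- mags(1200)
  # the closed form scales each draw by sqrt(T); distributions must shift up
  expect_true(all(stats::quantile(m1200, c(0.25, 0.5, 0.75)) >
                    stats::quantile(m300, c(0.25, 0.5, 0.75))))
})

test_that("mean displacement vanishes by sign symmetry", {
  nm <- toy_modes$diatomic
  set.seed(13)
  n <- 4000L
  disp <- vapply(seq_len(n), function(i)
    as.vector(generate_conformer(nm, 600)$displacement), numeric(6L))
  # componentwise 3-sigma band around zero (binomial sign symmetry)
  for (j in seq_len(6L)) {
    se <- stats::sd(disp[j, ]) / sqrt(n)
    expect_lt(abs(mean(disp[j, ])), max(3 * se, 1e-12))
  }
})

test_that("uniform temperature mode draws below the scheduled maximum", {
  toy <- toys$water
  sched <- sampling_schedule(0:8, rep(2L, 9L), rep(800, 9L),
                             temperature_mode = "uniform_up_to_max")
  cs <- sample_window(toy$molecule, toy_modes$water, sched,
                      toy_harmonic(toy), seed = 2L, n = 40L)
  expect_true(all(cs$temperatures <= 800))
  expect_gt(stats::sd(cs$temperatures), 0)
})
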