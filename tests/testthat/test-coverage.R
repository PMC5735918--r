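diatomic_record <- function(r, species = c("H", "H"), energy = -1) {
  ani_record(species, rbind(c(0, 0, 0), c(0, 0, r)), energy)
}

test_that("histograms conserve mass and normalize to unit total", {
  set.seed(41)
  rec <- ani_record(c("H", "H", "H"),
                    array(stats::rnorm(5 * 9), dim = c(5L, 3L, 3L)),
                    rep(-1, 5L))
  h <- pair_distance_histogram(rec, c("H", "H"), r0 = 1)
  # 3 atoms -> choose(3,2)=3 pairs per conformer, 5 conformers
  expect_identical(h$total, 15L)
  expect_identical(sum(h$counts), h$total)
  expect_equal(sum(h$counts / h$total), 1, tolerance = 1e-12)
  # log series: occupied bins finite, empty bins NA (omitted, not clamped)
  expect_true(all(is.finite(h$log10_norm[h$counts > 0L])))
  expect_true(all(is.na(h$log10_norm[h$counts == 0L])))
})

test_that("a diatomic at its reference distance lands in the r/r0 = 1 bin", {
  rec <- diatomic_record(0.96, c("O", "H"))
  breaks <- seq(0.05, 2.05, by = 0.1)  # 1.0 is interior to a bin
  h <- pair_distance_histogram(rec, c("H", "O"), r0 = 0.96, breaks = breaks)
  expect_identical(h$total, 1L)
  bin_of_one <- findInterval(1, breaks)
  expect_identical(h$counts[bin_of_one], 1L)
  expect_identical(sum(h$counts), 1L)
})

test_that("distance histograms are invariant to rigid motions", {
  set.seed(43)
  coords <- array(stats::rnorm(4 * 12), dim = c(4L, 4L, 3L))
  sp <- c("C", "H", "H", "O")
  rec <- ani_record(sp, coords, rep(-40, 4L))
  # random rotation (QR of a Gaussian matrix) + translation per conformer
  rot <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  moved <- coords
  for (k in 1:4)
    moved[k, , ] <- coords[k, , ] %*% rot + rep(c(5, -2, 7), each = 4L)
  rec2 <- ani_record(sp, moved, rep(-40, 4L))
  breaks <- seq(0, 12, by = 0.05)
  h1 <- pair_distance_histogram(rec, c("C", "H"), 1.09, breaks = breaks)
  h2 <- pair_distance_histogram(rec2, c("C", "H"), 1.09, breaks = breaks)
  expect_identical(h1$counts, h2$counts)
})

test_that("Bernoulli subsampling tallies a binomial share of the pairs", {
  set.seed(47)
  n_atoms <- 450L  # choose(450, 2) = 101025 pairs in one conformer
  rec <- ani_record(rep("H", n_atoms),
                    array(stats::rnorm(n_atoms * 3) * 5,
                          dim = c(1L, n_atoms, 3L)),
                    -1)
  p <- 0.01
  h <- pair_distance_histogram(rec, c("H", "H"), r0 = 1,
                               subsample_rate = p, seed = 3L,
                               breaks = seq(0, 60, by = 0.5))
  n_pairs <- choose(n_atoms, 2L)
  expect_lt(abs(h$total - n_pairs * p), 4 * sqrt(n_pairs * p * (1 - p)))
  # same seed, same tally; different seed, (almost surely) different
  h_again <- pair_distance_histogram(rec, c("H", "H"), r0 = 1,
                                     subsample_rate = p, seed = 3L,
                                     breaks = seq(0, 60, by = 0.5))
  expect_identical(h$counts, h_again$counts)
})

test_that("angle histograms tally internal angles in [0, 180] degrees", {
  equilateral <- ani_record(
    c("H", "H", "H"),
    rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)), -1)
  h <- angle_histogram(equilateral, c("H", "H", "H"), mode = "all")
  expect_identical(h$total, 3L)  # each vertex once (unordered ends)
  expect_identical(sum(h$counts[h$mids > 55 & h$mids < 65]), 3L)

  collinear <- ani_record(c("O", "C", "O"),
                          rbind(c(0, 0, -1.16), c(0, 0, 0), c(0, 0, 1.16)),
                          -188)
  h2 <- angle_histogram(collinear, c("O", "C", "O"), mode = "all")
  expect_identical(h2$counts[length(h2$counts)], 1L)  # the 180-degree bin

  set.seed(51)
  rand <- ani_record(c("H", "O", "H"),
                     array(stats::rnorm(6 * 3), dim = c(6L, 3L, 3L)),
                     rep(-76, 6L))
  h3 <- angle_histogram(rand, c("H", "O", "H"), mode = "all")
  expect_identical(h3$n_out_of_range, 0L)  # angles never leave [0, 180]
  expect_identical(h3$total, 6L)
})

test_that("bonded mode drops triples beyond the distance cutoff", {
  # one H near O, one H far away: the bonded triple count is zero
  stretched <- ani_record(c("O", "H", "H"),
                          rbind(c(0, 0, 0), c(0, 0, 0.96), c(0, 0, 5)),
                          -76)
  r0_tab <- c("H-O" = 0.96)
  expect_error(angle_histogram(stretched, c("H", "O", "H"),
                               r0_table = r0_tab),
               "no matching")
  near <- ani_record(c("O", "H", "H"),
                     rbind(c(0, 0, 0), c(0, 0, 0.96), c(0, 0.96, 0)), -76)
  h <- angle_histogram(near, c("H", "O", "H"), r0_table = r0_tab)
  expect_identical(h$total, 1L)
})

test_that("energy-per-electron histograms divide and normalize per subset", {
  rec <- ani_record(c("H", "H"), array(0, dim = c(2L, 2L, 3L)),
                    c(-1.0, -1.2))
  out <- energy_per_electron_distribution(
    rec, breaks = seq(-0.7, -0.4, by = 0.01))
  expect_named(out, "gdb00")
  h <- out[[1L]]
  expect_identical(h$total, 2L)
  vals_expected <- c(-0.5, -0.6)
  for (v in vals_expected)
    expect_identical(h$counts[findInterval(v, h$breaks,
                                           left.open = TRUE)], 1L)
  expect_equal(sum(h$counts / h$total), 1, tolerance = 1e-12)
  # translating every energy by a per-electron shift translates the tally
  rec2 <- ani_record(c("H", "H"), array(0, dim = c(2L, 2L, 3L)),
                     c(-1.0, -1.2) + 2 * 0.05)
  h2 <- energy_per_electron_distribution(
    rec2, breaks = seq(-0.7, -0.4, by = 0.01) + 0.05)[[1L]]
  expect_identical(h2$counts, h$counts)
})

test_that("atomization-energy tallies report their maximum", {
  tab <- c(H = -0.5, O = -75)
  recs <- list(
    ani_record(c("O", "H", "H"), array(0, dim = c(2L, 3L, 3L)),
               c(-76.3, -76.1)),
    ani_record(c("H", "H"), array(0, dim = c(1L, 2L, 3L)), -1.1))
  h <- atomization_energy_distribution(recs, tab)
  expect_identical(h$total, 3L)
  expect_equal(h$max_value, max(-76.3, -76.1) + 76, tolerance = 1e-12)
  expect_lt(h$max_value, 0)  # all conformers bound by construction
  # the all-zero table reduces to a histogram of raw totals
  h_raw <- atomization_energy_distribution(recs, c(H = 0, O = 0))
  expect_equal(h_raw$max_value, -1.1, tolerance = 1e-12)
})
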