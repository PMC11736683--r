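test_that("flat and two-level histograms invert to the expected profiles", {
  kT <- 0.008314462618 * 310
  # analytically uniform histogram -> F identically zero
  breaks <- seq(-5, 5, by = 2.5)
  z <- z_from_bin_probs(breaks, c(10, 10, 10, 10))
  tr <- traj_from_z(z, box_z = 10)
  pr <- free_energy_profile(tr, breaks = breaks, water_region = c(2.5, 5),
                            temperature = 310, n_blocks = 0)
  expect_equal(pr$F, rep(0, 4), tolerance = 1e-12)

  # doubling one bin's probability lowers its F by exactly kBT ln 2
  z <- z_from_bin_probs(breaks, c(10, 10, 20, 10))
  tr <- traj_from_z(z, box_z = 10)
  pr <- free_energy_profile(tr, breaks = breaks, water_region = c(2.5, 5),
                            temperature = 310, n_blocks = 0)
  expect_equal(pr$F, c(0, 0, -kT * log(2), 0), tolerance = 1e-12)

  # in kBT units the drop is exactly ln 2
  pr_kt <- free_energy_profile(tr, breaks = breaks, water_region = c(2.5, 5),
                               temperature = 310, units = "kBT",
                               n_blocks = 0)
  expect_equal(pr_kt$F[3], -log(2), tolerance = 1e-12)
})

test_that("empty bins are missing values, never infinities", {
  breaks <- seq(-5, 5, by = 2.5)
  z <- z_from_bin_probs(breaks, c(10, 0, 20, 10))
  tr <- traj_from_z(z, box_z = 10)
  pr <- free_energy_profile(tr, breaks = breaks, water_region = c(2.5, 5),
                            n_blocks = 0)
  expect_true(is.na(pr$F[2]))
  expect_false(any(is.infinite(pr$F)))
  # histogram conservation
  expect_equal(sum(pr$counts), n_frames(tr) * 1L)
})

test_that("a constant added to the generator's F leaves the profile unchanged", {
  well <- function(z) -2 * exp(-z^2 / 8)
  shifted <- function(z) well(z) + 7
  sp1 <- permeation_spec(F = well, D = 1, box_z = 20, n_steps = 5000,
                         seed = 9)
  sp2 <- permeation_spec(F = shifted, D = 1, box_z = 20, n_steps = 5000,
                         seed = 9)
  t1 <- simulate_permeation_1d(sp1)
  t2 <- simulate_permeation_1d(sp2)
  expect_equal(t1$xyz, t2$xyz, tolerance = 1e-12)
  p1 <- free_energy_profile(t1, water_region = c(7, 10), n_blocks = 0)
  p2 <- free_energy_profile(t2, water_region = c(7, 10), n_blocks = 0)
  expect_equal(p1$F, p2$F, tolerance = 1e-12)
})

test_that("identical blocks give zero block error", {
  segment <- c(z_from_bin_probs(seq(-5, 5, 2.5), c(5, 8, 12, 5)))
  z <- rep(segment, 10)
  tr <- traj_from_z(z, box_z = 10)
  err <- block_errors(tr, breaks = seq(-5, 5, 2.5), water_region = c(2.5, 5),
                      n_blocks = 10)
  expect_equal(err, rep(0, 4), tolerance = 1e-12)
})

test_that("block errors shrink roughly as 1/sqrt(length)", {
  mk <- function(n, seed) {
    sp <- permeation_spec(D = 1, box_z = 30, n_steps = n, seed = seed)
    simulate_permeation_1d(sp)
  }
  e1 <- block_errors(mk(1e5, 4), bin_width = 1, water_region = c(10, 15))
  e2 <- block_errors(mk(2e5, 4), bin_width = 1, water_region = c(10, 15))
  ratio <- mean(e2 / e1, na.rm = TRUE)
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 0.85)
})

test_that("independent seeds agree within two combined errors", {
  well <- function(z) -2 * exp(-z^2 / (2 * 2^2))
  run <- function(seed) {
    sp <- permeation_spec(F = well, D = 1, box_z = 30, n_steps = 2e5,
                          seed = seed)
    tr <- simulate_permeation_1d(sp)
    pr <- free_energy_profile(tr, bin_width = 1, water_region = c(10, 15))
    pr
  }
  p1 <- run(101)
  p2 <- run(202)
  sampled <- p1$counts > 100 & p2$counts > 100
  dev <- abs(p1$F - p2$F)[sampled]
  comb <- sqrt(p1$F_err^2 + p2$F_err^2)[sampled]
  expect_gte(mean(dev <= 2 * comb), 0.95)
})

test_that("reference-region and block-count validation errors fire", {
  z <- z_from_bin_probs(seq(-5, 5, 2.5), c(10, 10, 10, 0))
  tr <- traj_from_z(z, box_z = 10)
  expect_error(free_energy_profile(tr, breaks = seq(-5, 5, 2.5),
                                   water_region = c(3.8, 5), n_blocks = 0),
               "no counts")
  expect_error(block_errors(tr, water_region = c(0, 5), n_blocks = 1),
               "n_blocks >= 2")
})

test_that("membrane partitioning free energy has the documented sign", {
  mk_profile <- function(F_kt) {
    breaks <- seq(-5, 5, 2.5)
    structure(list(bin_centers = (breaks[-1] + breaks[-5]) / 2,
                   F = F_kt, F_err = rep(NA_real_, 4),
                   counts = rep(10L, 4), breaks = breaks,
                   water_region = c(2.5, 5), temperature = 310,
                   units = "kBT"),
              class = "fe_profile")
  }
  expect_equal(delta_g_membrane(mk_profile(c(0, 0, 0, 0))), 0)
  # a well of -3.22 kBT at the center maps to dG_m = +3.22 kBT
  expect_equal(delta_g_membrane(mk_profile(c(0, 0, -3.22, 0))), 3.22)
  # kJ/mol profiles are converted to kBT
  p <- mk_profile(c(0, 0, -2 * 0.008314462618 * 310, 0))
  p$units <- "kJ/mol"
  expect_equal(delta_g_membrane(p), 2, tolerance = 1e-12)
  # empty center bin is a reference error
  p2 <- mk_profile(c(0, 0, NA, 0))
  expect_error(delta_g_membrane(p2), "empty")
})

test_that("the generator's input profile is recovered by inversion", {
  well <- function(z) -2 * exp(-z^2 / (2 * 2.5^2))
  sp <- permeation_spec(F = well, D = 1, box_z = 30, n_steps = 2e5,
                        seed = 1, temperature = 310)
  tr <- simulate_permeation_1d(sp)
  pr <- free_energy_profile(tr, bin_width = 1, water_region = c(10, 15))
  sampled <- pr$counts > 200
  truth <- well(pr$bin_centers) -
    mean(well(pr$bin_centers)[sampled &
           abs(pr$bin_centers) >= 10 & abs(pr$bin_centers) <= 15])
  expect_lt(max(abs(pr$F - truth)[sampled]), 0.35)  # kJ/mol
})
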