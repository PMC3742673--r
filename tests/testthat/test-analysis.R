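test_that("radius of gyration matches closed forms", {
  expect_identical(radius_of_gyration(matrix(c(5, 2, 9), 1)), 0)

  # 12 collinear nodes spaced 2 apart: Rg = sqrt(572/12)
  rod <- generate_fixture("rod", n = 12, spacing = 2)
  expect_equal(radius_of_gyration(rod$coords), sqrt(572 / 12),
               tolerance = 1e-12)
  expect_equal(radius_of_gyration(rod$coords), 6.90410986, tolerance = 1e-6)
})

test_that("power-law exponent fits recover exact exponents", {
  t <- 10^seq(0, 4, by = 0.1)
  f1 <- fit_power_exponent(t, t, window = range(t))
  expect_equal(f1$exponent, 1, tolerance = 1e-10)
  f2 <- fit_power_exponent(t, sqrt(t), window = range(t))
  expect_equal(f2$exponent, 0.5, tolerance = 1e-10)

  expect_error(fit_power_exponent(t[1:4], t[1:4], window = range(t[1:4])),
               "at least 5")
  expect_error(fit_power_exponent(t, t - 5, window = range(t)), "nonpositive")
})

test_that("center-of-mass displacement is zero at t=0 and for frozen chains", {
  cfg <- simulation_config(L = 16L, C_p = 0.2, T = 1.0, n_mcs = 100L,
                           seed = 6L)
  tr <- run_simulation(cfg)
  dyn <- rms_com_displacement(tr)
  expect_identical(dyn$rc[1], 0)
  expect_true(all(dyn$rc >= 0))

  # a zero-MCS (frozen) trajectory has identically zero displacement
  cfg0 <- simulation_config(L = 16L, C_p = 0.2, T = 1.0, n_mcs = 0L,
                            seed = 6L)
  dyn0 <- rms_com_displacement(run_simulation(cfg0))
  expect_identical(dyn0$rc, 0)
})

test_that("free chains diffuse with gamma near 1/2", {
  # constraint-only dynamics (zero interaction matrix) as the random-walk
  # oracle for center-of-mass diffusion
  zero <- delta_matrix("A", "A", 0)
  trs <- lapply(c(101L, 102L, 103L), function(s) {
    cfg <- simulation_config(L = 16L, C_p = 0.3, T = 1.0, n_mcs = 3000L,
                             seed = s)
    run_simulation(cfg, matrix = zero)
  })
  fit <- fit_power_exponent(rms_com_displacement(trs))
  expect_gt(fit$exponent, 0.35)
  expect_lt(fit$exponent, 0.65)
})

test_that("per-residue profiles expose end effects and pair accounting", {
  # uniform homopolymer with all-equal attraction: ends are more mobile
  # than the interior, and energy-profile sums are consistent with the
  # system's pairwise accounting (each pair counted twice)
  mat <- delta_matrix("A", "A", -5)
  cfg <- simulation_config(L = 16L, C_p = 0.3, T = 1.0, n_mcs = 400L,
                           seed = 11L)
  poly <- parse_sequence(paste(rep("A", 10), collapse = ""), name = "polyA")
  tr <- run_simulation(cfg, poly, mat)

  mob <- mobility_profile(tr)
  inner <- mean(mob$mean[4:7])
  expect_gt(mob$mean[1], inner)
  expect_gt(mob$mean[10], inner)

  ep <- energy_profile(tr)
  expect_identical(nrow(ep), 10L)
  expect_true(all(ep$se >= 0))
  # profile mean x node count == 2 x pair energy, averaged over the window
  sel <- which(tr$times >= max(tr$times) / 2)
  mean_total <- mean(tr$energy[sel])
  expect_equal(sum(ep$mean) * tr$state$n_chains / 2, mean_total,
               tolerance = 1e-6)

  # zero-MCS trajectory: mobility identically zero
  cfg0 <- simulation_config(L = 16L, C_p = 0.3, T = 1.0, n_mcs = 0L,
                            seed = 11L)
  mob0 <- mobility_profile(run_simulation(cfg0, poly, mat))
  expect_identical(unname(mob0$mean), rep(0, 10))

  expect_error(energy_profile(tr, window = c(1e6, 2e6)), "window")
})

test_that("radial profile conserves residues and tracks density", {
  # all residues at the center: everything in the first bin
  pc <- generate_fixture("point_cluster", n = 50)
  rdf <- radial_distribution(pc)
  expect_identical(rdf$count[1], 50L)
  expect_identical(sum(rdf$count), 50L)

  # uniform occupancy: counts proportional to shell volume
  gas <- generate_fixture("uniform_gas", n = 8000, L = 32, seed = 8L)
  rdfg <- radial_distribution(gas, bin_width = 1)
  expect_identical(sum(rdfg$count), 8000L)
  vol <- 4 / 3 * pi * (rdfg$r_upper^3 - rdfg$r_lower^3)
  inner <- rdfg$r_upper <= 16   # shells fully inside the box
  dens <- rdfg$count[inner] / vol[inner]
  expect_lt(stats::sd(dens[-(1:3)]) / mean(dens[-(1:3)]), 0.15)
})

test_that("structure factor has exact coherent and ideal-chain limits", {
  # coincident points: S(q) = N for every q
  pc <- generate_fixture("point_cluster", n = 25, L = 16)
  sq <- structure_factor(pc)
  expect_equal(unname(sq$S), rep(25, nrow(sq)), tolerance = 1e-9)
  expect_true(all(sq$S >= 0))
  expect_identical(attr(sq, "N"), 25L)

  # q -> 0 bin equals N for any configuration
  gas <- generate_fixture("uniform_gas", n = 200, L = 16, seed = 3L)
  sqg <- structure_factor(gas)
  expect_equal(sqg$S[sqg$q == 0], 200, tolerance = 1e-9)

  # ideal random walk: log-log slope about -2 (D about 2) in the scaling
  # window between the coil size and the bond scale
  rw <- generate_fixture("random_walk", n = 8000, L = 128, seed = 14L)
  sqr <- structure_factor(rw)
  fit <- fit_effective_dimension(sqr, c(2 * pi / 30, 1.0))
  expect_gt(fit$D, 1.75)
  expect_lt(fit$D, 2.3)
})

test_that("effective-dimension fits recover exponents and flag D > 3", {
  q <- exp(seq(log(0.1), log(2), length.out = 40))
  prof <- structure(data.frame(q = q, S = q^-3, n_modes = 1L),
                    class = c("sq_profile", "data.frame"))
  fit <- fit_effective_dimension(prof, c(0.1, 2))
  expect_equal(fit$D, 3, tolerance = 1e-10)
  expect_false(fit$flagged)

  prof4 <- structure(data.frame(q = q, S = q^-4, n_modes = 1L),
                     class = c("sq_profile", "data.frame"))
  expect_warning(fit4 <- fit_effective_dimension(prof4, c(0.1, 2)),
                 "artifact")
  expect_true(fit4$flagged)
  expect_equal(fit4$D, 4, tolerance = 1e-10)

  expect_error(fit_effective_dimension(prof, c(5, 6)), "empty")
})
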