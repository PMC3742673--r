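test_that("pair potential follows the truncated generalized 12-6 form", {
  # beyond the cutoff sqrt(8): exactly zero for any well depth
  expect_identical(pair_potential(-6, 3), 0)
  expect_identical(pair_potential(67, 3), 0)
  expect_identical(pair_potential(-149, 2.9), 0)

  # attractive pair at r = 2: 6 * ((1/2)^12 - (1/2)^6)
  expect_equal(pair_potential(-6, 2), 6 * (2^-12 - 2^-6), tolerance = 1e-12)
  expect_equal(pair_potential(-6, 2), -0.09228515625)

  # like-charge pair at r = 2 is purely repulsive: 67 * ((1/2)^12 + (1/2)^6)
  expect_equal(pair_potential(67, 2), 67 * (2^-12 + 2^-6), tolerance = 1e-12)
  expect_equal(pair_potential(67, 2), 1.063232421875)
  expect_gt(pair_potential(67, 1.2), 0)

  # attractive well is negative between sigma and the cutoff
  expect_lt(pair_potential(-6, 1.5), 0)
  # at r = sigma = 1 the 12-6 terms cancel for attractive pairs
  expect_identical(pair_potential(-6, 1), 0)

  expect_error(pair_potential(-6, 0), "positive")
})

test_that("interaction shell enumerates all vectors with |v|^2 <= 8", {
  off <- neighbor_offsets()
  # 6 + 12 + 8 + 6 + 24 + 24 + 12 over |v|^2 in {1,2,3,4,5,6,8}
  expect_identical(nrow(off), 92L)
  s <- rowSums(off^2)
  expect_true(all(s >= 1 & s <= 8))
  expect_identical(sum(s == 7), 0L)
  has <- function(v) any(apply(off, 1, function(r) all(r == v)))
  expect_true(has(c(2, 2, 0)))
  expect_false(has(c(3, 0, 0)))   # |v|^2 = 9 > 8
  # closed under negation, no duplicates
  expect_true(all(apply(off, 1, function(r) has(-r))))
  expect_identical(anyDuplicated(off), 0L)
})

test_that("local energies agree with the brute-force oracle", {
  st <- small_system(L = 12L, C_p = 0.05, seed = 31L)
  st <- metropolis_sweep(st, 50L)

  # sum of per-node local energies counts each pair twice
  le <- vapply(seq_len(st$n_chains * st$chain_len), function(n) {
    local_energy(st, (n - 1) %/% st$chain_len + 1L,
                 (n - 1) %% st$chain_len + 1L)
  }, numeric(1))
  expect_equal(sum(le) / 2, total_energy_oracle(st), tolerance = 1e-10)

  # a node probed at an empty faraway site sees nothing... unless neighbors
  # are present; an isolated dimer node sees only its partner
  cfg1 <- simulation_config(L = 16L, C_p = 2 / 16^3 + 1e-9, n_mcs = 1L,
                            seed = 2L, occupancy_mode = "site")
  d <- initialize_system(cfg1, parse_sequence("AA"), quiet_matrix())
  bond <- d$coords[2, ] - d$coords[1, ]
  bond <- bond - d$L * round(bond / d$L)
  r <- sqrt(sum(bond^2))
  expect_equal(local_energy(d, 1, 1), pair_potential(-6, r), tolerance = 1e-12)
})

test_that("incremental energy matches the oracle after 1000 sweeps", {
  st <- small_system(L = 12L, C_p = 0.05, T = 0.8, seed = 77L)
  st <- metropolis_sweep(st, 1000L)
  e_oracle <- total_energy_oracle(st)
  expect_lt(abs(st$energy - e_oracle) / max(abs(e_oracle), 1), 1e-8)
  expect_lt(e_oracle, 0)   # attractive-dominated system
})

test_that("a single bonded dimer samples the exact Boltzmann distribution", {
  # exact enumeration over the 108 allowed bond vectors is the oracle
  mat <- delta_matrix("A", "A", -100)
  bv <- allowed_bond_vectors("classic")
  r2 <- rowSums(bv^2)
  E <- vapply(sqrt(r2), function(r) pair_potential(-100, r), numeric(1))
  Tred <- 1.0
  w <- exp(-E / Tred)
  classes <- sort(unique(r2))
  p_exact <- vapply(classes, function(cl) sum(w[r2 == cl]), numeric(1)) / sum(w)

  cfg <- simulation_config(L = 8L, C_p = 2 / 512 + 1e-9, T = Tred,
                           n_mcs = 1L, seed = 123L, occupancy_mode = "site")
  st <- initialize_system(cfg, parse_sequence("AA"), mat)
  expect_identical(st$n_chains, 1L)

  n_samp <- 1500L
  counts <- setNames(numeric(length(classes)), classes)
  for (i in seq_len(n_samp)) {
    st <- metropolis_sweep(st, 50L)
    b <- st$coords[2, ] - st$coords[1, ]
    b <- b - st$L * round(b / st$L)
    cl <- as.character(sum(b^2))
    counts[cl] <- counts[cl] + 1
  }
  p_obs <- counts / n_samp
  se <- sqrt(p_exact * (1 - p_exact) / n_samp)
  # within 3 standard errors per bond-length class (samples 50 MCS apart)
  expect_true(all(abs(p_obs - p_exact) <= pmax(3.5 * se, 0.02)),
              info = paste("obs:", paste(round(p_obs, 3), collapse = " "),
                           "exact:", paste(round(p_exact, 3), collapse = " ")))
})

test_that("dynamics respect the MCS contract and degenerate limits", {
  st <- small_system(L = 12L, C_p = 0.05, seed = 55L)
  N <- st$n_chains * st$chain_len

  st1 <- metropolis_sweep(st, 7L)
  expect_identical(attr(st1, "attempts"), 7 * N)

  # zero sweeps change nothing
  st0 <- metropolis_sweep(st, 0L)
  expect_identical(st0$coords, st$coords)
  expect_identical(attr(st0, "attempts"), 0)

  # downhill-or-flat moves always accepted: with a zero matrix the
  # acceptance rate equals the athermal constraint-only rate; at T -> Inf
  # the interacting system approaches the same rate
  zero <- delta_matrix("A", "A", 0)
  cfg <- simulation_config(L = 12L, C_p = 0.05, T = 1e6, n_mcs = 1L, seed = 9L,
                           occupancy_mode = "site")
  sti <- initialize_system(cfg, matrix = quiet_matrix())
  sti <- metropolis_sweep(sti, 400L)
  stz <- initialize_system(cfg, matrix = zero)
  stz <- metropolis_sweep(stz, 400L)
  r_inf <- attr(sti, "accepted") / attr(sti, "attempts")
  r_free <- attr(stz, "accepted") / attr(stz, "attempts")
  expect_lt(abs(r_inf - r_free), 0.02)

  # determinism: same config and seed give identical trajectories
  cfg2 <- simulation_config(L = 12L, C_p = 0.05, T = 0.9, n_mcs = 50L,
                            seed = 33L, occupancy_mode = "site")
  tr_a <- run_simulation(cfg2)
  tr_b <- run_simulation(cfg2)
  expect_identical(tr_a$state$coords, tr_b$state$coords)
  expect_identical(tr_a$energy, tr_b$energy)
  expect_identical(tr_a$hops, tr_b$hops)
})

test_that("trajectories record monotone checkpoints and rejected overlaps", {
  cfg <- simulation_config(L = 12L, C_p = 0.05, T = 1.0, n_mcs = 0L, seed = 4L,
                           occupancy_mode = "site")
  tr0 <- run_simulation(cfg)
  expect_identical(tr0$times, 0L)          # only the initial checkpoint
  expect_identical(dim(tr0$node_energy)[2], 1L)

  cfg2 <- simulation_config(L = 12L, C_p = 0.05, T = 1.0, n_mcs = 200L,
                            seed = 4L, occupancy_mode = "site")
  tr <- run_simulation(cfg2)
  expect_true(all(diff(tr$times) > 0))
  expect_identical(max(tr$times), 200L)
  # hop counters are non-decreasing
  expect_true(all(apply(tr$hops, 1, function(h) all(diff(h) >= 0))))
  # excluded volume held at every stored configuration
  expect_true(verify_state(tr$state)$ok)
})
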