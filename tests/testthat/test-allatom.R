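test_that("switching function is 1 below R_on, 0 above R_C, smooth between", {
  p <- switching_params()   # R_on = 1.0 nm, R_C = 1.2 nm
  expect_identical(switching_function(0.9, p), 1)
  expect_identical(switching_function(1.0, p), 1)
  expect_identical(switching_function(1.2, p), 0)
  expect_identical(switching_function(1.3, p), 0)

  # direct evaluation of the X-PLOR form at 1.1 nm
  sw_ref <- (1.44 - 1.21)^2 * (1.44 + 2 * 1.21 - 3) / (1.44 - 1)^3
  expect_equal(switching_function(1.1, p), sw_ref, tolerance = 1e-12)
  expect_equal(switching_function(1.1, p), 0.534065, tolerance = 1e-5)
  expect_gt(switching_function(1.1, p), 0)
  expect_lt(switching_function(1.1, p), 1)

  # continuity at both endpoints and monotone decrease in between
  R <- seq(0, 1.5, by = 1e-3)
  sw <- switching_function(R, p)
  expect_true(all(sw >= 0 & sw <= 1))
  expect_true(all(diff(sw) <= 1e-9))
  expect_lt(abs(switching_function(1.0 + 1e-9, p) - 1), 1e-6)
  expect_lt(switching_function(1.2 - 1e-6, p), 1e-9)
})

test_that("switched pair energy has the vdW minimum and exact cutoff", {
  p <- switching_params()
  at <- function(x, ...) atom_records(x = x, y = 0, z = 0, ...)

  # beyond the cutoff: exactly zero
  g1 <- at(0, eps = 0.2, rmin_half = 0.2)
  g2 <- at(1.25, eps = 0.2, rmin_half = 0.2)
  expect_identical(pair_interaction_energy(g1, g2, p), 0)

  # two neutral atoms at the combined Rmin (< R_on): minus the combined
  # well depth sqrt(eps_i eps_j)
  ga <- at(0, eps = 0.11, rmin_half = 0.19)
  gb <- at(0.41, eps = 0.15, rmin_half = 0.22)
  expect_equal(pair_interaction_energy(ga, gb, p), -sqrt(0.11 * 0.15),
               tolerance = 1e-12)

  # swapping the groups changes nothing
  expect_identical(pair_interaction_energy(ga, gb, p),
                   pair_interaction_energy(gb, ga, p))

  # pure Coulomb pair inside R_on: C q1 q2 / R
  gc1 <- at(0, charge = 0.5)
  gc2 <- at(0.5, charge = -0.4)
  expect_equal(pair_interaction_energy(gc1, gc2, p),
               33.20637 * 0.5 * -0.4 / 0.5, tolerance = 1e-9)

  # energy -> 0 continuously as separation approaches the cutoff
  e_near <- pair_interaction_energy(at(0, charge = 1), at(1.1999, charge = 1), p)
  expect_lt(abs(e_near), 1e-4)

  expect_error(pair_interaction_energy(gc1, at(0, charge = 1), p),
               "coincident")
})

test_that("group energy is invariant under rigid motions of both groups", {
  p <- switching_params()
  set.seed(19)
  gi <- atom_records(x = runif(4), y = runif(4), z = runif(4),
                     charge = runif(4, -0.5, 0.5), eps = runif(4, 0.05, 0.2),
                     rmin_half = runif(4, 0.15, 0.25))
  gj <- atom_records(x = runif(3) + 0.8, y = runif(3), z = runif(3),
                     charge = runif(3, -0.5, 0.5), eps = runif(3, 0.05, 0.2),
                     rmin_half = runif(3, 0.15, 0.25))
  e0 <- pair_interaction_energy(gi, gj, p)

  shift <- c(1.3, -0.4, 2.2)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  move <- function(g) {
    xyz <- t(rot %*% t(as.matrix(g[, c("x", "y", "z")]))) +
      matrix(shift, nrow(g), 3, byrow = TRUE)
    g[, c("x", "y", "z")] <- xyz
    g
  }
  expect_equal(pair_interaction_energy(move(gi), move(gj), p), e0,
               tolerance = 1e-10)
})

test_that("trajectory-minimum reduction and multi-frame CSV round-trip", {
  p <- switching_params()
  mk_frame <- function(d) list(
    group_i = atom_records(x = 0, y = 0, z = 0, eps = 0.2, rmin_half = 0.2),
    group_j = atom_records(x = d, y = 0, z = 0, eps = 0.2, rmin_half = 0.2))

  frames <- lapply(c(0.31, 0.40, 0.55), mk_frame)
  e <- vapply(frames, function(fr)
    pair_interaction_energy(fr$group_i, fr$group_j, p), numeric(1))
  m <- minimum_trajectory_energy(frames, p)
  expect_equal(as.numeric(m), min(e))
  expect_identical(attr(m, "which_frame"), which.min(e))

  # single frame: that frame's energy
  m1 <- minimum_trajectory_energy(frames[2], p)
  expect_equal(as.numeric(m1), e[2])
  expect_error(minimum_trajectory_energy(list(), p), "empty")

  # multi-frame CSV reader
  f <- tempfile(fileext = ".csv")
  rows <- do.call(rbind, lapply(seq_along(frames), function(k) {
    fr <- frames[[k]]
    rbind(cbind(frame = k, group = "i", fr$group_i),
          cbind(frame = k, group = "j", fr$group_j))
  }))
  utils::write.csv(rows, f, row.names = FALSE)
  frames2 <- read_atoms_csv(f)
  expect_length(frames2, 3L)
  m2 <- minimum_trajectory_energy(frames2, p)
  expect_equal(as.numeric(m2), min(e))
  unlink(f)

  expect_error(read_atoms_csv({
    f2 <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(x = 1, y = 2), f2, row.names = FALSE)
    f2
  }), "missing column")
  unlink(f2)
})
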