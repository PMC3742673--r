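# Small systems and matrices shared across tests.

quiet_matrix <- function(...) load_simulated_matrix(quiet = TRUE, ...)

small_system <- function(L = 12L, C_p = 0.05, T = 1.0, seed = 42L,
                         n_mcs = 10L, sequence = parse_sequence(P1_SEQUENCE),
                         occupancy_mode = "site", ...) {
  cfg <- simulation_config(L = L, C_p = C_p, T = T, n_mcs = n_mcs,
                           seed = seed, occupancy_mode = occupancy_mode, ...)
  initialize_system(cfg, sequence, quiet_matrix())
}

# A custom matrix with a single non-zero entry, for controlled energetics.
delta_matrix <- function(a = "A", b = "A", value = -1) {
  m <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m[a, b] <- m[b, a] <- value
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(m, check.names = FALSE), f, quote = FALSE)
  on.exit(unlink(f))
  load_matrix_file(f, provenance = "custom")
}

# Fallback closed form of the coarse-grained pair potential.
lj_ref <- function(eps, r) abs(eps) / r^12 + eps / r^6
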