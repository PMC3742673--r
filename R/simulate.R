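# Simulation driver: checkpointed Metropolis runs.

# Logarithmically spaced checkpoint times in (0, n_mcs], plus the endpoint.
checkpoint_schedule <- function(n_mcs, per_decade = 30L) {
  if (n_mcs < 1L) return(integer(0))
  tt <- unique(round(10^seq(0, log10(n_mcs), by = 1 / per_decade)))
  sort(unique(as.integer(c(tt, n_mcs))))
}

#' Run a checkpointed lattice Monte Carlo simulation
#'
#' Initializes the system from `config` and runs `config$n_mcs` Metropolis
#' sweeps, recording observables on a logarithmic checkpoint schedule
#' (roughly `config$checkpoints_per_decade` per decade of MCS, needed for
#' power-law fits of the dynamics).  At each checkpoint the trajectory
#' stores the per-chain centers of mass (unwrapped), per-chain radii of
#' gyration, per-node interaction energies, cumulative per-node hop counts,
#' and the cached system energy.  Runs are fully reproducible from
#' `config$seed`.
#'
#' @param config A `bfm_config`.
#' @param sequence A `peptide`; default the packaged 12-mer HSSYWYAFNNKT.
#' @param matrix An `interaction_matrix`; default the packaged simulated
#'   matrix.
#' @return A `bfm_trajectory` list with elements `times`, `energy`,
#'   `com` (chains x 3 x checkpoints), `rg` (checkpoints x chains),
#'   `node_energy` and `hops` (nodes x checkpoints), `configs` (named list
#'   of stored full configurations), `state` (final `bfm_state`),
#'   `acceptance` (overall acceptance rate), plus the inputs.
#' @examples
#' \donttest{
#' cfg <- simulation_config(L = 16, C_p = 0.05, T = 1.0, n_mcs = 200, seed = 7)
#' traj <- run_simulation(cfg)
#' tail(traj$times)
#' }
#' @export
run_simulation <- function(config, sequence = parse_sequence(P1_SEQUENCE),
                           matrix = load_simulated_matrix(quiet = TRUE)) {
  stopifnot(inherits(config, "bfm_config"))
  state <- initialize_system(config, sequence, matrix, reseed = TRUE)
  sched <- checkpoint_schedule(config$n_mcs, config$checkpoints_per_decade)
  times <- c(0L, sched)
  n_ck <- length(times)
  n_chains <- state$n_chains
  len <- state$chain_len
  N <- n_chains * len

  com <- array(NA_real_, dim = c(n_chains, 3, n_ck))
  rg <- matrix(NA_real_, n_ck, n_chains)
  node_energy <- matrix(NA_real_, N, n_ck)
  hops <- matrix(NA_integer_, N, n_ck)
  energy <- numeric(n_ck)
  configs <- list()

  keep_cfg <- switch(config$store_configs,
                     none = integer(0),
                     final = n_ck,
                     tail = seq.int(max(2L, n_ck - 4L), n_ck),
                     all = seq_len(n_ck))

  record <- function(k) {
    for (d in 1:3)   # chains are contiguous blocks of `len` rows
      com[, d, k] <<- colMeans(matrix(state$unwrapped[, d], nrow = len))
    rg[k, ] <<- vapply(seq_len(n_chains), function(ch) {
      rows <- ((ch - 1L) * len + 1L):(ch * len)
      radius_of_gyration(state$unwrapped[rows, , drop = FALSE])
    }, numeric(1))
    node_energy[, k] <<- node_energies(state)
    hops[, k] <<- state$hops
    energy[k] <<- state$energy
    if (k %in% keep_cfg)
      configs[[as.character(times[k])]] <<- state$coords
  }

  record(1L)
  accepted <- 0; attempts <- 0
  for (k in seq_along(sched)) {
    state <- metropolis_sweep(state, sched[k] - state$mcs)
    accepted <- accepted + attr(state, "accepted")
    attempts <- attempts + attr(state, "attempts")
    record(k + 1L)
  }

  structure(list(times = times, energy = energy, com = com, rg = rg,
                 node_energy = node_energy, hops = hops, configs = configs,
                 state = state, config = config, sequence = sequence,
                 matrix_provenance = attr(matrix, "provenance"),
                 acceptance = if (attempts > 0) accepted / attempts else NA_real_,
                 seed = config$seed),
            class = "bfm_trajectory")
}

#' @export
print.bfm_trajectory <- function(x, ...) {
  cat("Trajectory: ", x$state$n_chains, " chains x ", x$state$chain_len,
      " residues, ", max(x$times), " MCS (", length(x$times),
      " checkpoints), T = ", x$config$T, "\n", sep = "")
  cat("  acceptance rate ", format(round(x$acceptance, 4)),
      ", final energy ", format(x$energy[length(x$energy)]), "\n", sep = "")
  invisible(x)
}
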