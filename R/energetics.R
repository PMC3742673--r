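# Coarse-grained pair potential and Metropolis dynamics.

#' Generalized Lennard-Jones pair potential
#'
#' Interaction energy between two residue nodes separated by distance `r`
#' (lattice constants), with well-depth coefficient `eps` taken from the
#' interaction matrix:
#' \deqn{V(r) = |\epsilon|\,(\sigma/r)^{12} + \epsilon\,(\sigma/r)^{6},
#'       \qquad r \le r_c,}
#' and 0 beyond the cutoff.  An attractive pair (`eps < 0`) therefore feels a
#' standard 12-6 well whose depth scales with `|eps|`; a repulsive
#' (like-charge) pair feels a purely positive potential.  The potential is
#' truncated, not shifted, at `r_c`.
#'
#' @param eps Signed well-depth coefficient (negative = attractive).
#' @param r Distance in lattice constants (> 0); vectorized.
#' @param r_c Interaction cutoff, default \eqn{\sqrt 8}.
#' @param sigma Length unit, default 1 lattice constant.
#' @return Energy (same units as `eps`).
#' @export
pair_potential <- function(eps, r, r_c = sqrt(8), sigma = 1) {
  if (any(r <= 0)) stop("r must be positive (excluded volume forbids r = 0)",
                        call. = FALSE)
  s6 <- (sigma / r)^6
  ifelse(r > r_c, 0, abs(eps) * s6^2 + eps * s6)
}

# Pair-energy lookup over (type a, type b, r^2 = 1..8) for the kernel.
energy_table <- function(matrix, r_c = sqrt(8), sigma = 1) {
  m <- unclass(matrix)
  et <- array(0, dim = c(20, 20, 8))
  for (r2 in 1:8) {
    r <- sqrt(r2)
    if (r <= r_c) et[, , r2] <- abs(m) * (sigma / r)^12 + m * (sigma / r)^6
  }
  as.double(et)
}

#' Interaction-shell offsets
#'
#' All integer displacement vectors with squared length in `[1, 8]` — the
#' sites whose occupants interact with a given node under the \eqn{r_c =
#' \sqrt 8} cutoff — in a fixed deterministic order.
#'
#' @return Integer matrix (92 rows, 3 columns).
#' @export
neighbor_offsets <- function() {
  cpp_interaction_offsets()
}

# Per-node interaction energies on the current configuration (each pair
# contributes to both of its members, as in per-residue energy profiles).
node_energies <- function(state, at_coords = NULL) {
  cpp_node_energies(if (is.null(at_coords)) state$coords else at_coords,
                    state$occ, state$typ, state$chain_len, state$L,
                    state$etable, state$config$boundary == "periodic",
                    state$config$exclude_bonded)
}

#' Interaction energy of one node at a (possibly hypothetical) site
#'
#' Sums the pair potential over every other node within the interaction
#' range of `at`, using minimum-image distances under periodic boundaries.
#' Useful for inspecting the energetics of a contemplated move; the hot
#' path of the simulation uses the same arithmetic in compiled code.
#'
#' @param state A `bfm_state`.
#' @param chain Chain index (1-based).
#' @param node Residue position within the chain (1-based).
#' @param at Integer site (x, y, z), default the node's current position.
#' @return Energy.
#' @export
local_energy <- function(state, chain, node, at = NULL) {
  n <- (chain - 1L) * state$chain_len + node
  if (is.null(at)) at <- state$coords[n, ]
  at <- as.integer(at)
  L <- state$L
  periodic <- state$config$boundary == "periodic"
  off <- neighbor_offsets()
  pts <- sweep(off, 2, at, "+")
  if (periodic) {
    pts <- pts %% L
    keep <- rep(TRUE, nrow(pts))
  } else {
    keep <- !apply(pts < 0L | pts >= L, 1, any)
    pts <- pts[keep, , drop = FALSE]
  }
  ids <- state$occ[site_index(pts, L)]
  r2 <- rowSums(off[keep, , drop = FALSE]^2)
  sel <- ids != 0L & ids != n
  if (state$config$exclude_bonded) {
    bonded <- ids != 0L & abs(ids - n) == 1L &
      ((ids - 1L) %/% state$chain_len) == ((n - 1L) %/% state$chain_len)
    sel <- sel & !bonded
  }
  if (!any(sel)) return(0)
  m <- unclass(state$matrix)
  eps <- m[cbind(state$typ[n], state$typ[ids[sel]])]
  sum(pair_potential(eps, sqrt(r2[sel])))
}

#' Reference total energy (brute-force double loop)
#'
#' Recomputes the system energy as an O(N^2) sum of the pair potential over
#' all node pairs with minimum-image distances, independent of the cached
#' incremental bookkeeping.  Intended as a verification oracle.
#'
#' @param state A `bfm_state`.
#' @return Total energy.
#' @export
total_energy_oracle <- function(state) {
  coords <- state$coords
  N <- nrow(coords)
  if (N < 2) return(0)
  L <- state$L
  periodic <- state$config$boundary == "periodic"
  m <- unclass(state$matrix)
  r_c2 <- 8
  e <- 0
  for (i in seq_len(N - 1)) {
    j <- (i + 1):N
    d <- coords[j, , drop = FALSE] -
      matrix(coords[i, ], length(j), 3, byrow = TRUE)
    if (periodic) d <- d - L * round(d / L)
    r2 <- rowSums(d^2)
    sel <- r2 <= r_c2
    if (state$config$exclude_bonded) {
      bonded <- (j == i + 1) & (((j - 1) %/% state$chain_len) ==
                                  ((i - 1) %/% state$chain_len))
      sel <- sel & !bonded
    }
    if (any(sel)) {
      eps <- m[cbind(state$typ[i], state$typ[j[sel]])]
      e <- e + sum(pair_potential(eps, sqrt(r2[sel])))
    }
  }
  e
}

#' Run Metropolis sweeps on a system state
#'
#' Performs `n_sweeps` Monte Carlo steps.  One MCS makes N attempts (N =
#' residue count); each attempt picks a random chain, a random residue of
#' that chain, and a random elementary step, rejects it outright if excluded
#' volume or the bond-length constraints would be violated, and otherwise
#' accepts with the Metropolis probability `min(1, exp(-dE/T))`.  The cached
#' energy and per-node hop counters are updated incrementally.  Randomness
#' comes from R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param state A `bfm_state`.
#' @param n_sweeps Number of MCS to run (default 1).
#' @param T Reduced temperature; defaults to `state$config$T`.
#' @return The updated `bfm_state`; the attempt/acceptance counts of this
#'   call are attached as attributes `attempts` and `accepted`.
#' @export
metropolis_sweep <- function(state, n_sweeps = 1L, T = state$config$T) {
  stopifnot(inherits(state, "bfm_state"), T > 0, n_sweeps >= 0)
  if (n_sweeps == 0L) {
    attr(state, "attempts") <- 0; attr(state, "accepted") <- 0
    return(state)
  }
  res <- cpp_run_sweeps(state$coords, state$unwrapped, state$occ, state$typ,
                        state$chain_len, state$L, state$etable, state$bond_ok,
                        T, as.integer(n_sweeps), state$hops, state$energy,
                        state$config$boundary == "periodic",
                        state$config$move_dirs, state$config$exclude_bonded,
                        state$config$occupancy_mode == "cube",
                        state$occ_cube)
  state$coords <- res$coords
  state$unwrapped <- res$unwrapped
  state$occ <- res$occ
  if (state$config$occupancy_mode == "cube") state$occ_cube <- res$occ_cube
  state$hops <- res$hops
  state$energy <- res$energy
  state$mcs <- state$mcs + as.integer(n_sweeps)
  attr(state, "attempts") <- res$attempts
  attr(state, "accepted") <- res$accepted
  state
}
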