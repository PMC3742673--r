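# Cubic-lattice geometry, bond-fluctuation constraints, system setup.

#' Allowed bond vectors of the bond-fluctuation model
#'
#' Bonded residues are connected by vectors of length between 2 and
#' \eqn{\sqrt{10}} lattice constants.  `"classic"` returns the standard
#' 3-D bond-fluctuation vector classes (2,0,0), (2,1,0), (2,1,1), (2,2,1),
#' (3,0,0), (3,1,0) with all sign/permutation images (108 vectors); this set
#' excludes the (2,2,0) class and so preserves the non-crossing property of
#' the classic model under cube occupancy.  `"literal_range"` returns every
#' integer vector with squared length in `[4, 10]` (120 vectors, adding the
#' 12 images of (2,2,0)).
#'
#' @param mode `"classic"` or `"literal_range"`.
#' @return Integer matrix, one allowed displacement per row.
#' @export
allowed_bond_vectors <- function(mode = c("classic", "literal_range")) {
  mode <- match.arg(mode)
  g <- as.matrix(expand.grid(x = -3:3, y = -3:3, z = -3:3))
  dimnames(g) <- NULL
  s <- rowSums(g^2)
  if (mode == "literal_range") {
    keep <- s >= 4 & s <= 10
  } else {
    # vector classes by sorted absolute components
    key <- apply(abs(g), 1, function(v) paste(sort(v), collapse = ","))
    classes <- c("0,0,2", "0,1,2", "1,1,2", "1,2,2", "0,0,3", "0,1,3")
    keep <- key %in% classes
  }
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

# 7x7x7 membership lookup over components in [-3,3], flattened for the kernel.
bond_lookup <- function(bondset) {
  ok <- logical(343L)
  idx <- (bondset[, 1] + 3L) + 7L * ((bondset[, 2] + 3L) + 7L * (bondset[, 3] + 3L))
  ok[idx + 1L] <- TRUE
  ok
}

#' Simulation configuration
#'
#' Collects every knob of a lattice run.  Defaults reproduce the package's
#' reference conditions: a 64^3 box at peptide volume fraction 0.1 (node
#' count over site count) with the 12-mer HSSYWYAFNNKT and periodic
#' boundaries.
#'
#' @param L Lattice edge length in sites (>= 8).
#' @param C_p Peptide volume fraction: occupied sites per lattice site (a
#'   node fills one site in `"site"` mode, its 8-site cube in `"cube"`
#'   mode).
#' @param T Reduced temperature (units of the interaction-energy scale).
#' @param n_mcs Number of Monte Carlo steps; one MCS is one attempted move
#'   per residue in the box.
#' @param seed RNG seed (integer) for reproducible runs.
#' @param occupancy_mode `"cube"` (default: classic Carmesin-Kremer
#'   bond-fluctuation occupancy, each node filling the 8 sites of a unit
#'   cube, which guarantees bond non-crossing and a minimum nonbonded
#'   separation of 2) or `"site"` (one node per site; nonbonded pairs may
#'   approach to distance 1, giving far stickier effective contacts).
#' @param bond_set_mode Bond-vector set, see [allowed_bond_vectors()].
#' @param boundary `"periodic"` (minimum image; required for a meaningful
#'   reciprocal-lattice structure factor) or `"closed"`.
#' @param move_dirs Elementary move stencil: 6 (unit vectors) or 26.
#' @param exclude_bonded Drop 1-2 bonded pairs from the nonbonded sum.
#' @param checkpoints_per_decade Density of the logarithmic checkpoint
#'   schedule.
#' @param store_configs Which full configurations to keep in the trajectory:
#'   `"final"`, `"tail"` (last 5 checkpoints), `"all"`, or `"none"`.
#' @return A `bfm_config` list.
#' @export
simulation_config <- function(L = 64L, C_p = 0.1, T = 1.0, n_mcs = 1000L,
                              seed = 1L,
                              occupancy_mode = c("cube", "site"),
                              bond_set_mode = c("classic", "literal_range"),
                              boundary = c("periodic", "closed"),
                              move_dirs = 6L, exclude_bonded = FALSE,
                              checkpoints_per_decade = 30L,
                              store_configs = c("final", "tail", "all", "none")) {
  occupancy_mode <- match.arg(occupancy_mode)
  bond_set_mode <- match.arg(bond_set_mode)
  boundary <- match.arg(boundary)
  store_configs <- match.arg(store_configs)
  L <- as.integer(L); n_mcs <- as.integer(n_mcs); seed <- as.integer(seed)
  if (L < 8L) stop("L must be at least 8", call. = FALSE)
  if (!(C_p > 0 && C_p < 1))
    stop("C_p must lie in (0, 1)", call. = FALSE)
  if (T <= 0) stop("T must be positive", call. = FALSE)
  if (n_mcs < 0L) stop("n_mcs must be non-negative", call. = FALSE)
  if (!move_dirs %in% c(6L, 26L)) stop("move_dirs must be 6 or 26", call. = FALSE)
  structure(list(L = L, C_p = C_p, T = T, n_mcs = n_mcs, seed = seed,
                 occupancy_mode = occupancy_mode,
                 bond_set_mode = bond_set_mode, boundary = boundary,
                 move_dirs = as.integer(move_dirs),
                 exclude_bonded = isTRUE(exclude_bonded),
                 checkpoints_per_decade = as.integer(checkpoints_per_decade),
                 store_configs = store_configs),
            class = "bfm_config")
}

site_index <- function(coords, L) {
  coords[, 1] + L * (coords[, 2] + L * coords[, 3]) + 1L
}

cube_corner_sites <- function(xyz, L) {
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  pts <- sweep(corners, 2, xyz, "+") %% L
  pts[, 1] + L * (pts[, 2] + L * pts[, 3]) + 1L
}

#' Initialize a lattice system of peptides
#'
#' Places `floor(C_p * L^3 / (s * chain_length))` copies of the peptide in
#' the box (`s` = sites per node: 1 in site mode, 8 in cube mode) as random
#' walks over the allowed bond vectors, subject to excluded volume.  Seeds
#' the RNG from `config$seed` so initialization is reproducible.
#'
#' @param config A `bfm_config`.
#' @param sequence A `peptide` (see [parse_sequence()]); defaults to the
#'   packaged 12-mer.
#' @param matrix An `interaction_matrix` used for cached-energy bookkeeping;
#'   defaults to the packaged simulated matrix.
#' @param reseed Set the RNG from `config$seed` first (default `TRUE`).
#' @param max_restarts Chain regrowth attempts before giving up.
#' @return A `bfm_state`.
#' @export
initialize_system <- function(config, sequence = parse_sequence(P1_SEQUENCE),
                              matrix = load_simulated_matrix(quiet = TRUE),
                              reseed = TRUE, max_restarts = NULL) {
  stopifnot(inherits(config, "bfm_config"))
  if (reseed) set.seed(config$seed)
  L <- config$L
  len <- length(sequence)
  # volume-fraction convention: occupied sites / L^3 (a node fills one site
  # in site mode, the 8 sites of its unit cube in cube mode)
  sites_per_node <- if (config$occupancy_mode == "cube") 8L else 1L
  n_chains <- as.integer(floor(config$C_p * L^3 / (sites_per_node * len)))
  if (n_chains < 1L)
    stop("C_p too small: no complete chain fits the requested box", call. = FALSE)
  N <- n_chains * len
  if (is.null(max_restarts)) max_restarts <- max(1000L, 50L * n_chains)
  cube <- config$occupancy_mode == "cube"
  periodic <- config$boundary == "periodic"
  bondset <- allowed_bond_vectors(config$bond_set_mode)
  nb <- nrow(bondset)

  occ <- integer(L^3)
  occ_cube <- if (cube) integer(L^3) else integer(0)
  coords <- matrix(0L, N, 3)
  restarts <- 0L

  free_at <- function(xyz, self_id) {
    if (periodic) xyz <- xyz %% L
    else if (any(xyz < 0L) || any(xyz >= L)) return(FALSE)
    if (cube && !periodic && any(xyz >= L - 1L)) return(FALSE)
    if (cube) {
      cs <- cube_corner_sites(xyz, L)
      all(occ_cube[cs] == 0L | occ_cube[cs] == self_id)
    } else {
      occ[xyz[1] + L * (xyz[2] + L * xyz[3]) + 1L] == 0L
    }
  }
  place <- function(xyz, id) {
    occ[xyz[1] + L * (xyz[2] + L * xyz[3]) + 1L] <<- id
    if (cube) occ_cube[cube_corner_sites(xyz, L)] <<- id
  }
  unplace <- function(xyz) {
    occ[xyz[1] + L * (xyz[2] + L * xyz[3]) + 1L] <<- 0L
    if (cube) occ_cube[cube_corner_sites(xyz, L)] <<- 0L
  }

  for (ch in seq_len(n_chains)) {
    repeat {
      placed <- matrix(0L, len, 3)
      start <- as.integer(sample.int(L, 3, replace = TRUE) - 1L)
      ok <- free_at(start, 0L)
      k <- 0L
      if (ok) {
        placed[1, ] <- if (periodic) start %% L else start
        place(placed[1, ], (ch - 1L) * len + 1L)
        k <- 1L
        while (k < len) {
          found <- FALSE
          for (b in sample.int(nb)) {
            cand <- placed[k, ] + bondset[b, ]
            if (free_at(cand, 0L)) {
              k <- k + 1L
              placed[k, ] <- if (periodic) cand %% L else cand
              place(placed[k, ], (ch - 1L) * len + k)
              found <- TRUE
              break
            }
          }
          if (!found) break
        }
      }
      if (k == len) {
        coords[((ch - 1L) * len + 1L):(ch * len), ] <- placed
        break
      }
      if (k > 0L) for (j in seq_len(k)) unplace(placed[j, ])
      restarts <- restarts + 1L
      if (restarts > max_restarts)
        stop("could not place ", n_chains, " chains after ", restarts,
             " regrowth attempts; lower C_p or increase L", call. = FALSE)
    }
  }

  # Unfold each chain along its minimum-image bonds so unwrapped
  # coordinates are continuous even for chains straddling the boundary.
  unwrapped <- matrix(as.double(coords), N, 3)
  if (periodic) {
    for (ch in seq_len(n_chains)) {
      rows <- ((ch - 1L) * len + 1L):(ch * len)
      d <- diff(coords[rows, , drop = FALSE])
      d <- d - L * round(d / L)
      steps <- rbind(rep(0, 3), d)
      unwrapped[rows, ] <- apply(steps, 2, cumsum) +
        matrix(as.double(coords[rows[1], ]), len, 3, byrow = TRUE)
    }
  }

  state <- structure(list(
    coords = coords, unwrapped = unwrapped,
    occ = occ, occ_cube = occ_cube,
    typ = rep.int(sequence_indices(sequence), n_chains),
    chain_len = len, n_chains = n_chains, L = L,
    config = config, sequence = sequence, matrix = matrix,
    etable = energy_table(matrix),
    bond_ok = bond_lookup(bondset),
    hops = integer(N), mcs = 0L, energy = 0), class = "bfm_state")
  state$energy <- sum(node_energies(state)) / 2
  state
}

#' @export
print.bfm_state <- function(x, ...) {
  cat("Lattice peptide system: ", x$n_chains, " chains x ", x$chain_len,
      " residues on ", x$L, "^3 (", x$config$occupancy_mode,
      " occupancy, ", x$config$boundary, ")\n", sep = "")
  cat("  t = ", x$mcs, " MCS, cached energy = ", format(x$energy), "\n", sep = "")
  invisible(x)
}

#' Verify the internal invariants of a system state
#'
#' Checks bond constraints, excluded volume, occupancy-index consistency,
#' wrapped/unwrapped congruence modulo L, and agreement of the cached energy
#' with an independent full recomputation (relative tolerance 1e-8).
#'
#' @param state A `bfm_state`.
#' @return A `bfm_report` list with elements `ok` (logical) and `violations`
#'   (character vector naming the first offenders).
#' @export
verify_state <- function(state) {
  v <- character(0)
  L <- state$L
  len <- state$chain_len
  coords <- state$coords
  periodic <- state$config$boundary == "periodic"

  if (any(coords < 0L | coords >= L))
    v <- c(v, "coordinates outside [0, L)")
  if (!all((state$unwrapped - coords) %% L == 0))
    v <- c(v, "unwrapped coordinates disagree with wrapped modulo L")

  bondset <- allowed_bond_vectors(state$config$bond_set_mode)
  key <- paste(bondset[, 1], bondset[, 2], bondset[, 3])
  for (ch in seq_len(state$n_chains)) {
    rows <- ((ch - 1L) * len + 1L):(ch * len)
    d <- diff(coords[rows, , drop = FALSE])
    if (periodic) d <- d - L * round(d / L)
    bad <- which(!(paste(d[, 1], d[, 2], d[, 3]) %in% key))
    if (length(bad) > 0) {
      v <- c(v, paste0("chain ", ch, " bond ", bad[1], "-", bad[1] + 1L,
                       " has disallowed displacement (", d[bad[1], 1], ",",
                       d[bad[1], 2], ",", d[bad[1], 3], ")"))
      break
    }
  }

  idx <- site_index(coords, L)
  if (anyDuplicated(idx))
    v <- c(v, "two nodes occupy the same site")
  occ_expect <- integer(L^3)
  occ_expect[idx] <- seq_len(nrow(coords))
  if (!identical(occ_expect, state$occ))
    v <- c(v, "occupancy index does not mirror node coordinates")
  if (state$config$occupancy_mode == "cube") {
    all_corners <- unlist(lapply(seq_len(nrow(coords)), function(n)
      cube_corner_sites(coords[n, ], L)))
    if (anyDuplicated(all_corners))
      v <- c(v, "two node cubes overlap")
  }

  if (length(v) == 0) {   # geometry must be sound before energies make sense
    e <- total_energy_oracle(state)
    denom <- max(abs(e), 1)
    if (abs(e - state$energy) / denom > 1e-8)
      v <- c(v, sprintf("cached energy %.10g differs from recomputed %.10g",
                        state$energy, e))
  }

  structure(list(ok = length(v) == 0, violations = v), class = "bfm_report")
}

#' @export
print.bfm_report <- function(x, ...) {
  if (x$ok) cat("state OK\n")
  else cat("state INVALID:\n", paste0("  - ", x$violations, "\n"), sep = "")
  invisible(x)
}
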