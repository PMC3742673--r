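# Switched nonbonded pair energy of the atomistic stage.

#' Switching/cutoff parameters for the nonbonded energy
#'
#' Defaults follow the atomistic protocol behind the packaged interaction
#' table: switching distance 1.0 nm, cutoff 1.2 nm.  `coulomb_const` is the
#' dimensional constant of the electrostatic term for distances in nm,
#' charges in elementary units, and energies in kcal/mol
#' (332.0637 kcal mol^-1 A e^-2 = 33.20637 kcal mol^-1 nm e^-2).
#'
#' @param r_on Switching distance (nm).
#' @param r_c Cutoff distance (nm).
#' @param coulomb_const Electrostatic prefactor.
#' @return A `switching_params` list.
#' @export
switching_params <- function(r_on = 1.0, r_c = 1.2,
                             coulomb_const = 33.20637) {
  stopifnot(r_on > 0, r_c > r_on)
  structure(list(r_on = r_on, r_c = r_c, coulomb_const = coulomb_const),
            class = "switching_params")
}

#' X-PLOR switching function
#'
#' Smoothly takes a nonbonded pair energy from full strength at the
#' switching distance to zero at the cutoff:
#' \deqn{SW(R) = \frac{(R_C^2 - R^2)^2 (R_C^2 + 2R^2 - 3R_{on}^2)}
#'                    {(R_C^2 - R_{on}^2)^3}, \quad R_{on} < R < R_C,}
#' with `SW = 1` for `R <= R_on` and `SW = 0` for `R >= R_C`.  Continuous
#' (with continuous first derivative) at both endpoints and monotonically
#' non-increasing in between.
#'
#' @param R Distance(s), nm; vectorized.
#' @param params A [switching_params()] object.
#' @return Factor(s) in `[0, 1]`.
#' @export
switching_function <- function(R, params = switching_params()) {
  stopifnot(all(R >= 0))
  ron2 <- params$r_on^2
  rc2 <- params$r_c^2
  sw <- (rc2 - R^2)^2 * (rc2 + 2 * R^2 - 3 * ron2) / (rc2 - ron2)^3
  ifelse(R <= params$r_on, 1, ifelse(R >= params$r_c, 0, sw))
}

#' Build an atom-record table
#'
#' Atoms carry nm coordinates, partial charges (elementary units), and
#' Lennard-Jones parameters in the Rmin convention: `eps` is the positive
#' well depth (kcal/mol) and `rmin_half` half the self-pair minimum-energy
#' distance (nm).  Cross parameters combine as
#' `eps_ij = sqrt(eps_i eps_j)`, `Rmin_ij = rmin_half_i + rmin_half_j`
#' (overridable in [pair_interaction_energy()]).
#'
#' @param x,y,z Coordinates (nm).
#' @param charge Partial charges (e).
#' @param eps LJ well depths (kcal/mol, >= 0).
#' @param rmin_half Half Rmin values (nm, >= 0).
#' @param id Optional atom labels.
#' @return An `atom_records` data frame.
#' @export
atom_records <- function(x, y, z, charge = 0, eps = 0, rmin_half = 0,
                         id = NULL) {
  n <- length(x)
  df <- data.frame(id = if (is.null(id)) paste0("a", seq_len(n)) else id,
                   x = x, y = y, z = z,
                   charge = rep_len(charge, n), eps = rep_len(eps, n),
                   rmin_half = rep_len(rmin_half, n))
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("non-finite coordinates", call. = FALSE)
  if (any(df$eps < 0) || any(df$rmin_half < 0))
    stop("eps and rmin_half must be non-negative", call. = FALSE)
  structure(df, class = c("atom_records", "data.frame"))
}

#' Read atom records from CSV
#'
#' Expects columns `x, y, z, charge, eps, rmin_half` (and optionally `id`).
#' A `frame` column marks multi-frame files; a `group` column ("i"/"j" or
#' 1/2) splits each frame into the two interacting groups.
#'
#' @param path CSV path.
#' @return An `atom_records` data frame (single frame, no groups), or a
#'   list of `list(group_i, group_j)` per frame when `frame`/`group`
#'   columns are present.
#' @export
read_atoms_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  needed <- c("x", "y", "z", "charge", "eps", "rmin_half")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0)
    stop("atom CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mk <- function(d) atom_records(d$x, d$y, d$z, d$charge, d$eps, d$rmin_half,
                                 id = if ("id" %in% names(d)) d$id else NULL)
  if (!"frame" %in% names(df)) {
    if (!"group" %in% names(df)) return(mk(df))
    df$frame <- 1L
  }
  if (!"group" %in% names(df))
    stop("multi-frame atom CSV needs a 'group' column", call. = FALSE)
  lapply(split(df, df$frame), function(fr) {
    gs <- split(fr, fr$group)
    if (length(gs) != 2L)
      stop("each frame must contain exactly two groups", call. = FALSE)
    list(group_i = mk(gs[[1]]), group_j = mk(gs[[2]]))
  })
}

#' Switched nonbonded interaction energy between two atom groups
#'
#' Sums, over all cross-group atom pairs within the cutoff, the 12-6 van
#' der Waals term (Rmin convention) plus the Coulomb term
#' `C Q_i Q_j / R_ij`, each modulated by the X-PLOR switching function:
#' \deqn{E = \sum_{i,j} SW(R_{ij}) \left[
#'   \epsilon_{ij}\!\left(\!\left(\frac{R^{min}_{ij}}{R_{ij}}\right)^{12}
#'   \!- 2\left(\frac{R^{min}_{ij}}{R_{ij}}\right)^{6}\right)
#'   + \frac{C\,Q_i Q_j}{R_{ij}} \right].}
#' Pairs beyond the cutoff contribute exactly zero, and the switched energy
#' goes to zero continuously as the separation approaches the cutoff.
#'
#' @param group_i,group_j `atom_records` for the two (disjoint) groups.
#' @param params A [switching_params()] object.
#' @param combine Optional override: function `(eps_i, eps_j, rh_i, rh_j)`
#'   returning `list(eps, rmin)` per pair.
#' @return Energy in kcal/mol.
#' @export
pair_interaction_energy <- function(group_i, group_j,
                                    params = switching_params(),
                                    combine = NULL) {
  xi <- as.matrix(group_i[, c("x", "y", "z")])
  xj <- as.matrix(group_j[, c("x", "y", "z")])
  ni <- nrow(xi); nj <- nrow(xj)
  d2 <- outer(rowSums(xi^2), rowSums(xj^2), `+`) - 2 * xi %*% t(xj)
  R <- sqrt(pmax(d2, 0))
  if (any(R < 1e-9))
    stop("coincident atoms across groups", call. = FALSE)
  if (is.null(combine)) {
    eps_ij <- sqrt(outer(group_i$eps, group_j$eps))
    rmin_ij <- outer(group_i$rmin_half, group_j$rmin_half, `+`)
  } else {
    cmb <- combine(rep(group_i$eps, nj), rep(group_j$eps, each = ni),
                   rep(group_i$rmin_half, nj),
                   rep(group_j$rmin_half, each = ni))
    eps_ij <- matrix(cmb$eps, ni, nj)
    rmin_ij <- matrix(cmb$rmin, ni, nj)
  }
  s6 <- (rmin_ij / R)^6
  vdw <- eps_ij * (s6^2 - 2 * s6)
  elec <- params$coulomb_const * outer(group_i$charge, group_j$charge) / R
  sw <- switching_function(R, params)
  sum(ifelse(R >= params$r_c, 0, sw * (vdw + elec)))
}

#' Minimum pair-interaction energy along a trajectory
#'
#' Reduces a list of coordinate frames of two interacting groups to the
#' minimum of [pair_interaction_energy()] over frames — the quantity
#' tabulated per residue pair in the packaged interaction matrix.
#'
#' @param frames List of `list(group_i, group_j)` atom-record pairs (as
#'   returned by [read_atoms_csv()] on a multi-frame file).
#' @param params A [switching_params()] object.
#' @return The minimum energy (kcal/mol) and the frame attaining it
#'   (attribute `which_frame`).
#' @export
minimum_trajectory_energy <- function(frames, params = switching_params()) {
  if (length(frames) == 0) stop("empty frame list", call. = FALSE)
  e <- vapply(frames, function(fr)
    pair_interaction_energy(fr$group_i, fr$group_j, params), numeric(1))
  structure(min(e), which_frame = which.min(e))
}
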