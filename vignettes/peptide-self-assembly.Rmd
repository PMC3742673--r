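---
title: "Coarse-grained lattice Monte Carlo of peptide self-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained lattice Monte Carlo of peptide self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepbfm)
```

## The model

`pepbfm` simulates the self-assembly of short peptides with a two-level
coarse-graining. At the lower level, the chemistry of a residue pair is
reduced to a single signed number: the minimum interaction energy of the
isolated pair, tabulated for all 210 unordered pairs of the 20 amino acids.
The package ships such a table, derived from atomistic simulations of capped
residue pairs in vacuum (`load_simulated_matrix()`), with the sign convention
that the six like-charge pairs (D-D, D-E, E-E, R-R, R-K, K-K) are repulsive
and all others attractive. Any table in the same CSV format can be
substituted (`load_matrix_file()`), e.g. a knowledge-based contact matrix.

At the upper level, a peptide is a chain of residue *nodes* on a cubic
lattice, connected by fluctuating bonds of length $2 \le \ell \le \sqrt{10}$
(in lattice constants) — the bond-fluctuation model (BFM). Non-bonded nodes
within the cutoff $r_c = \sqrt 8$ interact through a generalized 12-6
potential whose well-depth coefficient is the matrix entry
$\epsilon_{ij}$:

$$V(r) \;=\; |\epsilon_{ij}|\left(\frac{\sigma}{r}\right)^{12}
  + \epsilon_{ij}\left(\frac{\sigma}{r}\right)^{6},
  \qquad \sigma = 1,\; r \le r_c,$$

truncated (not shifted) at $r_c$. An attractive pair ($\epsilon < 0$) feels
a standard Lennard-Jones well scaled by $|\epsilon|$; a like-charge pair is
purely repulsive. Temperature is reduced: $T$ carries the units of
$\epsilon$, and only the ratio $\epsilon_{ij}/T$ enters the dynamics.

Dynamics are Metropolis: each attempt picks a random chain, a random residue
of that chain, and a random unit-vector step, rejects it outright if excluded
volume or the bond constraints would be violated, and otherwise accepts with
probability $\min(1, e^{-\Delta E / T})$. One Monte Carlo step (MCS) is $N$
attempts, $N$ the residue count. The hot loop is compiled (Rcpp); all
randomness flows through R's RNG, so a run is reproducible from its seed.

## Excluded volume: why the cube representation is the default

Two excluded-volume representations are provided:

* `occupancy_mode = "cube"` (default): each node fills the 8 sites of a unit
  cube, the classic Carmesin–Kremer BFM. No two cubes may overlap, which
  enforces a minimum non-bonded separation of 2 and guarantees chains cannot
  cross.
* `occupancy_mode = "site"`: each node fills a single site. Non-bonded nodes
  may then approach to distance 1.

The choice matters far more than it may appear. The closest approach sets
the contact energy actually realized on the lattice: at $r = \sqrt 2$ the
well is $-0.109\,|\epsilon|$, at $r = 2$ only $-0.015\,|\epsilon|$ — seven
times shallower. In test runs with the packaged matrix (L = 32, $C_p = 0.1$,
$10^5$ MCS) the site representation produced a kinetically arrested glass at
every temperature we examined up to $T = 1$: center-of-mass displacement
exponents $\gamma \approx 0.1$, acceptance rates below 1%, and chain radii
of gyration inflated by stretching through over-dense aggregates. The cube
representation instead yields the phenomenology expected of a sticky-chain
fluid: normal diffusion ($\gamma \approx 0.5$) at high temperature, a
sub-diffusive, aggregating regime appearing as $T$ drops (in these
conditions below $T \approx 0.25$), and per-chain $R_g$ decreasing
monotonically with cooling. Since the bond-length floor of 2 is meaningless
unless non-bonded contacts respect the same node size, we regard the cube
representation as the physically consistent BFM and make it the default;
the site representation remains available for experimentation.

Two consequences follow. First, the volume fraction $C_p$ counts *occupied
sites* ($8N_{\rm nodes}/L^3$ under cube occupancy), so a 64³ box at
$C_p = 0.1$ holds 273 twelve-mers. Second, the temperature scale of any
phenomenon depends on the realized contact energies $\sim |\epsilon|/64$,
not on $|\epsilon|$ itself; with the packaged matrix the
diffusive-to-sub-diffusive crossover of the 12-mer HSSYWYAFNNKT sits near
$T \approx 0.2$, and the deep-quench aggregation of knowledge-based-scale
matrices (entries of order unity) near $T \approx 0.01$. Whether a printed
temperature from another implementation of such a model is comparable
depends on the exact potential that implementation used at contact; we keep
the matrix entries as published and report our own scale rather than
rescaling either.

## Observables

All observables average over chains, checkpoints of a stated window, and
replicate runs.

* `rms_com_displacement()`: $R_c(t) = \sqrt{\langle|{\bf r}_{\rm
  com}(t)-{\bf r}_{\rm com}(0)|^2\rangle}$ from unwrapped coordinates;
  `fit_power_exponent()` fits $R_c \propto t^\gamma$ on log-log axes over a
  window that defaults to the final time decade (the asymptotic regime) and
  is always reported with the fit. $\gamma = 1/2$ is normal diffusion;
  $\gamma < 1/2$ signals hindered motion inside aggregates.
* `radius_of_gyration()`, per chain, and its equilibrium mean over the
  second half of a run (the default equilibration window; the $R_g(t)$
  plateau is the criterion for having reached steady state).
* `energy_profile()` / `mobility_profile()`: per-sequence-position mean
  interaction energy (each pair attributed to both members) and successful
  hops per MCS. Chain ends are more mobile than the interior; the
  lowest-energy position of the packaged 12-mer is its lysine.
* `radial_distribution()`: unnormalized residue counts in spherical shells
  about the residue cloud's center of mass (computed by the circular-mean
  construction under periodic boundaries; a box-center option exists).
* `structure_factor()`: $S(q) = |\sum_j e^{i{\bf q}\cdot{\bf r}_j}|^2/N$ on
  the reciprocal lattice ${\bf q} = (2\pi/L)\,{\bf n}$ via FFT, direction-
  averaged in $|q|$ bins of 5% relative width. `fit_effective_dimension()`
  turns a power-law decay $S \propto q^{-1/\nu}$ into the mass-scaling
  dimension $D = 1/\nu$: $D \approx 3$ a compact solid, $D \approx 2$ an
  ideal chain. Fits with $D > 3$ are unphysical and flagged as probable
  fit-window artifacts (crossover contamination).

## Synthetic fixtures and what the tests do (and do not) show

`generate_fixture()` builds configurations with known analytic properties:
a rod (closed-form $R_g$), an ideal lattice random walk ($S(q)$ slope $-2$
in the window between coil size and bond length), coincident points
($S(q) = N$ exactly), and a uniform gas (shell-volume radial counts). These
serve as independent oracles for the analysis code. The Metropolis kernel
is checked against exact enumeration on the smallest non-trivial system — a
single bonded dimer, whose 108 bond states can be weighted by hand — and
against a brute-force $O(N^2)$ energy oracle. Passing these tests
establishes that the simulator samples the Boltzmann distribution of *this*
potential and that the observables measure what they claim; it does not
establish that the coarse-grained potential quantitatively reproduces any
particular experimental peptide system, and the vacuum-derived matrix
ignores solvent entirely.

The packaged knowledge-based-style matrix (`kb_synthetic_matrix()`) is
*synthetic* — a hydropathy-plus-charge surrogate with the magnitude
structure of published contact tables — and is intended only to exercise
the workflow; real comparisons should load the published table of interest.
At deep quench ($T \approx 0.01$) it aggregates irreversibly
(diffusion-limited cluster growth): at the scaled-down sizes used in the
tests the resulting clusters fit $D \approx 2\!-\!2.5$ in the
$q \in [0.4, 0.8]$ window, short of full compaction.

## Numerical choices

* Boundary conditions default to periodic with minimum-image distances
  (required for a reciprocal-lattice $S(q)$); a closed box is available.
* Bond set: the classic six BFM vector classes (108 vectors). The literal
  reading of the length constraint admits the 12 images of (2,2,0) as well
  (`bond_set_mode = "literal_range"`); they are excluded by default because
  they break the non-crossing guarantee.
* Bonded 1-2 pairs also feel the non-bonded potential (no exclusion is
  applied), configurable via `exclude_bonded`.
* Checkpoints are log-spaced, ~30 per decade, because power-law fits need
  log-uniform sampling; hop counters and the incrementally cached energy are
  recorded at every checkpoint, and the cache is validated against the
  oracle to 1e-8 relative tolerance in the test suite.
* Chain placement grows each chain as a random walk over the bond set with
  restart-on-dead-end; unwrapped coordinates are unfolded along minimum-image
  bonds at t = 0 so that boundary-straddling chains measure correct radii.
* Replicate seeds in `cli_sweep()` and the acceptance script are derived
  affinely from the base seed, keeping every run reproducible from one
  integer.

## Problem sizes

The reference conditions for the packaged matrix are a 64³ box at
$C_p = 0.1$ with 100 replicates of $5\times10^5$ MCS. The package's own
acceptance script and test suite run a scaled-down protocol — L = 32
(34 chains), 3–10 replicates, $0.5\!-\!2\times10^5$ MCS — chosen so a full
pass completes in minutes on one CPU while leaving the fitted exponents
stable to a few percent between seed sets.

## Known limitations

* The exact contact-energy scale realized on the lattice is a property of
  the 12-6 form at integer distances; conclusions about absolute
  temperatures should be drawn only after the user verifies the crossover
  scale for their matrix (a `cli_sweep()` over T is the intended tool).
* Vacuum-derived pair energies: no solvent, no screening, no many-body
  effects; like-charge repulsion relies on the sign convention alone.
* At deep quench the dynamics are diffusion-limited aggregation; observables
  taken there describe kinetic arrest, not equilibrium.
* Single-sequence systems only (all chains identical); mixtures would need
  per-chain sequences in the state layout.
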