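# pepbfm

Coarse-grained lattice Monte Carlo simulation of peptide self-assembly.

Short peptides aggregate — into functional assemblies, amyloid-like
deposits, or designed nanomaterials — and whether they do so is decided by
the interplay between sequence-specific residue–residue attraction and
temperature. `pepbfm` is for researchers who want to explore that interplay
at scales atomistic simulation cannot reach. It implements a hierarchical
coarse-graining: all atomistic detail of a residue pair is condensed into a
single signed energy ε\_ij (a packaged 20×20 table of minimum pair
interaction energies from atomistic simulations of capped residue pairs in
vacuum, or any user-supplied contact matrix, e.g. a knowledge-based one),
and peptides become chains of residue nodes on a cubic lattice evolving by
the bond-fluctuation model.

**Model.** Bonded nodes are joined by fluctuating bonds of length
2 ≤ ℓ ≤ √10 (lattice constants); each node excludes a unit cube of 8 sites
(classic Carmesin–Kremer occupancy, the default). Non-bonded nodes within
r\_c = √8 interact via a generalized Lennard-Jones potential

    V(r) = |ε_ij| (σ/r)^12 + ε_ij (σ/r)^6,   σ = 1,  truncated at r_c,

so ε\_ij < 0 gives an attractive well scaled by |ε\_ij| and the six
like-charge pairs (D-D, D-E, E-E, R-R, R-K, K-K; ε > 0) are purely
repulsive. Dynamics are Metropolis at reduced temperature T (one Monte Carlo
step = one attempted unit-vector move per residue), with a compiled kernel;
runs are bit-reproducible from a seed. Observables cover per-residue energy
and mobility profiles, radius of gyration, center-of-mass RMS displacement
with its anomalous-diffusion exponent γ (R\_c ∝ t^γ), radial density
profiles, and the static structure factor S(q) with power-law fits
S(q) ∝ q^(−1/ν) giving the effective mass-scaling dimension D = 1/ν
(D ≈ 3 compact solid, D ≈ 2 ideal chain; D > 3 flagged as a fit artifact).
The switched (X-PLOR) nonbonded pair-energy function used at the atomistic
stage is also provided for user-supplied atom records.

## Worked example

Twelve-residue peptide HSSYWYAFNNKT at T = 0.7 in a 32³ box at volume
fraction 0.1 (34 chains):

```r
library(pepbfm)
m <- load_simulated_matrix()
epsilon(m, "K", "E")          # strongest attraction: lysine-glutamate
#> [1] -149

cfg <- simulation_config(L = 32, C_p = 0.1, T = 0.7, n_mcs = 20000,
                         seed = 42, store_configs = "tail")
traj <- run_simulation(cfg)
traj
#> Trajectory: 34 chains x 12 residues, 20000 MCS (111 checkpoints), T = 0.7
#>   acceptance rate 0.269, final energy -35.39355

fit_power_exponent(rms_com_displacement(traj))
#> power-law exponent 0.4315 +/- 0.0126 (window [2000, 20000], 31 points)

energy_profile(traj)
#>    position residue   mean      se
#> 1         1       H -0.156 0.00776
#> ...
#> 11       11       K -0.369 0.01631
#> 12       12       T -0.185 0.00848
```

The exponent γ ≈ 0.43 just below ½ shows mildly hindered diffusion from
transient association at this temperature; cooling further (try a
`cli_sweep()` over T) drives γ well below ½ as aggregates form. The energy
profile resolves sequence specificity: position 11 (the lysine) is the most
strongly bound residue of the chain, the asparagine pair (9-N, 10-N) binds
next most strongly, and the central alanine (position 7) is the least bound
— specificity of both residue identity and sequence position. A deep quench
with a knowledge-based-scale matrix (`kb_synthetic_matrix()`, a synthetic
surrogate) produces irreversible cluster aggregation whose S(q) fits give
D ≈ 2–2.5 at the scaled-down sizes of the test suite.

A YAML-driven command line lives in `inst/cli/pepbfm.R`:

```sh
Rscript inst/cli/pepbfm.R simulate --config run.yaml --out out/
Rscript inst/cli/pepbfm.R analyze  --dir out/ --what gamma,rg,sq,rdf
Rscript inst/cli/pepbfm.R sweep    --config run.yaml \
        --temperatures 0.5,0.75,1.0 --replicates 5 --out sweep/
```

Every run directory carries a JSON manifest (config, seed, package version,
acceptance rate, file inventory) sufficient to regenerate it.

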