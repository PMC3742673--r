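Package: pepbfm
Title: Coarse-Grained Lattice Monte Carlo Simulation of Peptide Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bond-fluctuation Monte Carlo simulation of short peptides on a
    cubic lattice, in which each residue is a lattice node and non-bonded
    nodes interact through a generalized Lennard-Jones potential whose well
    depths come from a 20x20 residue-pair interaction matrix (a packaged
    matrix derived from all-atom simulations, or any user-supplied contact
    matrix in the same format). Includes Metropolis dynamics with a compiled
    kernel, trajectory observables (per-residue energy and mobility profiles,
    radius of gyration, center-of-mass displacement and anomalous diffusion
    exponent, radial density profile), structure-factor analysis with
    effective fractal dimension fits, the switched nonbonded pair-energy
    function used at the atomistic stage, and a small command-line front end
    for temperature sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
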