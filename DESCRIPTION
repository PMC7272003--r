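Package: helixtps
Title: Transition-Path Sampling and Kinetics of Transmembrane Helix Dimerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the association mechanism and kinetics of
    transmembrane helix dimers with dividing-surface transition-path sampling.
    Provides collective variables for two-chain systems (interhelical distance
    RMSD, crossing pseudo-dihedral angle, and a hybrid linear combination of
    the two), recovery of free-energy surfaces from umbrella-sampling windows
    by the weighted histogram analysis method with projection onto arbitrary
    coordinates, conjugate-momenta shooting from a dividing surface with
    basin-interval outcome classification, reactive-flux rate estimation from
    shooting ensembles with recrossing-corrected path weights, and per-contact
    mechanism statistics p(q|TP) and p(TP|q) that identify which residue
    contacts drive association. A synthetic-dynamics module (overdamped
    Langevin models on analytic multi-well potentials and a Brownian-dynamics
    toy helix dimer in a membrane plane) generates test systems with known
    kinetics so that every estimator can be validated against brute-force
    transition counting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
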