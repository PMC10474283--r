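Package: confens
Title: Conformational Ensemble Analysis: Free-Energy Landscapes, Clustering, Normal Modes and Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of protein conformational ensembles (multi-model PDB or
    plain multi-frame coordinate files): collective-variable evaluation
    (center-of-mass distances, three-group interdomain angles), Gibbs
    free-energy landscapes by Boltzmann inversion of binned densities,
    GROMOS-style conformational clustering on pairwise best-fit RMSD,
    all-atom elastic-network normal modes with rotation-translation-block
    reduction, essential-dynamics principal component analysis and mode
    overlap, per-residue heavy-atom contact prevalence, hydrogen-bond
    proxies, water occupancy grids, and deterministic synthetic-ensemble
    generators (two-domain hinge proteins, ligand binding schedules,
    hydrated sites, membrane slabs) with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
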