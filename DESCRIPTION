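Package: pathratchet
Title: Path-Collective-Variable Ratchet Dynamics for Ranking Ligand Unbinding Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adiabatic-bias (ratchet) stochastic dynamics driven by path
    collective variables, together with the trajectory-analysis pipeline used
    to rank ligand residence times across receptor mutants: frameset
    construction and S/Z path variables in mean-square-deviation space,
    ratchet and wall bias potentials with a Langevin integrator on analytic
    toy systems, translocation criteria (atom-pair distance, ligand RMSD,
    centre-of-mass distance, solvent-accessible surface fraction, solvation
    shell), protein-ligand interaction fingerprints with Tanimoto-distance
    residence-time estimation, metastable-state clustering with net-flow
    graphs, and rank-correlation statistics (replica summaries, Spearman and
    Pearson correlation against experimental dissociation rates, regression
    with outlier removal, bootstrap sample-size analysis, median-threshold
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    cluster,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
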