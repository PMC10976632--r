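Package: wbpremd
Title: Bias-Potential Replica Exchange and Unbiasing for Proline
    Cis-Trans Isomerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study coupled proline cis-trans isomerization with
    a Hamiltonian replica-exchange scheme that scales the prolyl
    peptide-bond torsion barrier across replicas and adds a one-fold
    bias destabilizing the trans isomer in every replica.  Includes a
    reduced three-dihedral-angle model with an exact quadrature oracle
    and iterative calibration to target state free energies, a
    Metropolis Monte Carlo replica-exchange sampler, histogram
    reweighting of the biased replica into unbiased densities, state
    probabilities, Boltzmann-inversion free-energy tables, potentials of
    mean force, marginal and conditional isomerization free energies
    with block standard errors, sampling diagnostics (running state
    means, transition rates, state correlations), and structural
    observables (NOE upper-bound violations, hydrogen-bond occupancies,
    feature ranking and density-based conformational clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    utils,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    ranger
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
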