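Package: dfekit
Title: Dissociation Free Energy Estimation from Metadynamics Deposition Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the Dissociation Free Energy (DFE) approach to binding
    potency estimation: reconstruction of one-dimensional metadynamics free
    energy surfaces from Gaussian deposition records, ensemble averaging on a
    common grid, a nominal-partition-function free energy of dissociation,
    one-way-trip auditing of replica trajectories, convergence diagnostics,
    and least-squares calibration of DFE against experimental binding free
    energies. Includes a one-dimensional overdamped Langevin metadynamics
    simulator so the whole pipeline can be exercised and tested without a
    molecular dynamics engine, and ships the published protein-protein and
    protein-ligand reference tables as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
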