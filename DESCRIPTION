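Package: nanobrush
Title: Peptide Adsorption Analysis on PEO-Grafted Carbon Nanotubes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds atomistic models of polymer-brush-coated carbon
    nanotubes (zigzag tube geometry from chirality indices, radially
    grafted poly(ethylene oxide) chains, homopeptides, explicit water and
    NaCl) and analyses configuration ensembles of such systems:
    cylindrical density profiles around the tube axis, radial
    distribution functions, geometric hydrogen-bond detection and
    classification, sodium-bridge detection, pattern-based secondary
    structure assignment, radius of gyration with axial decomposition,
    superposed RMSD, and MM-PBSA binding free energies with a
    finite-difference linearized Poisson-Boltzmann solver and
    Shrake-Rupley solvent-accessible surface areas. A synthetic-ensemble
    generator with known statistical ground truth makes every estimator
    testable without molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
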