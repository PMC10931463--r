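Package: lassofold
Title: Coarse-Grained Go-Model Folding with a Generic Ligand and
    Lasso-Entanglement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A one-bead-per-residue structure-based (Go) folding simulator
    for proteins, optionally coupled to a generic nine-site coarse-grained
    small-molecule ligand, together with an analysis toolkit for
    non-covalent lasso entanglements.  Provides Langevin dynamics with a
    simplified ribosome wall for nascent-chain simulations, discrete Gauss
    linking-number estimation, native-contact order parameters Q(I|J),
    entanglement gain/loss fractions, ligand-binding detection, binding
    affinity scans over the ligand-site well depth with bootstrap
    confidence intervals, and loop-erased folding-pathway analysis over
    metastable states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
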