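Package: mutantcycle
Title: Double and Triple Mutant Cycle Free-Energy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for thermodynamic coupling analysis of protein mutations:
    free-energy estimation from non-equilibrium work distributions (Bennett
    acceptance ratio, Crooks Gaussian intersection, Jarzynski), double
    mutant cycle nonadditivity and triple mutant box decomposition with
    error propagation, positional mutational scans of third-site effects,
    benchmark statistics for calculated versus experimental stability
    changes, inter-residue distances from PDB structures, and a synthetic
    free-energy landscape generator with planted pairwise and triangular
    couplings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
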