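Package: trphop
Title: Electron-Hole Transfer Kinetics Along the Cryptochrome Tryptophan Tetrad
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing electron-hole transfer along the conserved
    tryptophan tetrad of cryptochrome 4, the photoreceptor implicated in
    radical-pair magnetoreception. Implements the reversible four-state
    kinetic model of hole hopping (TrpA to TrpD), exact master-equation
    propagation, multi-start nonlinear least-squares extraction of the six
    transfer rate constants from ensemble occupation data, a kinetic
    Monte-Carlo generator of trajectory ensembles with known ground truth,
    completed/stuck trajectory classification, site-energy and coupling
    summaries, and structural descriptors (solvent-shell water counts and
    edge-to-edge donor-acceptor distance distributions with Gaussian fits)
    from PDB coordinate frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
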