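Package: idpens
Title: Characterization of Intrinsically Disordered Protein Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize heterogeneous conformational ensembles of
    intrinsically disordered proteins. Implements essential-dynamics principal
    component analysis of positional fluctuations with RMSIP subspace-overlap
    convergence checks, two-dimensional free-energy-landscape estimation and
    basin decomposition, Gromos RMSD clustering with the Fisher-Stultz ensemble
    order parameter, Kabsch-Sander secondary-structure assignment and
    Shrake-Rupley solvent-accessible surface profiling, persistence-weighted
    intramolecular interaction networks (hubs, connected components, simple
    paths), and Gaussian deconvolution of native ESI-MS charge-state
    distributions. A synthetic-ensemble generator with known ground truth
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
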