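Package: dipolarwave
Title: Orientational Analysis of Membrane-Bound Peptides from 19F-NMR
    Dipolar Couplings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to solve the membrane alignment of alpha-helical
    peptides from solid-state 19F-NMR orientational constraints measured
    on CF3-labelled analogs in macroscopically oriented lipid bilayers.
    Implements the geometric forward model from helix tilt (tau) and
    azimuthal rotation (rho) to signed CF3 dipolar splittings, Gaussian
    dynamic averaging (sigma_tau, sigma_rho), exhaustive least-squares
    fitting with RMSD landscapes and dipolar-wave curves, segmental
    analysis of bipartite peptides, and per-label classification of
    conformational states (helical, intrinsically unstructured in the
    membrane plane, or immobilized/aggregated) from the 0/90-degree
    sample-tilt behaviour and powder-pattern signatures. A synthetic-data
    generator reproduces the statistical structure of the experimental
    coupling tables so that every analysis stage can be exercised and
    validated end to end. Ships a worked analysis of the cell-penetrating
    peptide TP10.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
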