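Package: polyqens
Title: Trajectory-Ensemble Analysis of Huntingtin Exon-1 PolyQ Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for conformational ensembles of huntingtin
    exon-1 (N17-polyQ-PRD) constructs sampled by molecular dynamics.
    Provides per-residue secondary-structure statistics and helical-segment
    cooperativity maps from DSSP code matrices, helix-initiation kinetics
    with a Monte Carlo region-comparison statistic, bifurcated hydrogen-bond
    occupancy for glutamine sidechains, heavy-atom residue contact maps,
    transient beta-conformer detection, and two-dimensional free-energy
    landscapes over dimer order parameters.  A synthetic-trajectory
    generator produces secondary-structure time series, ideal-helix dimer
    coordinates and hydrogen-bond event tables with controlled statistical
    structure for testing and method calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
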