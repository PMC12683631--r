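Package: aquashift
Title: Empirical Prediction of Water 17O NMR Chemical Shifts from
    Hydrogen-Bond Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the 17O NMR chemical shift of water molecules
    directly from 3-D coordinates using an empirical distance power-law
    model of hydrogen bonding.  Reads XYZ and PDB structures, assigns
    covalent connectivity and molecule types (water, DMSO, glycerol,
    methane), detects conventional O-H...O hydrogen bonds and CH...O
    contacts with geometric criteria, classifies each water molecule as
    donor/acceptor/dangling, and evaluates calibrated r^-4 (water-water)
    and r^-6 (DMSO, CH...O) shift functions with per-term breakdowns.
    Includes the fixed-exponent power-law and linear calibration fitting
    machinery used to build the model, a synthetic-structure generator
    for water n-mers and solute complexes with prescribed hydrogen-bond
    topology, and frame-wise ensemble averaging for trajectories.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
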