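Package: pefpore
Title: Pulsed-Electric-Field Electroporation Analytics: PLS Modeling and
    Membrane Pore Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing pulsed-electric-field (PEF) electroporation
    and electrofusion data. Implements NIPALS partial least squares (PLS)
    regression with autoscaling, repeated random-split validation,
    leave-one-out Q2 and Y-scrambling permutation tests for small
    dye-uptake/fusion-rate sample tables; and membrane-trajectory analytics
    for particle configurations of hydrated lipid bilayers: charge-density
    profiles along the membrane normal, electrostatic potential by double
    integration of Poisson's equation, transmembrane potential imbalance,
    inter-leaflet water (pore) volume, and pore counting by periodic
    connected-component labeling. A synthetic-data module generates idealized
    bilayer frames with planted pores and a generative PEF dose-response
    dataset with known ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    EBImage,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
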