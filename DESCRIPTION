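Package: memblens
Title: Lipid Bilayer Order, Sterol Insertion, Segregation and Cooperative
    Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of planar lipid bilayer configurations and
    trajectories: acyl-chain order parameters referenced to the average
    leaflet tilt with ordered/disordered phase classification, sterol
    insertion depth relative to the phosphate plane, sterol tilt-angle
    distributions, number-density profiles along the bilayer normal,
    lateral segregation statistics (fraction of DPPC neighbors among
    phospholipid neighbors) with blocking-method standard errors, and
    cooperative (Hill) binding-isotherm fitting. Includes a synthetic
    bilayer generator with controllable chain order, lateral mixing state,
    sterol depth and tilt, and frame-to-frame temporal correlation, plus
    readers and writers for GRO and PDB coordinate files and DCD
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
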