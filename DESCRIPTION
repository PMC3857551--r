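Package: coactnet
Title: Meta-Analytic Co-Activation Networks from Peak Coordinates by
    Spatial ICA with Data-Driven Model-Order Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds modeled-activation brain volumes from peak activation
    coordinates, decomposes the resulting voxels-by-experiments matrix by
    spatial independent component analysis across a grid of model orders,
    projects experiment-level metadata labels onto the components, selects
    preferred model orders by the cophenetic correlation coefficient of
    metadata dendrograms, and tracks how low-order co-activation networks
    fractionate into higher-order sub-networks.  A synthetic corpus
    generator with planted spatial networks and correlated labels makes
    every stage testable without access to a coordinate database.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
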